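Package: statinpgx
Title: Statin Response Pharmacogenetics from Longitudinal Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derives non-HDL-cholesterol response to statin therapy from
    longitudinal prescribing and laboratory records, encodes statin
    adverse-drug-reaction variants under additive, dominant and recessive
    genetic models, builds a two-variant ABCB1/LILRB5 risk score, fits the
    univariate and covariate-adjusted linear models used in statin
    pharmacogenetic studies, quantifies synergy of joint genotype effects
    against the expected additive effect, and provides post hoc
    minimum-detectable-difference calculations. Ships a synthetic
    electronic-health-record generator so the whole pipeline is testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
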