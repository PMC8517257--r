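---
title: "Methods: statin response phenotyping, genetics, and synergy"
author: "statinpgx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statin response phenotyping, genetics, and synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinpgx)
```

## The problem

Statin intolerance — myalgia through, rarely, rhabdomyolysis — drives poor
adherence, switching and dose reduction, and through those behaviours can
blunt the cholesterol-lowering effect of therapy. Several common variants
(in *ABCB1*, *SLCO1B1*, *LILRB5*, *CYP3A4/5*) are associated with statin
adverse reactions; the question this package operationalises is whether such
variants also shift achieved cholesterol response in routine care, and
whether a pair of them acts synergistically.

The package implements the full analysis as a tested pipeline over four flat
tables (demographics, community prescribing events, lipid panels, genotypes),
plus a synthetic EHR generator so that every stage can be exercised and
validated without access to patient-level data — individual-level biobank
records of this kind are never publicly deposited.

## Outcome model

The response phenotype is the change in non-HDL cholesterol (total minus HDL,
mmol/L), the pro-atherogenic fraction recommended for risk monitoring:

* **baseline**: the nearest non-HDL-C on or before the first statin
  dispensing (no look-back limit by default; `max_lookback_days` restricts
  it);
* **follow-up**: the *first* non-HDL-C in the closed window 28–180 days
  after initiation;
* **absolute response** = baseline − follow-up (positive = reduction);
  **percent response** = 100 × absolute / baseline.

Association models are ordinary least squares with analytic standard errors
and t-based confidence intervals, in three nested adjustment tiers:

1. **Model 1** — genetic term only;
2. **Model 2** — adds the statin-intolerance features: adherence (PDC),
   switching, dose reduction;
3. **Model 3** — adds mean simvastatin-equivalent dose, duration of therapy
   in 28-day periods, type 2 diabetes, prior MACE, and baseline non-HDL-C.

Dose *increase* is derived but deliberately not a default covariate: the
intolerance proxies are behaviours consistent with adverse reactions, and a
dose increase is the opposite signal. It can be added explicitly to any
model's term list.

## Statin-usage covariates

**PDC.** Adherence is proportion-of-days-covered: days of supply
(quantity ÷ daily directions) summed over dispensings in
`[first, last)` prescription dates, divided by the first-to-last span in
days. The final dispensing is excluded from the numerator because its
tablets cover days after the span ends, and the ratio is left *uncapped*:
early refills and stockpiling legitimately push PDC above 1, and cohort
mean adherence above 1 must be representable. Patients with a single
dispensing before follow-up get supply ÷ (follow-up − dispense) days,
flagged `pdc_imputed`.

**Simvastatin-equivalent dose.** Potency ratios are a packaged, editable
YAML table (atorvastatin ×2, rosuvastatin ×4, pravastatin ×0.5,
fluvastatin ×0.5) — equivalence tables come from external dosing references
and are data, not code. Dose-change flags compare *equivalent* daily doses,
so a switch at constant potency is not a dose change: dose reduction proxies
intolerance, which is potency-relative.

**Windows.** "Before the follow-up measurement" is implemented uniformly as
on-or-before (`<=`) for switching, dose and PDC windows. The follow-up
window endpoints are inclusive: a lab at exactly day 28 or day 180
qualifies. Same-day duplicate assays are averaged — the only
order-independent tie rule.

## Genetics

Each panel variant carries a literature-pinned genetic model: additive
(minor-allele count), dominant (any-carrier indicator) or recessive
(homozygote indicator). `select_genetic_model()` also supports the
empirical route — fit all three encodings univariately and keep the
smallest p — with an override argument, because encoding choice in this
field combines p-values *and* prior literature. Note the empirical route is
noisy: with a true recessive effect of 0.09 mmol/L at n = 5,000 the
recessive encoding wins only ~78% of the time (measured by direct
simulation), so pinning by prior knowledge is the default in the pipeline.

Quality control is minor allele frequency (allele count over non-missing
calls; pairwise deletion per variant, so each model uses every patient with
that call) and a 1-df Pearson chi-square test of Hardy–Weinberg proportions
at the sample allele frequency, without continuity correction; a
Levene–Haldane exact test is available as an option (no installed package
exposes one, so it is implemented by enumeration over heterozygote counts).

**Two-SNP risk score.** Protection is defined jointly: level 0 (protected)
= *ABCB1* rs1045642 CC together with *LILRB5* rs12975366 CC or CT; level 1
(at risk) = *ABCB1* CT/TT together with *LILRB5* TT. These definitions
cover only 4 of the 9 genotype pairs. The score is therefore implemented in
two modes: **strict** (discordant pairs unassigned, excluded from the
binary contrast — the default) and **complement** (level 0 versus everyone
else). Which membership rule a given published analysis used is often
ambiguous — reported risk-score sample sizes tend to approach the full
genotyped cohort, which suggests intermediates were not always dropped —
so the pipeline logs the mode on every run rather than resolving the
ambiguity silently. Allele orientation in the packaged metadata records
which allele is *protective*, independent of which happens to be the
population minor allele (for *ABCB1* rs1045642 the C allele sits near 0.5
in Europeans, so "minor" is fragile).

## Synergy

For two variants A and B and the score S, all fitted under identical
outcome and covariates:

* expected additive effect = estimate(A) + estimate(B);
* synergy excess = estimate(S) − expected additive.

The excess is an exact arithmetic identity on the three estimates
(`synergy_from_estimates()` exposes the pure arithmetic; `synergy()` runs
the three fits). A positive excess means the joint effect exceeds the sum
of marginal effects — epistasis on the scale of analysis. The
`interaction_test()` operation complements this with a product term fitted
jointly with both main effects.

## Power

`minimum_detectable_difference()` is the closed-form two-sample bound

MDD = (z₁₋α/₂ + z_power) · σ · √(1/n₁ + 1/n₂),

with group sizes implied by Hardy–Weinberg proportions: the exposed
fraction is maf² (recessive) or 1 − (1 − maf)² (dominant). Neither the
power level nor the genetic model behind a published post hoc claim is
always stated; the defaults here are two-sided α = 0.05 and 80% power, both
explicit parameters, and reproduction of one-decimal published bounds is
asserted only to one decimal. The empirical power at the returned MDD,
measured by simulating individual-level data and t-testing (N = 2,000,
3,000 replicates), sits within ±2% of the target.

## The synthetic cohort generator

`simulate_cohort()` emulates a statin-initiating cohort with the
statistical structure the analysis assumes. Defaults (all tunable in
`sim_config()`):

| quantity | default | unit |
|---|---|---|
| baseline non-HDL-C | N(4.43, 1.19²) | mmol/L |
| absolute reduction, marginal mean | 1.45 | mmol/L |
| residual reduction SD | 1.04 | mmol/L |
| adherence (latent PDC) | N(1.54, 0.79²), truncated at 0 | — |
| adherence effect | 0.26 | mmol/L per PDC unit |
| baseline effect | 0.53 | mmol/L per mmol/L |
| T2D / MACE effects | −0.13 / −0.04 | mmol/L |
| statin mix | 74.7 / 19.4 / 5.9 | % simva / atorva / other |
| switchers | 3 | % |
| dose reduction / increase | 49 / 62 | % of patients |
| T2D / prior-MACE prevalence | 71.4 / 18.6 | % |
| variants | rs1045642 recessive MAF 0.48, effect 0.09; rs12975366 dominant MAF 0.40, effect 0.04 | mmol/L |
| interaction effect | 0.01 | mmol/L |

The outcome is built on the absolute-reduction scale: reduction =
mean + Σ effect × (encoding − E[encoding]) + interaction × (joint −
E[joint]) + adherence, comorbidity and baseline contributions (all centred)
+ N(0, σ²) noise; percent-reduction effects arise implicitly. Centring
keeps the marginal mean equal to the configured mean under any genetic
architecture. The default interaction effect of 0.01 makes the strict
score contrast 0.09 + 0.04 + 0.01 = 0.14 mmol/L. The follow-up non-HDL-C is
floored at 0.05 mmol/L (labs cannot go negative); with the baseline effect
at its default the floor binds for ~0.5% of patients and is immaterial,
which the recovery tests confirm.

Timing: dispensings occur every 28 days (the standard pack period) from
initiation to one pack beyond the follow-up lab, with per-patient quantity
jitter so recomputed PDC tracks latent adherence (r > 0.99 at defaults).
Baseline labs sit a lognormal median 12 days before initiation (IQR ≈
4–35), follow-up labs a median ≈ 75 days after (IQR ≈ 49–112), clamped
into [28, 180]. Decoy labs — an older historical panel, a too-early panel
(7–27 days), a post-window panel — are generated with configurable
probabilities to exercise the selection rules.

What the generator does **not** emulate: correlation between adherence,
dose changes and switching (treated as independent unless configured);
ICD-coded admission streams (comorbidities are flags); visit-driven lab
scheduling; secular trends in prescribing; pharmacokinetics. Passing
recovery tests therefore demonstrate that the estimator machinery is
unbiased under the stated architecture, not that any particular real-world
cohort satisfies that architecture.

The `truth` table (latent adherence, true encodings, injected effects) is
returned for test assertions only and is never consumed by the analysis
modules — a one-way firewall.

## Determinism and numerical choices

* Identical seed + config ⇒ bit-identical tables; the pipeline writes
  byte-identical result files on reruns.
* Phenotyping is pure and row-order independent; the only tie rules
  (same-day labs, same-day dispensings) are symmetric or ordered
  deterministically.
* OLS is `stats::lm`; the test suite checks it against an explicit
  normal-equation solve to 1e-10, and confidence intervals use the
  t-distribution with residual degrees of freedom.
* Replicate seeds are drawn once from the master seed via `sample.int`,
  keeping every seed below 2³¹.

## Problem sizes used by the checks

The replicate recovery studies (`recover_univariate_effect()`) run 200
cohorts per scenario at the cohort sizes the scenarios represent (8,843 for
the single-variant scenarios, 8,070 for the score contrast) and assert the
mean recovered univariate coefficient within 2 Monte-Carlo standard errors
of the injected truth — about 3.5 minutes on one CPU. Null-calibration
checks (HWE rejection rate, interaction-test type-I error) use 2,000
replicates at smaller n (800 and 400), where the asymptotics they test are
already in force.

## Known limitations

* Percent-reduction models are OLS on the per-patient percentage; the
  percentage is also summarised by median/IQR, and the two pathways answer
  slightly different questions for skewed baselines.
* The duration covariate runs from initiation to the follow-up *lab*, not
  to the last prescription; with long windows these diverge.
* PDC is computed over prescriptions up to the follow-up lab by default
  (the alternative — all prescriptions — is a switch in
  `compute_pdc()`-based workflows, not the pipeline default).
* The empirical genetic-model selector is unreliable at realistic effect
  sizes (see above); prefer pinned models unless n is very large.
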