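# statinpgx

Statin response pharmacogenetics from longitudinal electronic health
records.

Statin adverse-reaction variants can blunt cholesterol response through
intolerance behaviours — poor adherence, switching, dose reduction. This
package turns that question into a tested, reusable pipeline for
biostatisticians working with EHR + biobank linkages:

* **Phenotyping** — derive each patient's non-HDL-cholesterol response
  (non-HDL-C = total − HDL, mmol/L) from prescribing and laboratory
  tables: nearest-before baseline, first follow-up in the closed 28–180-day
  window, absolute (baseline − follow-up) and percentage response, plus the
  statin-usage covariates: uncapped proportion-of-days-covered adherence
  (PDC), switching, dose-change flags on the simvastatin-equivalent scale,
  mean equivalent dose, and therapy duration in 28-day pack periods.
* **Genetics** — minor allele frequencies, Hardy–Weinberg chi-square (and
  exact) tests, additive/dominant/recessive encodings, and the two-variant
  *ABCB1* rs1045642 / *LILRB5* rs12975366 unweighted risk score
  (protected level 0 = ABCB1 CC with LILRB5 CC/CT; at-risk level 1 =
  ABCB1 CT/TT with LILRB5 TT).
* **Association** — nested OLS models (univariate; + intolerance features
  PDC/switching/dose-reduction; + dose, duration, diabetes, MACE history,
  baseline non-HDL-C), genetic-model selection, a two-locus interaction
  test, and the synergy statistic: `excess = combined − (effect_A +
  effect_B)`.
* **Power** — closed-form minimum detectable difference
  `MDD = (z₁₋α/₂ + z_power)·σ·√(1/n₁ + 1/n₂)` with genotype-group sizes
  from Hardy–Weinberg proportions.
* **Synthetic EHR generator** — cohorts with the full statistical
  structure above (HWE genotypes, lipid trajectories, 28-day dispensing
  cadence, switching, dose changes, adherence) so everything is testable
  with no data download.

## Worked example

```r
library(statinpgx)

cohort <- simulate_cohort(sim_config(n_patients = 2000, seed = 42))
pheno  <- derive_phenotypes(cohort$prescriptions, cohort$labs,
                            demographics = cohort$demographics)
round(colMeans(pheno[, .(baseline_nonhdl, followup_nonhdl,
                         absolute_reduction, pdc)]), 2)
#>    baseline_nonhdl    followup_nonhdl absolute_reduction                pdc
#>               4.46               3.01               1.44               1.59
```

A mean baseline of 4.46 mmol/L falling to 3.01 mmol/L is a typical
statin-initiation picture; mean PDC 1.59 shows the *uncapped* adherence
convention (early refills push PDC above 1).

```r
genotype_qc(cohort$genotypes)
#>          rsid   gene n_called   maf hwe_chisq hwe_p
#> 1:  rs1045642  ABCB1     2000 0.478   0.00686 0.934
#> 2: rs12975366 LILRB5     2000 0.377   0.04071 0.840

pheno <- add_genetic_terms(pheno, cohort$genotypes)
fit_linear_model(pheno, "absolute_reduction",
                 c("enc_rs1045642", model_covariates(2)))
#> <pgx_model> absolute_reduction ~ enc_rs1045642 + pdc + switched + dose_reduced  (n = 2000 )
#>                term  estimate std_error conf_low conf_high   p_value
#> 1:      (Intercept)  1.095593   0.06944  0.95941    1.2318 6.121e-53
#> 2:    enc_rs1045642  0.063902   0.06542 -0.06439    0.1922 3.288e-01
#> 3:              pdc  0.208923   0.03680  0.13676    0.2811 1.563e-08
#> 4:     switchedTRUE -0.152086   0.16830 -0.48214    0.1780 3.663e-01
#> 5: dose_reducedTRUE  0.009156   0.05905 -0.10665    0.1250 8.768e-01
```

The recessive ABCB1 genotype coefficient (0.064 mmol/L here) estimates the
extra non-HDL-C reduction in CC homozygotes; each PDC unit of adherence
adds ~0.21 mmol/L. At n = 2,000 a 0.09 mmol/L genetic effect is within
noise of its estimate — the minimum-detectable-difference calculator makes
that explicit:

```r
minimum_detectable_difference(9401, maf = 0.16, "recessive",
                              outcome_sd = 1.04)   # 0.19 mmol/L
multiple_testing_threshold(n_snps = 7, n_models = 3)  # 0.00238
```

Synergy of the two-variant score against the expected additive effect,
fully adjusted, on the percentage scale:

```r
synergy(pheno, "enc_rs1045642", "enc_rs12975366", "score_protected",
        outcome = "percent_reduction", covariates = model_covariates(3))
#> <pgx_synergy> single effects: 3.4 + 0.0653 => expected additive 3.46 |
#>   combined 3.45 | excess -0.0144
```

`run_pipeline()` chains all of the above (simulate or load → phenotype →
QC → models 1–3 per variant and for the score → synergy) and produces an
attrition report and audit log; see the methods vignette
(`vignettes/statin-response-methods.Rmd`) for the model, the generator's
assumptions, and design decisions.

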