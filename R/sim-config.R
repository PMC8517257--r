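#' Default variant specification for the simulator
#'
#' The two-variant architecture used throughout the package demos: the ABCB1
#' rs1045642 variant (recessive, protective CC) and the LILRB5 rs12975366
#' variant (dominant, protective C carriers), at the panel's default minor
#' allele frequencies with protective effects of 0.09 and 0.04 mmol/L on the
#' absolute non-HDL-C reduction.
#'
#' @param variants Variant metadata table, see [variant_metadata()].
#' @param rsids Which panel variants to include.
#' @return `data.table` with columns `rsid`, `maf`, `genetic_model`,
#'   `effect`, `major_allele`, `minor_allele`.
#' @export
default_variant_specs <- function(variants = variant_metadata(),
                                  rsids = c("rs1045642", "rs12975366")) {
  miss <- setdiff(rsids, variants$rsid)
  if (length(miss)) {
    stop("unknown rsid(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  v <- variants[match(rsids, variants$rsid)]
  data.table::data.table(
    rsid = v$rsid, maf = v$default_maf, genetic_model = v$genetic_model,
    effect = v$default_effect,
    major_allele = v$major_allele, minor_allele = v$minor_allele
  )
}

#' Configuration for the synthetic EHR generator
#'
#' Bundles all tunables of [simulate_cohort()] with defaults matching the
#' cohort conditions the package emulates: baseline non-HDL-C N(4.43, 1.19^2)
#' mmol/L, mean absolute reduction 1.45 mmol/L with residual SD 1.04, mean
#' adherence (PDC) 1.54 with SD 0.79, statin mix 74.7% simvastatin / 19.4%
#' atorvastatin / 5.9% other, 3% switchers, type-2-diabetes prevalence 71.4%
#' and prior-MACE prevalence 18.6%, with follow-up labs 28-180 days after
#' initiation (median near 75 days) and baseline labs a median of 12 days
#' before.
#'
#' Genetic and covariate contributions enter the absolute-reduction scale
#' centred on their population expectation, so `reduction_mean` stays the
#' marginal mean whatever architecture is configured.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   tables.
#' @param variant_specs `data.table` as from [default_variant_specs()]:
#'   one row per simulated variant with `rsid`, `maf` (in (0, 0.5]),
#'   `genetic_model`, `effect` (mmol/L added to the absolute reduction per
#'   unit of the protective encoding), and the allele labels.
#' @param interaction_effect Extra mmol/L of reduction when both
#'   `interaction_variants` carry their protective encoding; 0 means a purely
#'   additive architecture.
#' @param interaction_variants Character pair naming the interacting rsids.
#' @param baseline_mean,baseline_sd Pre-treatment non-HDL-C distribution
#'   (mmol/L).
#' @param reduction_mean,reduction_sd Marginal mean and residual SD of the
#'   absolute reduction (mmol/L).
#' @param adherence_mean,adherence_sd Latent adherence (PDC scale, truncated
#'   at zero); values above 1 are legal.
#' @param adherence_effect mmol/L of extra reduction per PDC unit above the
#'   adherence mean.
#' @param baseline_effect mmol/L of extra reduction per mmol/L of baseline
#'   non-HDL-C above the baseline mean (regression to need: high-baseline
#'   patients reduce more).
#' @param t2d_effect,mace_effect Centred additive effects of the comorbidity
#'   flags on the reduction (mmol/L).
#' @param switch_prob Probability a patient switches statin type before the
#'   follow-up measurement.
#' @param dose_reduction_prob,dose_increase_prob Probabilities of a dose
#'   step-down / step-up somewhere before the follow-up measurement.
#' @param statin_mix Probabilities for the first statin type, named
#'   `simvastatin`, `atorvastatin`, `other`.
#' @param t2d_prev,mace_prev Comorbidity prevalences.
#' @param female_prob,age_mean,age_sd Demographics.
#' @param followup_day_range Closed window (days after initiation) in which
#'   the guaranteed follow-up lab falls.
#' @param baseline_offset_median,baseline_offset_sdlog Lognormal draw for the
#'   days between baseline lab and initiation.
#' @param followup_offset_median,followup_offset_sdlog Lognormal draw for the
#'   follow-up lab offset, clamped into `followup_day_range`.
#' @param extra_lab_prob Probability of an additional, older historical lipid
#'   panel (exercises the nearest-before baseline rule).
#' @param early_lab_prob Probability of a decoy lab 7-27 days after
#'   initiation (must be skipped by the 28-180 day window rule).
#' @param late_lab_prob Probability of a decoy lab more than 180 days after
#'   initiation.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 500, seed = 1)
#' @export
sim_config <- function(n_patients = 8843,
                       seed = NULL,
                       variant_specs = default_variant_specs(),
                       interaction_effect = 0.01,
                       interaction_variants = c("rs1045642", "rs12975366"),
                       baseline_mean = 4.43, baseline_sd = 1.19,
                       reduction_mean = 1.45, reduction_sd = 1.04,
                       adherence_mean = 1.54, adherence_sd = 0.79,
                       adherence_effect = 0.26,
                       baseline_effect = 0.53,
                       t2d_effect = -0.13, mace_effect = -0.04,
                       switch_prob = 0.03,
                       dose_reduction_prob = 0.49,
                       dose_increase_prob = 0.62,
                       statin_mix = c(simvastatin = 0.747,
                                      atorvastatin = 0.194,
                                      other = 0.059),
                       t2d_prev = 0.714, mace_prev = 0.186,
                       female_prob = 0.453,
                       age_mean = 63.06, age_sd = 10.97,
                       followup_day_range = c(28L, 180L),
                       baseline_offset_median = 12,
                       baseline_offset_sdlog = 1.55,
                       followup_offset_median = 75,
                       followup_offset_sdlog = 0.61,
                       extra_lab_prob = 0.3,
                       early_lab_prob = 0.15,
                       late_lab_prob = 0.2) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients <= 0L) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  vs <- data.table::as.data.table(variant_specs)
  req <- c("rsid", "maf", "genetic_model", "effect",
           "major_allele", "minor_allele")
  if (nrow(vs) && !all(req %in% names(vs))) {
    stop("variant_specs must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(vs)) {
    if (any(vs$maf <= 0 | vs$maf > 0.5)) {
      stop("MAFs must lie in (0, 0.5] (minor-allele convention)",
           call. = FALSE)
    }
    if (!all(vs$genetic_model %in% c("additive", "dominant", "recessive"))) {
      stop("genetic_model must be additive, dominant or recessive",
           call. = FALSE)
    }
    if (anyDuplicated(vs$rsid)) stop("duplicate rsid in variant_specs",
                                     call. = FALSE)
  }
  probs <- c(switch_prob, dose_reduction_prob, dose_increase_prob,
             t2d_prev, mace_prev, female_prob, extra_lab_prob,
             early_lab_prob, late_lab_prob, statin_mix)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(statin_mix) - 1) > 1e-8) {
    stop("statin_mix must sum to 1", call. = FALSE)
  }
  sds <- c(baseline_sd, reduction_sd, adherence_sd, age_sd)
  if (any(sds <= 0)) stop("all SDs must be positive", call. = FALSE)
  if (length(followup_day_range) != 2L ||
      followup_day_range[1] < 1 ||
      followup_day_range[2] <= followup_day_range[1]) {
    stop("followup_day_range must be an increasing pair of positive days",
         call. = FALSE)
  }
  cfg <- list(
    n_patients = n_patients, seed = seed, variant_specs = vs,
    interaction_effect = interaction_effect,
    interaction_variants = interaction_variants,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    reduction_mean = reduction_mean, reduction_sd = reduction_sd,
    adherence_mean = adherence_mean, adherence_sd = adherence_sd,
    adherence_effect = adherence_effect, baseline_effect = baseline_effect,
    t2d_effect = t2d_effect, mace_effect = mace_effect,
    switch_prob = switch_prob,
    dose_reduction_prob = dose_reduction_prob,
    dose_increase_prob = dose_increase_prob,
    statin_mix = statin_mix, t2d_prev = t2d_prev, mace_prev = mace_prev,
    female_prob = female_prob, age_mean = age_mean, age_sd = age_sd,
    followup_day_range = as.integer(followup_day_range),
    baseline_offset_median = baseline_offset_median,
    baseline_offset_sdlog = baseline_offset_sdlog,
    followup_offset_median = followup_offset_median,
    followup_offset_sdlog = followup_offset_sdlog,
    extra_lab_prob = extra_lab_prob,
    early_lab_prob = early_lab_prob,
    late_lab_prob = late_lab_prob
  )
  structure(cfg, class = "sim_config")
}
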