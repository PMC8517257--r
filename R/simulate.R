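# Synthetic EHR generator: cohorts with prescribing histories, lipid
# trajectories, genotypes and comorbidity flags carrying the statistical
# structure the downstream analysis assumes.

# truncated-normal sampler (lower bound only), by resampling the tail
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

# expected value of the protective encoding under HWE at a given MAF
encoding_expectation <- function(maf, model) {
  switch(model,
    additive  = 2 * maf,
    dominant  = 1 - (1 - maf)^2,
    recessive = maf^2,
    stop("unknown genetic model: ", model, call. = FALSE)
  )
}

# binary protective-carrier indicator used for the interaction term
protective_indicator <- function(minor_count, model) {
  if (model == "recessive") as.integer(minor_count == 2L)
  else as.integer(minor_count >= 1L)
}

#' Draw genotype counts under Hardy-Weinberg proportions
#'
#' Single multinomial draw of (major homozygote, heterozygote, minor
#' homozygote) counts with probabilities ((1-maf)^2, 2 maf (1-maf), maf^2).
#'
#' @param maf Minor allele frequency, strictly inside (0, 1).
#' @param n Number of individuals (> 0).
#' @param seed Optional integer seed.
#' @return Named integer vector `c(major_hom, het, minor_hom)` summing to `n`.
#' @examples
#' genotype_frequencies_hwe(0.16, 1000, seed = 1)
#' @export
genotype_frequencies_hwe <- function(maf, n, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf >= 1) {
    stop("maf must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  counts <- drop(rmultinom(1L, n, p))
  setNames(as.integer(counts), c("major_hom", "het", "minor_hom"))
}

#' Simulate a synthetic statin-user cohort
#'
#' Generates the four analysis input tables (demographics, community
#' prescribing events, lipid labs, genotypes) plus a latent truth table kept
#' only for test assertions. Genotypes are drawn under Hardy-Weinberg
#' proportions; the post-treatment non-HDL-C equals the baseline minus an
#' absolute reduction composed of the configured mean, centred genetic and
#' covariate contributions, an adherence contribution, and Gaussian noise.
#' Prescriptions are dispensed every 28 days (the standard pack period) with
#' per-patient quantity jitter, so that the proportion-of-days-covered
#' recomputed by the phenotyping stage tracks the latent adherence.
#' Switchers change statin type before the follow-up lab.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `synthetic_cohort`: `demographics`,
#'   `prescriptions`, `labs`, `genotypes`, `truth` (never consumed by the
#'   analysis modules), and the `config` used.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 200, seed = 7))
#' sapply(cohort[1:4], nrow)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be created by sim_config()", call. = FALSE)
  }
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_patients
  patient_id <- sprintf("P%06d", seq_len(n))

  ## demographics -----------------------------------------------------------
  init_date <- as.Date("1995-01-01") + sample.int(7305L, n, replace = TRUE) - 1L
  age <- rnorm_trunc(n, cfg$age_mean, cfg$age_sd, lower = 18)
  sex <- ifelse(runif(n) < cfg$female_prob, "F", "M")
  t2d <- rbinom(n, 1L, cfg$t2d_prev)
  mace <- rbinom(n, 1L, cfg$mace_prev)
  birth_year <- as.integer(format(init_date, "%Y")) - as.integer(round(age))
  demographics <- data.table::data.table(
    patient_id = patient_id, sex = sex, birth_year = birth_year,
    t2d = t2d, mace = mace
  )

  ## genotypes --------------------------------------------------------------
  vs <- cfg$variant_specs
  geno_list <- vector("list", nrow(vs))
  minor_counts <- matrix(0L, nrow = n, ncol = nrow(vs),
                         dimnames = list(NULL, vs$rsid))
  if (nrow(vs)) {
    for (j in seq_len(nrow(vs))) {
      g <- rbinom(n, 2L, vs$maf[j])  # HWE: binomial allele sampling
      minor_counts[, j] <- g
      a1 <- ifelse(g == 2L, vs$minor_allele[j], vs$major_allele[j])
      a2 <- ifelse(g >= 1L, vs$minor_allele[j], vs$major_allele[j])
      swap <- a1 > a2  # store alleles alphabetically for determinism
      tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
      geno_list[[j]] <- data.table::data.table(
        patient_id = patient_id, rsid = vs$rsid[j],
        allele1 = a1, allele2 = a2
      )
    }
  }
  genotypes <- if (nrow(vs)) data.table::rbindlist(geno_list) else
    data.table::data.table(patient_id = character(), rsid = character(),
                           allele1 = character(), allele2 = character())
  data.table::setkey(genotypes, patient_id, rsid)

  ## latent adherence and lab timing ----------------------------------------
  adherence <- rnorm_trunc(n, cfg$adherence_mean, cfg$adherence_sd, lower = 0.05)
  b_off <- pmax(1, round(rlnorm(n, log(cfg$baseline_offset_median),
                                cfg$baseline_offset_sdlog)))
  fu_lo <- cfg$followup_day_range[1]
  fu_hi <- cfg$followup_day_range[2]
  fu_off <- pmin(fu_hi, pmax(fu_lo, round(rlnorm(
    n, log(cfg$followup_offset_median), cfg$followup_offset_sdlog))))

  ## outcome ----------------------------------------------------------------
  baseline <- rnorm_trunc(n, cfg$baseline_mean, cfg$baseline_sd, lower = 0.3)
  det <- rep(cfg$reduction_mean, n)
  if (nrow(vs)) {
    for (j in seq_len(nrow(vs))) {
      enc <- switch(vs$genetic_model[j],
        additive  = minor_counts[, j],
        dominant  = as.integer(minor_counts[, j] >= 1L),
        recessive = as.integer(minor_counts[, j] == 2L)
      )
      det <- det + vs$effect[j] *
        (enc - encoding_expectation(vs$maf[j], vs$genetic_model[j]))
    }
  }
  joint <- rep(0L, n)
  iv <- cfg$interaction_variants
  if (cfg$interaction_effect != 0 && all(iv %in% vs$rsid)) {
    j1 <- match(iv[1], vs$rsid); j2 <- match(iv[2], vs$rsid)
    ind1 <- protective_indicator(minor_counts[, j1], vs$genetic_model[j1])
    ind2 <- protective_indicator(minor_counts[, j2], vs$genetic_model[j2])
    joint <- ind1 * ind2
    # expectation of the product of the two binary protective indicators
    e_joint <- prod(vapply(c(j1, j2), function(j) {
      m <- if (vs$genetic_model[j] == "recessive") "recessive" else "dominant"
      encoding_expectation(vs$maf[j], m)
    }, numeric(1)))
    det <- det + cfg$interaction_effect * (joint - e_joint)
  }
  det <- det +
    cfg$adherence_effect * (adherence - cfg$adherence_mean) +
    cfg$t2d_effect * (t2d - cfg$t2d_prev) +
    cfg$mace_effect * (mace - cfg$mace_prev) +
    cfg$baseline_effect * (baseline - cfg$baseline_mean)
  reduction_raw <- det + rnorm(n, 0, cfg$reduction_sd)
  followup_val <- pmax(0.05, baseline - reduction_raw)  # physical floor
  reduction <- baseline - followup_val

  ## labs -------------------------------------------------------------------
  hdl <- rnorm_trunc(n, 1.3, 0.25, lower = 0.5)
  lab_parts <- list(
    data.table::data.table(patient_id = patient_id,
                           date = init_date - b_off, non_hdl = baseline),
    data.table::data.table(patient_id = patient_id,
                           date = init_date + fu_off, non_hdl = followup_val)
  )
  add_decoy <- function(keep, dates, values) {
    if (!any(keep)) return(NULL)
    data.table::data.table(patient_id = patient_id[keep], date = dates[keep],
                           non_hdl = pmax(0.05, values[keep]))
  }
  keep <- runif(n) < cfg$extra_lab_prob   # older historical panel
  lab_parts$hist <- add_decoy(keep,
    init_date - b_off - sample(30:365, n, replace = TRUE),
    baseline + rnorm(n, 0, 0.3))
  keep <- runif(n) < cfg$early_lab_prob   # too-early post-initiation panel
  lab_parts$early <- add_decoy(keep,
    init_date + sample(7:27, n, replace = TRUE),
    baseline + rnorm(n, 0, 0.3))
  keep <- runif(n) < cfg$late_lab_prob    # beyond the follow-up window
  lab_parts$late <- add_decoy(keep,
    init_date + sample((fu_hi + 1):(fu_hi + 200), n, replace = TRUE),
    followup_val + rnorm(n, 0, 0.3))
  labs <- data.table::rbindlist(lab_parts, use.names = TRUE)
  labs[, hdl_cholesterol := hdl[match(patient_id, demographics$patient_id)]]
  labs[, total_cholesterol := non_hdl + hdl_cholesterol]
  labs[, non_hdl := NULL]
  data.table::setkey(labs, patient_id, date)

  ## prescriptions -----------------------------------------------------------
  statins <- c("simvastatin", "atorvastatin", "rosuvastatin",
               "pravastatin", "fluvastatin")
  mix <- cfg$statin_mix
  type_grp <- sample(names(mix), n, replace = TRUE, prob = mix)
  type1 <- ifelse(type_grp == "other",
                  sample(c("rosuvastatin", "pravastatin", "fluvastatin"),
                         n, replace = TRUE),
                  type_grp)
  switch_flag <- runif(n) < cfg$switch_prob
  type2 <- vapply(seq_len(n), function(i) {
    if (!switch_flag[i]) return(NA_character_)
    sample(setdiff(statins, type1[i]), 1L)
  }, character(1))
  ratios <- default_equivalence_table()
  start_equiv <- sample(c(10, 20, 40, 80), n, replace = TRUE,
                        prob = c(0.15, 0.45, 0.30, 0.10))
  red_flag <- runif(n) < cfg$dose_reduction_prob
  inc_flag <- runif(n) < cfg$dose_increase_prob
  k_pre <- fu_off %/% 28L + 1L            # scripts on/before follow-up lab
  k <- k_pre + 1L                         # plus one beyond, therapy continues
  switch_idx <- 2L + as.integer(floor(runif(n) * (k_pre - 1L)))
  red_idx <- 2L + as.integer(floor(runif(n) * (k_pre - 1L)))
  inc_idx <- 2L + as.integer(floor(runif(n) * (k_pre - 1L)))
  directions_pt <- ifelse(runif(n) < 0.1, 2, 1)
  q_jit <- runif(sum(k), 0.92, 1.08)

  idx <- rep(seq_len(n), k)
  script_index <- sequence(k)
  rx <- data.table::data.table(
    patient_id = patient_id[idx],
    dispense_date = init_date[idx] + (script_index - 1L) * 28L,
    statin_type = ifelse(switch_flag[idx] & script_index >= switch_idx[idx],
                         type2[idx], type1[idx]),
    equiv = start_equiv[idx] *
      ifelse(red_flag[idx] & script_index >= red_idx[idx], 0.5, 1) *
      ifelse(inc_flag[idx] & script_index >= inc_idx[idx], 2, 1),
    directions = directions_pt[idx]
  )
  rx[, strength := equiv / ratios[statin_type] / directions]
  rx[, quantity := pmax(1, round(28 * directions * adherence[idx] * q_jit))]
  rx[, equiv := NULL]
  data.table::setkey(rx, patient_id, dispense_date)

  ## truth (test-only; one-way firewall into the analysis) -------------------
  truth <- data.table::data.table(
    patient_id = patient_id, adherence = adherence,
    baseline_nonhdl = baseline, followup_nonhdl = followup_val,
    expected_reduction = det, reduction = reduction,
    joint_protective = joint, switched = switch_flag,
    followup_offset_days = fu_off
  )
  if (nrow(vs)) {
    for (j in seq_len(nrow(vs))) {
      truth[, paste0("enc_", vs$rsid[j]) := switch(vs$genetic_model[j],
        additive  = minor_counts[, j],
        dominant  = as.integer(minor_counts[, j] >= 1L),
        recessive = as.integer(minor_counts[, j] == 2L))]
    }
  }

  structure(
    list(demographics = demographics, prescriptions = rx, labs = labs,
         genotypes = genotypes, truth = truth, config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$config$n_patients, "patients;",
      nrow(x$prescriptions), "prescriptions;", nrow(x$labs), "labs;",
      nrow(x$genotypes), "genotype calls\n")
  invisible(x)
}

#' Write a synthetic cohort as CSV input tables
#'
#' Writes `demographics.csv`, `prescriptions.csv`, `labs.csv` and
#' `genotypes.csv` (RFC-4180, ISO-8601 dates) to a directory, optionally also
#' a minimal VCF 4.2 of the genotypes. The truth table is deliberately not
#' written: it must never reach the analysis modules.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @param vcf Also write `genotypes.vcf`?
#' @param variants Variant metadata (needed for VCF CHROM/POS/REF/ALT).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE,
                         variants = variant_metadata()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    demographics = file.path(dir, "demographics.csv"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    labs = file.path(dir, "labs.csv"),
    genotypes = file.path(dir, "genotypes.csv")
  )
  data.table::fwrite(cohort$demographics, paths["demographics"])
  data.table::fwrite(cohort$prescriptions, paths["prescriptions"],
                     dateTimeAs = "ISO")
  data.table::fwrite(cohort$labs, paths["labs"], dateTimeAs = "ISO")
  data.table::fwrite(cohort$genotypes, paths["genotypes"])
  if (vcf) {
    vpath <- file.path(dir, "genotypes.vcf")
    write_genotypes_vcf(cohort$genotypes, vpath, variants = variants)
    paths <- c(paths, vcf = vpath)
  }
  invisible(paths)
}
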