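# Orchestration: simulate (or load) -> phenotype -> genotype QC ->
# association -> synergy, with an attrition report and a plain-text log.

#' Run the full statin-response analysis pipeline
#'
#' Takes either a synthetic-cohort configuration (self-generation) or the
#' four input tables, derives the phenotype table, runs genotype QC, fits
#' the nested response models for each panel variant under its pinned
#' genetic model, builds the two-variant risk score, computes the synergy
#' statistic, and assembles an attrition report and run log. Deterministic
#' given the seed embedded in `sim`.
#'
#' @param sim A [sim_config()] for self-generation, or `NULL` when `tables`
#'   is given.
#' @param tables Optional named list with `demographics`, `prescriptions`,
#'   `labs`, `genotypes` (tables or CSV paths).
#' @param variants Variant metadata.
#' @param models Integer subset of 1:3 (see [model_covariates()]).
#' @param outcomes Outcome columns to model.
#' @param subsets Named list of first-statin-type restrictions (`NULL`
#'   element = all patients).
#' @param score_mode Risk-score mode, `"strict"` or `"complement"`.
#' @param out_dir Optional directory: writes phenotype/QC/model CSVs, a
#'   JSON synergy report, the attrition table and the log.
#' @return List of class `pgx_run`: `phenotypes`, `qc`, `model_results`
#'   (long `data.table`), `synergy` (nested list by subset and outcome),
#'   `attrition`, `log`.
#' @export
run_pipeline <- function(sim = NULL, tables = NULL,
                         variants = variant_metadata(),
                         models = 1:3,
                         outcomes = c("absolute_reduction",
                                      "percent_reduction"),
                         subsets = list(
                           all_statins = NULL,
                           simva_atorva = c("simvastatin", "atorvastatin")),
                         score_mode = "strict",
                         out_dir = NULL) {
  if (is.null(sim) == is.null(tables)) {
    stop("provide exactly one of `sim` or `tables`", call. = FALSE)
  }
  log <- character()
  say <- function(...) {
    line <- paste0(...)
    log <<- c(log, line)
    invisible(line)
  }

  if (!is.null(sim)) {
    say("simulating cohort: n_patients=", sim$n_patients,
        " seed=", if (is.null(sim$seed)) "NULL" else sim$seed)
    cohort <- simulate_cohort(sim)
    tables <- cohort[c("demographics", "prescriptions", "labs", "genotypes")]
  } else {
    tables <- lapply(tables, function(x) {
      if (is.character(x)) data.table::fread(x) else
        data.table::as.data.table(x)
    })
  }

  ph <- derive_phenotypes(tables$prescriptions, tables$labs,
                          demographics = tables$demographics)
  attrition <- attr(ph, "attrition")
  say("phenotypes derived: ", nrow(ph), " patients retained (",
      paste(names(attrition), attrition, sep = "=", collapse = ", "), ")")

  qc <- genotype_qc(tables$genotypes, variants)
  for (i in seq_len(nrow(qc))) {
    say("QC ", qc$rsid[i], ": n=", qc$n_called[i],
        " MAF=", round(qc$maf[i], 3), " HWE p=", signif(qc$hwe_p[i], 3))
  }

  ph <- add_genetic_terms(ph, tables$genotypes, variants,
                          score_mode = score_mode)
  say("risk-score mode: ", score_mode)
  attrition <- c(attrition,
                 score_assigned = sum(!is.na(ph$risk_score_level)))

  panel <- variants[variants$rsid %in% unique(tables$genotypes$rsid)]
  results <- list()
  for (sub_name in names(subsets)) {
    sub <- if (is.null(subsets[[sub_name]])) ph else
      statin_subset(ph, subsets[[sub_name]])
    for (outc in outcomes) {
      for (i in seq_len(nrow(panel))) {
        rs <- panel$rsid[i]
        say("variant ", rs, ": pinned genetic model ",
            panel$genetic_model[i])
        for (m in models) {
          fit <- fit_linear_model(sub, outc,
                                  c(paste0("enc_", rs), model_covariates(m)))
          tr <- term_row(fit, paste0("enc_", rs))
          results[[length(results) + 1L]] <- data.table::data.table(
            subset = sub_name, outcome = outc, term = rs, model = m,
            estimate = tr$estimate, std_error = tr$std_error,
            conf_low = tr$conf_low, conf_high = tr$conf_high,
            p_value = tr$p_value, n = fit$n)
        }
      }
      if ("score_protected" %in% names(sub)) {
        for (m in models) {
          fit <- fit_linear_model(sub, outc,
                                  c("score_protected", model_covariates(m)))
          tr <- term_row(fit, "score_protected")
          results[[length(results) + 1L]] <- data.table::data.table(
            subset = sub_name, outcome = outc, term = "two_snp_score",
            model = m, estimate = tr$estimate, std_error = tr$std_error,
            conf_low = tr$conf_low, conf_high = tr$conf_high,
            p_value = tr$p_value, n = fit$n)
        }
      }
    }
  }
  model_results <- data.table::rbindlist(results)

  syn <- list()
  score_vars <- c("rs1045642", "rs12975366")
  if (all(paste0("enc_", score_vars) %in% names(ph))) {
    for (sub_name in names(subsets)) {
      sub <- if (is.null(subsets[[sub_name]])) ph else
        statin_subset(ph, subsets[[sub_name]])
      syn[[sub_name]] <- lapply(setNames(outcomes, outcomes), function(outc) {
        synergy(sub, paste0("enc_", score_vars[1]),
                paste0("enc_", score_vars[2]), "score_protected",
                outcome = outc, covariates = model_covariates(3))
      })
      for (outc in outcomes) {
        s <- syn[[sub_name]][[outc]]
        say("synergy [", sub_name, ", ", outc, "]: combined=",
            signif(s$combined, 3), " expected_additive=",
            signif(s$expected_additive, 3), " excess=",
            signif(s$synergy_excess, 3))
      }
    }
  }

  out <- structure(
    list(phenotypes = ph, qc = qc, model_results = model_results,
         synergy = syn, attrition = attrition, log = log),
    class = "pgx_run"
  )
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  data.table::fwrite(run$phenotypes, file.path(out_dir, "phenotypes.csv"),
                     dateTimeAs = "ISO")
  data.table::fwrite(run$qc, file.path(out_dir, "genotype_qc.csv"))
  data.table::fwrite(run$model_results,
                     file.path(out_dir, "model_results.csv"))
  syn_flat <- lapply(run$synergy, function(by_out) {
    lapply(by_out, function(s) s[c("effect_a", "effect_b", "combined",
                                   "expected_additive", "synergy_excess")])
  })
  jsonlite::write_json(syn_flat, file.path(out_dir, "synergy.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(
    data.table::data.table(step = names(run$attrition),
                           n = as.integer(run$attrition)),
    file.path(out_dir, "attrition.csv"))
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.pgx_run <- function(x, ...) {
  cat("<pgx_run>", nrow(x$phenotypes), "patients phenotyped;",
      nrow(x$model_results), "model results\n")
  invisible(x)
}

# ---- replicate parameter-recovery studies ----------------------------------

recovery_config <- function(scenario, n_patients) {
  specs <- default_variant_specs()
  switch(scenario,
    abcb1 = sim_config(
      n_patients = n_patients,
      variant_specs = specs[specs$rsid == "rs1045642"],
      interaction_effect = 0),
    lilrb5 = sim_config(
      n_patients = n_patients,
      variant_specs = specs[specs$rsid == "rs12975366"],
      interaction_effect = 0),
    score = sim_config(
      n_patients = n_patients,
      variant_specs = specs,
      interaction_effect = 0.01),
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

# injected truth for each scenario: the single-variant effects, or for the
# score the strict level-0 vs level-1 contrast (sum of effects + interaction)
recovery_truth <- function(scenario) {
  specs <- default_variant_specs()
  switch(scenario,
    abcb1 = specs$effect[specs$rsid == "rs1045642"],
    lilrb5 = specs$effect[specs$rsid == "rs12975366"],
    score = sum(specs$effect) + 0.01
  )
}

#' Replicate parameter-recovery study
#'
#' Simulates `n_replicates` independent synthetic cohorts, runs each through
#' the full phenotyping and genotype-encoding pipeline, fits the univariate
#' linear model for the scenario's genetic term, and collects the
#' coefficient. Scenarios: `"abcb1"` (single recessive variant at MAF 0.48,
#' injected effect 0.09 mmol/L, default n 8,843), `"lilrb5"` (single
#' dominant variant at MAF 0.40, effect 0.04 mmol/L, n 8,843), `"score"`
#' (both variants plus interaction so the strict two-SNP score contrast is
#' 0.14 mmol/L, default n 8,070).
#'
#' @param scenario One of `"abcb1"`, `"lilrb5"`, `"score"`.
#' @param n_replicates Number of replicate cohorts (default 200).
#' @param n_patients Cohort size; scenario default if `NULL`.
#' @param seed Integer seed controlling all replicates.
#' @return List: `estimates` (per-replicate coefficients), `mean_estimate`,
#'   `mc_se` (Monte-Carlo standard error of the mean), `injected` (true
#'   value), `n_patients`, `n_used` (mean complete-case n across
#'   replicates), `scenario`.
#' @export
recover_univariate_effect <- function(scenario, n_replicates = 200,
                                      n_patients = NULL, seed = 1) {
  scenario <- match.arg(scenario, c("abcb1", "lilrb5", "score"))
  if (is.null(n_patients)) {
    n_patients <- if (scenario == "score") 8070L else 8843L
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  term <- switch(scenario,
    abcb1 = "enc_rs1045642", lilrb5 = "enc_rs12975366",
    score = "score_protected")
  cfg <- recovery_config(scenario, n_patients)
  est <- numeric(n_replicates)
  n_used <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg$seed <- rep_seeds[r]
    cohort <- simulate_cohort(cfg)
    ph <- derive_phenotypes(cohort$prescriptions, cohort$labs,
                            demographics = cohort$demographics)
    ph <- add_genetic_terms(ph, cohort$genotypes)
    fit <- fit_linear_model(ph, "absolute_reduction", term)
    tr <- term_row(fit, term)
    est[r] <- tr$estimate
    n_used[r] <- fit$n
  }
  list(
    estimates = est,
    mean_estimate = mean(est),
    mc_se = sd(est) / sqrt(n_replicates),
    injected = recovery_truth(scenario),
    n_patients = n_patients,
    n_used = mean(n_used),
    scenario = scenario
  )
}
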