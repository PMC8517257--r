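# Association models: univariate and covariate-adjusted OLS, genetic-model
# selection, the two-locus interaction test, and the observed-vs-expected
# synergy statistic.

#' Covariate sets for the nested adjustment models
#'
#' Model 1 is univariate (genetic term only). Model 2 adds the statin
#' intolerance features: adherence (PDC), switching, and dose reduction.
#' Model 3 adds mean simvastatin-equivalent dose, duration of therapy in
#' 28-day periods, type 2 diabetes, prior MACE, and baseline non-HDL-C.
#' Dose increase is computed by the phenotyping stage but is not a default
#' covariate; add it explicitly if wanted.
#'
#' @param model 1, 2 or 3.
#' @return Character vector of covariate column names (empty for model 1).
#' @export
model_covariates <- function(model) {
  if (!model %in% 1:3) stop("model must be 1, 2 or 3", call. = FALSE)
  m2 <- c("pdc", "switched", "dose_reduced")
  m3 <- c(m2, "mean_sim_equiv_dose", "duration_periods", "t2d", "mace",
          "baseline_nonhdl")
  switch(model, character(0), m2, m3)
}

#' Fit an ordinary least-squares response model
#'
#' Complete-case OLS of the chosen outcome on the given terms, with analytic
#' standard errors, t-based 95% confidence intervals and p-values. Results
#' are independent of row order. A rank-deficient design raises an explicit
#' singularity error naming the collinear terms.
#'
#' @param data Phenotype table (rows with any missing term are dropped).
#' @param outcome Outcome column, e.g. `"absolute_reduction"` (mmol/L) or
#'   `"percent_reduction"` (%).
#' @param terms Character vector of predictor column names / formula terms.
#'   Empty fits an intercept-only model.
#' @param conf_level Confidence level for the intervals.
#' @return Object of class `pgx_model`: list with `terms` (a `data.table`
#'   of estimate, std_error, conf_low, conf_high, p_value per term), `n`,
#'   `sigma` (residual SD), `r_squared`, `outcome`, `formula`.
#' @examples
#' d <- data.frame(y = c(5, 7, 9, 11), x = 1:4)
#' fit_linear_model(d, "y", "x")$terms
#' @export
fit_linear_model <- function(data, outcome, terms = character(),
                             conf_level = 0.95) {
  dt <- data.table::as.data.table(data)
  vars <- unique(c(outcome, all.vars(
    as.formula(paste("~", paste(c("1", terms), collapse = "+"))))))
  miss <- setdiff(vars, names(dt))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dt <- dt[complete.cases(dt[, ..vars]), ..vars]
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- as.formula(paste(outcome, "~", rhs))
  if (nrow(dt) <= length(terms) + 1L) {
    stop("not enough complete cases to fit the model", call. = FALSE)
  }
  fit <- lm(fml, data = dt)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("singular design: collinear term(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  df <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  res <- data.table::data.table(
    term = rownames(ct),
    estimate = ct[, 1], std_error = ct[, 2],
    conf_low = ct[, 1] - tcrit * ct[, 2],
    conf_high = ct[, 1] + tcrit * ct[, 2],
    p_value = ct[, 4]
  )
  structure(
    list(terms = res, n = nrow(dt), sigma = sm$sigma,
         r_squared = sm$r.squared, rss = sum(fit$residuals^2),
         outcome = outcome, formula = deparse(fml)),
    class = "pgx_model"
  )
}

#' @export
print.pgx_model <- function(x, ...) {
  cat("<pgx_model>", x$formula, " (n =", x$n, ")\n")
  print(x$terms, digits = 4)
  invisible(x)
}

# pull one term's row out of a pgx_model
term_row <- function(model, term) {
  idx <- which(model$terms[["term"]] == term)
  if (length(idx) != 1L) {
    stop("term not found in model: ", term, call. = FALSE)
  }
  model$terms[idx]
}

#' Choose the genetic model for a variant by univariate fit
#'
#' Fits the univariate outcome model under additive, dominant and recessive
#' encodings of one variant and returns the encoding with the smallest
#' p-value, unless a literature prior (`override`) pins the choice — the
#' packaged panel pins ABCB1 rs1045642 to recessive and LILRB5 rs12975366 to
#' dominant.
#'
#' @param phenotypes Phenotype table.
#' @param genotypes Long genotype table.
#' @param rsid Variant to encode.
#' @param variants Variant metadata (supplies the minor allele and any
#'   pinned model).
#' @param outcome Outcome column.
#' @param covariates Additional adjustment terms.
#' @param override `NULL` (use min-p), `"pinned"` (use the panel's model),
#'   or one of `"additive"`, `"dominant"`, `"recessive"`.
#' @return List: `chosen` (model name), `p_values` (named), `fits` (named
#'   list of `pgx_model`s, genetic term named `g`).
#' @export
select_genetic_model <- function(phenotypes, genotypes, rsid,
                                 variants = variant_metadata(),
                                 outcome = "absolute_reduction",
                                 covariates = character(),
                                 override = NULL) {
  idx <- which(variants$rsid == rsid)
  if (length(idx) != 1L) stop("unknown rsid: ", rsid, call. = FALSE)
  v <- variants[idx]
  gt <- data.table::as.data.table(genotypes)
  gt <- gt[gt$rsid == v$rsid]
  ph <- data.table::as.data.table(phenotypes)
  models <- c("additive", "dominant", "recessive")
  fits <- lapply(models, function(m) {
    enc_dt <- gt[, .(patient_id,
                     g = encode_genotype(allele1, allele2,
                                         v$minor_allele, m))]
    d <- merge(ph, enc_dt, by = "patient_id")
    fit_linear_model(d, outcome, c("g", covariates))
  })
  names(fits) <- models
  p <- vapply(fits, function(f) term_row(f, "g")$p_value, numeric(1))
  chosen <- if (is.null(override)) {
    models[which.min(p)]
  } else if (identical(override, "pinned")) {
    v$genetic_model
  } else {
    match.arg(override, models)
  }
  list(chosen = chosen, p_values = p, fits = fits)
}

#' Two-locus interaction (epistasis) test
#'
#' Fits the outcome on both encoded variants, their product term, and any
#' covariates, and reports the product-term estimate and p-value alongside
#' the full model.
#'
#' @param data Table containing the encoded variant columns.
#' @param term_a,term_b Encoded variant column names.
#' @param outcome Outcome column.
#' @param covariates Additional adjustment terms.
#' @return List: `model` (`pgx_model`), `interaction` (the product-term
#'   row).
#' @export
interaction_test <- function(data, term_a, term_b,
                             outcome = "absolute_reduction",
                             covariates = character()) {
  terms <- c(term_a, term_b, paste0(term_a, ":", term_b), covariates)
  fit <- fit_linear_model(data, outcome, terms)
  prod_name <- paste0(term_a, ":", term_b)
  list(model = fit, interaction = term_row(fit, prod_name))
}

#' Observed vs expected-additive synergy of two variants
#'
#' Fits the two single-variant models and the combined risk-score model
#' under identical outcome and covariates. The expected additive effect is
#' the sum of the two single-variant estimates; the synergy excess is the
#' combined (risk-score) estimate minus that sum. A positive excess means
#' the joint effect is greater than additive (synergistic).
#'
#' @param data Table with the encoded variant columns and the score column.
#' @param term_a,term_b,score_term Column names of the two encoded variants
#'   and the binary risk-score contrast.
#' @param outcome Outcome column (`"percent_reduction"` for
#'   percentage-scale synergy).
#' @param covariates Adjustment terms shared by all three fits.
#' @return Object of class `pgx_synergy`: effects, expected additive,
#'   excess, and the three fitted models.
#' @seealso [synergy_from_estimates()] for the pure arithmetic on already
#'   published estimates.
#' @export
synergy <- function(data, term_a, term_b, score_term,
                    outcome = "absolute_reduction",
                    covariates = character()) {
  fit_a <- fit_linear_model(data, outcome, c(term_a, covariates))
  fit_b <- fit_linear_model(data, outcome, c(term_b, covariates))
  fit_s <- fit_linear_model(data, outcome, c(score_term, covariates))
  est_a <- term_row(fit_a, term_a)$estimate
  est_b <- term_row(fit_b, term_b)$estimate
  est_s <- term_row(fit_s, score_term)$estimate
  out <- synergy_from_estimates(est_a, est_b, est_s)
  out$outcome <- outcome
  out$models <- list(a = fit_a, b = fit_b, score = fit_s)
  out
}

#' Synergy arithmetic from single-variant and combined estimates
#'
#' The expected additive effect of two variants is the sum of their
#' single-variant estimates; the synergy excess is the combined estimate
#' minus the expected additive effect (an exact arithmetic identity).
#'
#' @param effect_a,effect_b Single-variant effect estimates.
#' @param combined Combined (risk-score) effect estimate.
#' @return Object of class `pgx_synergy` with `effect_a`, `effect_b`,
#'   `combined`, `expected_additive`, `synergy_excess`.
#' @examples
#' synergy_from_estimates(0.45, 0.5, 1.61)$expected_additive # 0.95
#' @export
synergy_from_estimates <- function(effect_a, effect_b, combined = NA_real_) {
  expected <- effect_a + effect_b
  structure(
    list(effect_a = effect_a, effect_b = effect_b, combined = combined,
         expected_additive = expected,
         synergy_excess = combined - expected),
    class = "pgx_synergy"
  )
}

#' @export
print.pgx_synergy <- function(x, ...) {
  cat("<pgx_synergy> single effects:", format(x$effect_a, digits = 3), "+",
      format(x$effect_b, digits = 3),
      "=> expected additive", format(x$expected_additive, digits = 3),
      "| combined", format(x$combined, digits = 3),
      "| excess", format(x$synergy_excess, digits = 3), "\n")
  invisible(x)
}

#' Bonferroni threshold for the variant-model grid
#'
#' Significance threshold for testing `n_snps` variants under `n_models`
#' genetic models each: `alpha / (n_snps * n_models)`. Seven variants under
#' three models at alpha 0.05 gives 21 tests and a threshold near 0.002.
#'
#' @param n_snps,n_models Positive counts.
#' @param alpha Family-wise alpha.
#' @return The per-test threshold.
#' @examples
#' multiple_testing_threshold(7, 3) # 0.00238...
#' @export
multiple_testing_threshold <- function(n_snps, n_models, alpha = 0.05) {
  if (n_snps < 1 || n_models < 1) {
    stop("n_snps and n_models must be positive counts", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  alpha / (n_snps * n_models)
}

#' Restrict a phenotype table to chosen first statin types
#'
#' @param phenotypes Phenotype table with `first_statin_type`.
#' @param allowed Character vector of allowed statin types.
#' @return The filtered table (empty `allowed` gives an empty table).
#' @export
statin_subset <- function(phenotypes, allowed) {
  ph <- data.table::as.data.table(phenotypes)
  ph[first_statin_type %in% allowed]
}
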