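# Post hoc minimum-detectable-difference calculator for genotype-group
# contrasts on a continuous outcome.

# genotype-group fraction under HWE for the exposed group
hwe_group_fraction <- function(maf, genetic_model) {
  switch(genetic_model,
    recessive = maf^2,
    dominant  = 1 - (1 - maf)^2,
    stop("genetic_model must be 'dominant' or 'recessive'", call. = FALSE)
  )
}

#' Minimum detectable difference for a genotype-group contrast
#'
#' Closed-form two-sample minimum detectable difference for a continuous
#' outcome, with group sizes implied by Hardy-Weinberg proportions at the
#' given minor allele frequency: under a recessive model the exposed group
#' is the minor-homozygote fraction `maf^2`, under a dominant model the
#' carrier fraction `1 - (1 - maf)^2`. The normal-approximation formula is
#'
#' `MDD = (z[1 - alpha/2] + z[power]) * sd * sqrt(1/n1 + 1/n2)`.
#'
#' @param total_n Total cohort size (>= 4).
#' @param maf Minor allele frequency in (0, 1).
#' @param genetic_model `"recessive"` or `"dominant"`.
#' @param outcome_sd Outcome standard deviation (mmol/L).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.80).
#' @return Minimum detectable difference, same units as `outcome_sd`.
#' @examples
#' # a cohort of 9,401 with SD 1.04 and a recessive variant at MAF 0.16
#' minimum_detectable_difference(9401, 0.16, "recessive", 1.04)
#' @export
minimum_detectable_difference <- function(total_n, maf, genetic_model,
                                          outcome_sd, alpha = 0.05,
                                          power = 0.80) {
  if (total_n < 4) stop("total_n must be at least 4", call. = FALSE)
  if (maf <= 0 || maf >= 1) stop("maf must be in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must be in (0, 1)", call. = FALSE)
  }
  if (outcome_sd <= 0) stop("outcome_sd must be positive", call. = FALSE)
  f <- hwe_group_fraction(maf, genetic_model)
  n1 <- f * total_n
  n2 <- (1 - f) * total_n
  if (n1 < 2 || n2 < 2) {
    stop("expected group size below 2: contrast infeasible at this MAF",
         call. = FALSE)
  }
  (qnorm(1 - alpha / 2) + qnorm(power)) * outcome_sd * sqrt(1 / n1 + 1 / n2)
}

#' Is a given effect size detectable?
#'
#' An effect is detectable when it is at least the minimum detectable
#' difference for the query (closed boundary: an effect exactly equal to
#' the MDD counts as detectable).
#'
#' @inheritParams minimum_detectable_difference
#' @param effect Hypothesised true group difference (same units as
#'   `outcome_sd`).
#' @return Logical flag.
#' @export
detectable_at <- function(total_n, maf, genetic_model, outcome_sd, effect,
                          alpha = 0.05, power = 0.80) {
  effect >= minimum_detectable_difference(total_n, maf, genetic_model,
                                          outcome_sd, alpha, power)
}
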