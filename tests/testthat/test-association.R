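test_that("a noiseless line is recovered exactly", {
  d <- data.frame(x = 1:10)
  d$y <- 3 + 2 * d$x
  # summary.lm warns on exact fits; the point of the fixture
  fit <- suppressWarnings(fit_linear_model(d, "y", "x"))
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(unname(est["(Intercept)"]), 3)
  expect_equal(unname(est["x"]), 2)
  expect_lt(fit$terms$std_error[2], 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("OLS matches the explicit normal-equation solution to 1e-10", {
  set.seed(12)
  n <- 200
  for (p in c(3, 10)) {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    d <- as.data.frame(X)
    d$y <- rnorm(n)
    fit <- fit_linear_model(d, "y", colnames(X))
    Xd <- cbind(1, X)
    beta <- solve(crossprod(Xd), crossprod(Xd, d$y)) # independent oracle
    expect_lt(max(abs(fit$terms$estimate - drop(beta))), 1e-10)
    # analytic SEs against the oracle covariance
    s2 <- sum((d$y - Xd %*% beta)^2) / (n - p - 1)
    se <- sqrt(diag(s2 * solve(crossprod(Xd))))
    expect_lt(max(abs(fit$terms$std_error - se)), 1e-10)
  }
})

test_that("fits are invariant to row permutation and complete-case by model", {
  co <- small_cohort(600, seed = 22)
  ph <- add_genetic_terms(derive_phenotypes(co$prescriptions, co$labs,
                                            demographics = co$demographics),
                          co$genotypes)
  f1 <- fit_linear_model(ph, "absolute_reduction",
                         c("enc_rs1045642", model_covariates(2)))
  f2 <- fit_linear_model(ph[sample(nrow(ph))], "absolute_reduction",
                         c("enc_rs1045642", model_covariates(2)))
  expect_equal(f1$terms, f2$terms)
  # rows missing only the score still serve the single-variant model
  f3 <- fit_linear_model(ph, "absolute_reduction", "enc_rs1045642")
  f4 <- fit_linear_model(ph, "absolute_reduction", "score_protected")
  expect_gt(f3$n, f4$n)
})

test_that("model errors are explicit", {
  d <- data.frame(y = rnorm(20), a = rep(1, 20))
  d$b <- d$a * 2
  expect_error(fit_linear_model(d, "y", c("a", "b")), "collinear")
  expect_error(fit_linear_model(d, "y", "missing_col"), "missing columns")
  expect_error(fit_linear_model(d[1:2, ], "y", c("a", "b")),
               "complete cases")
})

test_that("nested covariate sets never increase the residual sum of squares", {
  co <- small_cohort(900, seed = 32)
  ph <- add_genetic_terms(derive_phenotypes(co$prescriptions, co$labs,
                                            demographics = co$demographics),
                          co$genotypes)
  rss <- sapply(1:3, function(m) {
    fit_linear_model(ph, "absolute_reduction",
                     c("enc_rs1045642", model_covariates(m)))$rss
  })
  expect_true(all(diff(rss) <= 1e-8))
  # and the covariate sets are strictly nested
  expect_true(all(model_covariates(2) %in% model_covariates(3)))
  expect_length(model_covariates(1), 0)
})

test_that("an injected recessive effect is picked up by model selection", {
  # direct-simulation oracle study: with a true recessive effect of 0.09
  # (SD 1.04, MAF 0.48, n = 5,000) the recessive encoding wins most often
  set.seed(42)
  wins <- 0L
  reps <- 60L
  for (r in seq_len(reps)) {
    g <- rbinom(5000, 2, 0.48)
    d <- data.frame(
      patient_id = sprintf("P%04d", 1:5000),
      absolute_reduction = 0.09 * (g == 2) + rnorm(5000, 0, 1.04)
    )
    gt <- data.frame(patient_id = d$patient_id, rsid = "rs1045642",
                     allele1 = ifelse(g == 2, "C", "T"),
                     allele2 = ifelse(g >= 1, "C", "T"))
    sel <- select_genetic_model(d, gt, "rs1045642")
    wins <- wins + (sel$chosen == "recessive")
  }
  expect_gte(wins / reps, 0.6)
})

test_that("model-selection override pins the encoding regardless of p", {
  co <- small_cohort(400, seed = 52)
  ph <- derive_phenotypes(co$prescriptions, co$labs)
  sel <- select_genetic_model(ph, co$genotypes, "rs1045642",
                              override = "pinned")
  expect_identical(sel$chosen, "recessive")
  sel <- select_genetic_model(ph, co$genotypes, "rs1045642",
                              override = "additive")
  expect_identical(sel$chosen, "additive")
  expect_named(sel$p_values, c("additive", "dominant", "recessive"))
})

test_that("interaction test keeps its nominal type-I error", {
  set.seed(62)
  reject <- replicate(2000, {
    d <- data.frame(
      a = as.numeric(rbinom(400, 2, 0.48) == 2),
      b = as.numeric(rbinom(400, 2, 0.40) >= 1),
      absolute_reduction = rnorm(400, 0, 1.04)
    )
    interaction_test(d, "a", "b")$interaction$p_value < 0.05
  })
  expect_gt(mean(reject), 0.035)
  expect_lt(mean(reject), 0.065)
})

test_that("interaction test has power against a real interaction", {
  set.seed(72)
  reject <- replicate(60, {
    a <- as.numeric(rbinom(8000, 2, 0.48) == 2)
    b <- as.numeric(rbinom(8000, 2, 0.40) >= 1)
    d <- data.frame(a = a, b = b,
                    absolute_reduction = 0.09 * a + 0.04 * b +
                      0.1 * a * b + rnorm(8000, 0, 1.04))
    interaction_test(d, "a", "b")$interaction$p_value < 0.05
  })
  expect_gt(mean(reject), 0.25) # measured power ~0.45 at these settings
})

test_that("a monomorphic variant raises a singularity error", {
  d <- data.frame(a = rep(0, 100), b = rbinom(100, 1, 0.5),
                  absolute_reduction = rnorm(100))
  expect_error(interaction_test(d, "a", "b"), "collinear")
})

test_that("synergy arithmetic is an exact identity", {
  s <- synergy_from_estimates(0.45, 0.5, 1.61)
  expect_equal(s$expected_additive, 0.95)
  expect_equal(s$synergy_excess, 1.61 - 0.95)
  s <- synergy_from_estimates(0.44, 0.79, 1.82)
  expect_equal(s$expected_additive, 1.23)
  # combined equal to the sum -> zero excess
  expect_equal(synergy_from_estimates(0.3, 0.2, 0.5)$synergy_excess, 0)
})

test_that("synergy excess is exactly zero when the score model is the sum model", {
  # balanced orthogonal design, deterministic additive outcome
  d <- expand.grid(a = c(0, 1), b = c(0, 1), rep = 1:25)
  d$absolute_reduction <- 1 + 0.5 * d$a + 0.3 * d$b
  d$score <- ifelse(d$a == 1 & d$b == 1, 1,
                    ifelse(d$a == 0 & d$b == 0, 0, NA))
  s <- suppressWarnings(synergy(d, "a", "b", "score")) # exact-fit warning
  expect_equal(s$effect_a, 0.5)
  expect_equal(s$effect_b, 0.3)
  expect_equal(s$combined, 0.8)
  expect_lt(abs(s$synergy_excess), 1e-12)
})

test_that("synergy excess is centred on zero under an additive architecture", {
  set.seed(82)
  excess <- replicate(40, {
    co <- simulate_cohort(sim_config(n_patients = 2500,
                                     interaction_effect = 0,
                                     seed = sample.int(1e8, 1)))
    ph <- add_genetic_terms(derive_phenotypes(co$prescriptions, co$labs),
                            co$genotypes)
    synergy(ph, "enc_rs1045642", "enc_rs12975366",
            "score_protected")$synergy_excess
  })
  mc_se <- sd(excess) / sqrt(length(excess))
  expect_lt(abs(mean(excess)), 3 * mc_se)
})

test_that("synergy excess is positive on average with an injected interaction", {
  set.seed(92)
  excess <- replicate(40, {
    co <- simulate_cohort(sim_config(n_patients = 2500,
                                     interaction_effect = 0.2,
                                     seed = sample.int(1e8, 1)))
    ph <- add_genetic_terms(derive_phenotypes(co$prescriptions, co$labs),
                            co$genotypes)
    synergy(ph, "enc_rs1045642", "enc_rs12975366",
            "score_protected")$synergy_excess
  })
  mc_se <- sd(excess) / sqrt(length(excess))
  expect_gt(mean(excess), 2 * mc_se)
})

test_that("multiple-testing threshold is alpha over the test grid", {
  expect_equal(multiple_testing_threshold(7, 3, 0.05), 0.05 / 21)
  expect_equal(round(multiple_testing_threshold(7, 3, 0.05), 3), 0.002)
  expect_equal(multiple_testing_threshold(1, 1, 0.05), 0.05)
  expect_error(multiple_testing_threshold(0, 3, 0.05), "positive")
})

test_that("statin subsetting matches the generator mix", {
  co <- small_cohort(4000, seed = 13)
  ph <- derive_phenotypes(co$prescriptions, co$labs)
  sub <- statin_subset(ph, c("simvastatin", "atorvastatin"))
  frac <- nrow(sub) / nrow(ph)
  se <- sqrt(0.941 * 0.059 / nrow(ph))
  expect_lt(abs(frac - 0.941), 3 * se)
  expect_identical(nrow(statin_subset(ph, character(0))), 0L)
  all_types <- unique(ph$first_statin_type)
  expect_identical(nrow(statin_subset(ph, all_types)), nrow(ph))
})
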