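d0 <- as.Date("2012-03-01")

test_that("baseline is the nearest measurement on or before initiation", {
  res <- derive_baseline(d0 + c(-40, -12, 30), c(5.1, 4.4, 3.0), d0)
  expect_equal(res$value, 4.4)
  expect_equal(res$offset_days, -12)
  # no pre-initiation lab -> absent
  expect_null(derive_baseline(d0 + c(5, 30), c(4, 3), d0))
  # same-day duplicate assays are averaged
  res <- derive_baseline(d0 + c(-12, -12), c(4.0, 4.6), d0)
  expect_equal(res$value, 4.3)
  # look-back limit excludes old values
  expect_null(derive_baseline(d0 - 400, 5.0, d0, max_lookback_days = 365))
})

test_that("follow-up is the earliest measurement in the closed 28-180 day window", {
  res <- derive_followup(d0 + c(10, 30, 90), c(4.2, 3.1, 2.9), d0)
  expect_equal(res$offset_days, 30)
  expect_equal(res$value, 3.1)
  expect_null(derive_followup(d0 + 27, 3.0, d0))
  # both endpoints are inclusive; earliest wins
  res <- derive_followup(d0 + c(28, 180), c(3.5, 3.0), d0)
  expect_equal(res$offset_days, 28)
  res <- derive_followup(d0 + 180, 3.0, d0)
  expect_equal(res$offset_days, 180)
})

test_that("response arithmetic and sign convention", {
  r <- compute_response(4.43, 2.98)
  expect_equal(r$absolute, 1.45)
  expect_equal(r$percent, 100 * 1.45 / 4.43) # ~32.7%
  r <- compute_response(4.0, 4.0)
  expect_equal(r$absolute, 0)
  expect_equal(r$percent, 0)
  r <- compute_response(3.0, 4.5) # worsening is negative
  expect_equal(r$absolute, -1.5)
  expect_equal(r$percent, -50)
  expect_error(compute_response(0, 1), "positive")
})

test_that("switching requires a second statin type before the follow-up lab", {
  types <- c("simvastatin", "simvastatin", "atorvastatin")
  dates <- d0 + c(0, 28, 56)
  expect_true(detect_switching(types, dates, d0 + 90))
  expect_false(detect_switching(types[1:2], dates[1:2], d0 + 90))
  # the switch happens after the follow-up lab: not a switcher
  expect_false(detect_switching(types, dates, d0 + 40))
})

test_that("duration is measured in 28-day pack periods", {
  expect_equal(duration_periods(d0, d0 + 84), 3)
  expect_equal(duration_periods(d0, d0 + 28), 1)
  expect_equal(duration_periods(d0, d0 + 75), 75 / 28)
})

test_that("simvastatin-equivalent doses come from the packaged ratio table", {
  expect_equal(sim_equiv_dose("simvastatin", 20), 20)
  expect_equal(sim_equiv_dose("atorvastatin", 10), 20)
  expect_equal(sim_equiv_dose("rosuvastatin", 5), 20)
  expect_equal(sim_equiv_dose("pravastatin", 40), 20)
  expect_error(sim_equiv_dose("ezetimibe", 10), "ezetimibe")
  # a custom table overrides the packaged ratios
  expect_equal(sim_equiv_dose("atorvastatin", 10, c(atorvastatin = 3)), 30)
})

test_that("mean dose averages equivalent daily doses before the follow-up lab", {
  types <- c("simvastatin", "simvastatin")
  expect_equal(mean_dose(types, c(20, 40), c(1, 1), d0 + c(0, 28), d0 + 60),
               30)
  expect_equal(mean_dose("simvastatin", 20, 1, d0, d0 + 60), 20)
  # mixed types through the equivalence table: simva 20 + atorva 20 -> 30
  expect_equal(mean_dose(c("simvastatin", "atorvastatin"), c(20, 20),
                         c(1, 1), d0 + c(0, 28), d0 + 60), 30)
  # directions multiply the daily dose
  expect_equal(mean_dose("simvastatin", 20, 2, d0, d0 + 60), 40)
})

test_that("dose-change flags track strict changes in equivalent dose", {
  types <- rep("simvastatin", 3)
  dates <- d0 + c(0, 28, 56)
  ch <- detect_dose_changes(types, c(20, 40, 20), rep(1, 3), dates, d0 + 90)
  expect_true(ch$dose_reduced)
  expect_true(ch$dose_increased)
  ch <- detect_dose_changes(types, c(20, 20, 20), rep(1, 3), dates, d0 + 90)
  expect_false(ch$dose_reduced)
  expect_false(ch$dose_increased)
  ch <- detect_dose_changes(types[1:2], c(40, 20), c(1, 1), dates[1:2],
                            d0 + 90)
  expect_true(ch$dose_reduced)
  expect_false(ch$dose_increased)
  # potency-neutral switch is not a dose change: simva 20 -> atorva 10
  ch <- detect_dose_changes(c("simvastatin", "atorvastatin"), c(20, 10),
                            c(1, 1), dates[1:2], d0 + 90)
  expect_false(ch$dose_reduced)
  expect_false(ch$dose_increased)
})

test_that("PDC follows the first-to-last span convention and stays uncapped", {
  # perfect coverage: 2 scripts 28 days apart, 28 tablets, 1/day
  r <- compute_pdc(d0 + c(0, 28), c(28, 28), c(1, 1))
  expect_equal(r$pdc, 1)
  expect_false(r$imputed)
  # 2/day directions halve the supplied days
  r <- compute_pdc(d0 + c(0, 28), c(28, 28), c(2, 2))
  expect_equal(r$pdc, 0.5)
  # early refills push PDC above 1: 3 scripts at days 0, 14, 28
  r <- compute_pdc(d0 + c(0, 14, 28), c(28, 28, 28), c(1, 1, 1))
  expect_equal(r$pdc, 2)
  # single prescription: imputed against the follow-up date
  r <- compute_pdc(d0, 28, 1, followup_date = d0 + 56)
  expect_equal(r$pdc, 0.5)
  expect_true(r$imputed)
})

test_that("the phenotype table matches the per-patient operations on a constructed EHR", {
  fx <- tiny_ehr()
  ph <- derive_phenotypes(fx$prescriptions, fx$labs)
  expect_identical(sort(ph$patient_id), c("P1", "P2"))
  att <- attr(ph, "attrition")
  expect_identical(unname(att),
                   c(4L, 3L, 2L)) # P3 lacks baseline, P4 lacks follow-up
  p1 <- ph[ph$patient_id == "P1", ]
  expect_equal(p1$baseline_nonhdl, 4.8)
  expect_equal(p1$followup_nonhdl, 3.3)
  expect_equal(p1$absolute_reduction, 1.5)
  expect_equal(p1$percent_reduction, 100 * 1.5 / 4.8)
  expect_equal(p1$duration_periods, 60 / 28)
  expect_false(p1$switched)
  expect_equal(p1$pdc, 1)
  p2 <- ph[ph$patient_id == "P2", ]
  expect_true(p2$switched)
  expect_true(p2$dose_reduced)
  expect_false(p2$dose_increased)
  # equivalent doses 40, 20, 10 -> mean 70/3
  expect_equal(p2$mean_sim_equiv_dose, 70 / 3)
  expect_equal(p2$pdc, 1)
})

test_that("phenotyping is pure and row-order independent", {
  co <- small_cohort(400, seed = 61)
  ph1 <- derive_phenotypes(co$prescriptions, co$labs)
  rx_shuf <- co$prescriptions[sample(nrow(co$prescriptions))]
  lb_shuf <- co$labs[sample(nrow(co$labs))]
  ph2 <- derive_phenotypes(rx_shuf, lb_shuf)
  expect_equal(ph1, ph2, ignore_attr = TRUE)
  # exact additivity: reduction + follow-up == baseline for every record
  expect_equal(ph1$absolute_reduction + ph1$followup_nonhdl,
               ph1$baseline_nonhdl)
})

test_that("switcher fraction matches the configured probability", {
  co <- small_cohort(4000, seed = 71, switch_prob = 0.03)
  ph <- derive_phenotypes(co$prescriptions, co$labs)
  se <- sqrt(0.03 * 0.97 / nrow(ph))
  expect_lt(abs(mean(ph$switched) - 0.03), 3 * se)
})

test_that("schema violations are reported with row numbers", {
  fx <- tiny_ehr()
  rx_bad <- fx$prescriptions
  rx_bad$strength[3] <- -1
  expect_error(derive_phenotypes(rx_bad, fx$labs), "rows 3")
  labs_bad <- fx$labs
  labs_bad$hdl_cholesterol[2] <- 99
  expect_error(derive_phenotypes(fx$prescriptions, labs_bad), "rows 2")
})
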