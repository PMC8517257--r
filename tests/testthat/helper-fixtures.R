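# Shared fixtures built in code: a small default cohort and a hand-written
# four-patient EHR covering the phenotyping edge cases.

small_cohort <- function(n = 1500, seed = 101, ...) {
  simulate_cohort(sim_config(n_patients = n, seed = seed, ...))
}

# a config with no genetic/covariate structure: pure noise around the means
neutral_config <- function(n, seed, reduction_sd = 1.04, ...) {
  sim_config(
    n_patients = n, seed = seed,
    variant_specs = default_variant_specs()[0],
    interaction_effect = 0, adherence_effect = 0,
    baseline_effect = 0, t2d_effect = 0, mace_effect = 0,
    reduction_sd = reduction_sd, ...
  )
}

# deterministic four-patient EHR:
#  P1: clean responder, two labs, no switch;
#  P2: switcher (simva -> atorva before follow-up) with dose reduction;
#  P3: no baseline lab (excluded);
#  P4: follow-up lab only at day 27 (outside window, excluded)
tiny_ehr <- function() {
  d0 <- as.Date("2012-03-01")
  rx <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P2", "P3", "P4"),
    dispense_date = d0 + c(0, 28, 0, 28, 56, 0, 0),
    statin_type = c("simvastatin", "simvastatin",
                    "simvastatin", "atorvastatin", "atorvastatin",
                    "simvastatin", "simvastatin"),
    strength = c(20, 20, 40, 10, 5, 20, 20),
    quantity = c(28, 28, 28, 28, 28, 28, 28),
    directions = c(1, 1, 1, 1, 1, 1, 1)
  )
  labs <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P4", "P4"),
    date = c(d0 - 12, d0 + 60, d0 - 5, d0 + 70, d0 + 40, d0 - 3, d0 + 27),
    total_cholesterol = c(6.0, 4.4, 6.5, 5.0, 5.5, 6.1, 5.2),
    hdl_cholesterol = c(1.2, 1.1, 1.3, 1.2, 1.1, 1.2, 1.1)
  )
  list(prescriptions = rx, labs = labs, d0 = d0)
}
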