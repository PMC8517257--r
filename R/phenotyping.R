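# Phenotyping: derive per-patient statin-response outcome and statin-usage
# covariates from prescribing and laboratory tables.

#' Baseline non-HDL-C: nearest value before statin initiation
#'
#' Picks the lipid measurement with the latest date on or before the
#' initiation date. Same-day duplicate assays are averaged (order-independent
#' tie rule). There is no look-back limit by default; set
#' `max_lookback_days` to restrict how old a baseline may be.
#'
#' @param dates Measurement dates (`Date`).
#' @param values Non-HDL-C values (mmol/L), same length as `dates`.
#' @param initiation_date Date of the first statin prescription.
#' @param max_lookback_days Maximum age of the baseline in days (default
#'   unlimited).
#' @return `list(value =, offset_days =)` with `offset_days <= 0`, or `NULL`
#'   if no eligible measurement exists (the patient is excluded downstream).
#' @examples
#' d0 <- as.Date("2010-06-01")
#' derive_baseline(d0 + c(-40, -12, 30), c(5.1, 4.4, 3.0), d0)
#' @export
derive_baseline <- function(dates, values, initiation_date,
                            max_lookback_days = Inf) {
  stopifnot(length(dates) == length(values))
  off <- as.numeric(dates - initiation_date)
  ok <- !is.na(off) & off <= 0 & -off <= max_lookback_days & !is.na(values)
  if (!any(ok)) return(NULL)
  best <- max(off[ok])
  list(value = mean(values[ok & off == best]), offset_days = best)
}

#' Follow-up non-HDL-C: first measurement in the response window
#'
#' Picks the earliest measurement whose offset from initiation lies in the
#' closed window (28-180 days by default). Same-day duplicates are averaged.
#'
#' @inheritParams derive_baseline
#' @param window Closed `[lower, upper]` window in days after initiation.
#' @return `list(value =, offset_days =)` or `NULL` if no in-window
#'   measurement exists.
#' @examples
#' d0 <- as.Date("2010-06-01")
#' derive_followup(d0 + c(10, 30, 90), c(4.2, 3.1, 2.9), d0)
#' @export
derive_followup <- function(dates, values, initiation_date,
                            window = c(28, 180)) {
  stopifnot(length(dates) == length(values))
  off <- as.numeric(dates - initiation_date)
  ok <- !is.na(off) & off >= window[1] & off <= window[2] & !is.na(values)
  if (!any(ok)) return(NULL)
  best <- min(off[ok])
  list(value = mean(values[ok & off == best]), offset_days = best)
}

#' Absolute and percentage non-HDL-C response
#'
#' Response is baseline minus follow-up: positive values are reductions
#' (improvement). Percentage response is the absolute response over baseline.
#'
#' @param baseline,followup Non-HDL-C (mmol/L); `baseline` must be positive.
#' @return `list(absolute =, percent =)`, vectorised over inputs.
#' @examples
#' compute_response(4.43, 2.98) # 1.45 mmol/L, ~32.7%
#' @export
compute_response <- function(baseline, followup) {
  if (any(!is.na(baseline) & baseline <= 0)) {
    stop("baseline non-HDL-C must be positive", call. = FALSE)
  }
  absolute <- baseline - followup
  list(absolute = absolute, percent = 100 * absolute / baseline)
}

#' Statin switching before the follow-up measurement
#'
#' A patient is a switcher if more than one distinct statin type appears
#' among prescriptions dispensed on or before the follow-up measurement date.
#'
#' @param statin_types Character vector of statin types per prescription.
#' @param dispense_dates Dispense dates, same length.
#' @param followup_date Date of the follow-up non-HDL-C measurement.
#' @return Logical flag.
#' @export
detect_switching <- function(statin_types, dispense_dates, followup_date) {
  keep <- dispense_dates <= followup_date
  length(unique(statin_types[keep])) > 1L
}

#' Duration of therapy in 28-day pack periods
#'
#' Days from initiation to the follow-up measurement, divided by the 28-day
#' standard pack period.
#'
#' @param initiation_date,followup_date Dates.
#' @return Real number of 28-day periods.
#' @examples
#' duration_periods(as.Date("2010-01-01"), as.Date("2010-03-26")) # 3
#' @export
duration_periods <- function(initiation_date, followup_date) {
  as.numeric(followup_date - initiation_date) / 28
}

#' Simvastatin-equivalent daily dose
#'
#' Converts a daily dose of any supported statin to the simvastatin dose of
#' equal potency using the packaged (editable) equivalence table.
#'
#' @param statin_type Character vector of statin types.
#' @param daily_dose_mg Daily dose in mg (strength x tablets per day).
#' @param equivalence Named ratio vector, see [default_equivalence_table()].
#' @return Simvastatin-equivalent daily dose in mg.
#' @examples
#' sim_equiv_dose("atorvastatin", 10) # 20 under the default x2 ratio
#' @export
sim_equiv_dose <- function(statin_type, daily_dose_mg,
                           equivalence = default_equivalence_table()) {
  unknown <- setdiff(unique(statin_type), names(equivalence))
  if (length(unknown)) {
    stop("no equivalence ratio configured for: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  daily_dose_mg * unname(equivalence[statin_type])
}

#' Mean simvastatin-equivalent dose during follow-up
#'
#' Mean of the equivalent daily doses over all prescriptions dispensed on or
#' before the follow-up measurement.
#'
#' @param statin_types,strengths,directions Per-prescription vectors
#'   (strength in mg per tablet, directions in tablets per day).
#' @param dispense_dates Dispense dates.
#' @param followup_date Follow-up measurement date.
#' @inheritParams sim_equiv_dose
#' @return Mean dose in simvastatin-equivalent mg.
#' @export
mean_dose <- function(statin_types, strengths, directions, dispense_dates,
                      followup_date,
                      equivalence = default_equivalence_table()) {
  keep <- dispense_dates <= followup_date
  if (!any(keep)) return(NA_real_)
  mean(sim_equiv_dose(statin_types[keep],
                      strengths[keep] * directions[keep], equivalence))
}

#' Dose reduction / increase flags
#'
#' Flags whether any chronologically consecutive pair of
#' simvastatin-equivalent daily doses strictly decreases (reduction) or
#' strictly increases, among prescriptions on or before the follow-up
#' measurement. Equivalent-dose comparison means a statin switch at constant
#' potency is not a dose change. Both flags can be true.
#'
#' @inheritParams mean_dose
#' @return `list(dose_reduced =, dose_increased =)`.
#' @export
detect_dose_changes <- function(statin_types, strengths, directions,
                                dispense_dates, followup_date,
                                equivalence = default_equivalence_table()) {
  keep <- dispense_dates <= followup_date
  if (sum(keep) < 2L) {
    return(list(dose_reduced = FALSE, dose_increased = FALSE))
  }
  ord <- order(dispense_dates[keep])
  eq <- sim_equiv_dose(statin_types[keep][ord],
                       (strengths[keep] * directions[keep])[ord], equivalence)
  d <- diff(eq)
  list(dose_reduced = any(d < 0), dose_increased = any(d > 0))
}

#' Proportion of days covered (PDC) adherence surrogate
#'
#' Days of tablet supply (quantity / daily directions) summed over
#' prescriptions dispensed within `[first, last)` prescription dates, divided
#' by the days between the first and last prescription. The final
#' prescription's supply is excluded from the numerator because it covers
#' days after the denominator window ends; the ratio is left uncapped, so
#' values above 1 (stockpiling / early refills) are representable. A patient
#' with a single prescription before follow-up gets supply divided by days
#' from dispensing to the follow-up measurement, flagged as imputed.
#'
#' @param dispense_dates,quantities,directions Per-prescription vectors.
#' @param followup_date Optional: only prescriptions on or before this date
#'   are used; required for the single-prescription rule.
#' @return `list(pdc =, imputed =)`; `pdc` is `NA` when undefined.
#' @examples
#' d <- as.Date("2010-01-01") + c(0, 14, 28)
#' compute_pdc(d, c(28, 28, 28), c(1, 1, 1)) # 56/28 = 2: PDC > 1 is legal
#' @export
compute_pdc <- function(dispense_dates, quantities, directions,
                        followup_date = NULL) {
  stopifnot(length(dispense_dates) == length(quantities),
            length(quantities) == length(directions))
  if (!is.null(followup_date)) {
    keep <- dispense_dates <= followup_date
    dispense_dates <- dispense_dates[keep]
    quantities <- quantities[keep]
    directions <- directions[keep]
  }
  n <- length(dispense_dates)
  if (n == 0L) return(list(pdc = NA_real_, imputed = NA))
  supply <- quantities / directions
  if (n == 1L) {
    if (is.null(followup_date)) return(list(pdc = NA_real_, imputed = NA))
    span <- as.numeric(followup_date - dispense_dates)
    if (span <= 0) return(list(pdc = NA_real_, imputed = NA))
    return(list(pdc = supply / span, imputed = TRUE))
  }
  first <- min(dispense_dates)
  last <- max(dispense_dates)
  span <- as.numeric(last - first)
  if (span <= 0) return(list(pdc = NA_real_, imputed = NA))
  covered <- sum(supply[dispense_dates < last])
  list(pdc = covered / span, imputed = FALSE)
}

#' Derive the analysis-ready phenotype table
#'
#' Applies the full phenotyping contract to the prescribing and laboratory
#' tables: initiation date and first statin type, nearest-before baseline,
#' first in-window follow-up, absolute and percentage response, switching,
#' duration in 28-day periods, mean simvastatin-equivalent dose, dose-change
#' flags, and uncapped PDC. Patients lacking a baseline or an in-window
#' follow-up are excluded; the exclusion counts are attached as the
#' `"attrition"` attribute. The derivation is pure: identical input tables
#' give an identical phenotype table regardless of row order.
#'
#' @param prescriptions Table with `patient_id`, `dispense_date`,
#'   `statin_type`, `strength`, `quantity`, `directions`.
#' @param labs Table with `patient_id`, `date`, `total_cholesterol`,
#'   `hdl_cholesterol` (non-HDL-C is total minus HDL).
#' @param demographics Optional table with `patient_id` plus covariate
#'   columns (e.g. `sex`, `birth_year`, `t2d`, `mace`) merged onto the
#'   output.
#' @param equivalence Simvastatin-equivalence ratios.
#' @param window Follow-up window in days, closed interval.
#' @param max_lookback_days Baseline look-back limit (default unlimited).
#' @return `data.table` with one row per retained patient and attribute
#'   `"attrition"` (named integer vector of counts at each step).
#' @export
derive_phenotypes <- function(prescriptions, labs, demographics = NULL,
                              equivalence = default_equivalence_table(),
                              window = c(28, 180),
                              max_lookback_days = Inf) {
  rx <- validate_prescriptions(prescriptions)
  lb <- validate_labs(labs)

  ## initiation: first prescription; first statin type with deterministic
  ## tie-break (alphabetical within the initiation day)
  data.table::setorder(rx, patient_id, dispense_date, statin_type)
  init <- rx[, .(initiation_date = dispense_date[1L],
                 first_statin_type = statin_type[1L]), by = patient_id]

  ## non-HDL-C with same-day duplicate averaging
  lb[, non_hdl := total_cholesterol - hdl_cholesterol]
  lb <- lb[, .(non_hdl = mean(non_hdl)), by = .(patient_id, date)]
  lb <- lb[init, on = "patient_id", nomatch = NULL]
  lb[, offset_days := as.numeric(date - initiation_date)]

  base <- lb[offset_days <= 0 & -offset_days <= max_lookback_days]
  base <- base[base[, .I[which.max(offset_days)], by = patient_id]$V1,
               .(patient_id, baseline_nonhdl = non_hdl,
                 baseline_offset_days = offset_days)]
  fup <- lb[offset_days >= window[1] & offset_days <= window[2]]
  fup <- fup[fup[, .I[which.min(offset_days)], by = patient_id]$V1,
             .(patient_id, followup_nonhdl = non_hdl,
               followup_offset_days = offset_days)]

  ph <- merge(init, base, by = "patient_id")
  n_with_baseline <- nrow(ph)
  ph <- merge(ph, fup, by = "patient_id")
  attrition <- c(
    patients_with_prescriptions = nrow(init),
    with_baseline_lab = n_with_baseline,
    with_followup_lab = nrow(ph)
  )
  if (nrow(ph) == 0L) {
    stop("no patients remain after baseline/follow-up filtering",
         call. = FALSE)
  }
  ph[, absolute_reduction := baseline_nonhdl - followup_nonhdl]
  ph[, percent_reduction := 100 * absolute_reduction / baseline_nonhdl]
  ph[, duration_periods := followup_offset_days / 28]
  ph[, followup_date := initiation_date + followup_offset_days]

  ## statin-usage covariates from prescriptions on/before the follow-up lab
  rxw <- rx[ph[, .(patient_id, followup_date)], on = "patient_id",
            nomatch = NULL][dispense_date <= followup_date]
  rxw[, equiv_daily_dose := sim_equiv_dose(statin_type,
                                           strength * directions,
                                           equivalence)]
  rxw[, days_supply := quantity / directions]
  # integer day arithmetic: grouped Date subtraction is needlessly slow
  rxw[, `:=`(dday = as.integer(dispense_date),
             fday = as.integer(followup_date))]
  data.table::setorder(rxw, patient_id, dday, statin_type)
  usage <- rxw[, {
    last <- max(dday)
    first <- min(dday)
    span <- last - first
    d <- diff(equiv_daily_dose)
    list(
      switched = length(unique(statin_type)) > 1L,
      mean_sim_equiv_dose = mean(equiv_daily_dose),
      dose_reduced = any(d < 0),
      dose_increased = any(d > 0),
      pdc = if (.N >= 2L && span > 0)
              sum(days_supply[dday < last]) / span
            else if (fday[1L] > first)
              sum(days_supply) / (fday[1L] - first)
            else NA_real_,
      pdc_imputed = .N < 2L || span <= 0
    )
  }, by = patient_id]
  ph <- merge(ph, usage, by = "patient_id")
  ph[, followup_date := NULL]

  if (!is.null(demographics)) {
    demo <- data.table::as.data.table(demographics)
    ph <- merge(ph, demo, by = "patient_id", all.x = TRUE)
  }
  data.table::setorder(ph, patient_id)
  data.table::setattr(ph, "attrition", attrition)
  ph[]
}

# ---- schema validation ------------------------------------------------------

report_bad_rows <- function(what, bad) {
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    rows <- which(bad | is.na(bad))
    stop(what, " (rows ", paste(head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) ", ..." else "", ")", call. = FALSE)
  }
}

validate_prescriptions <- function(prescriptions) {
  rx <- data.table::as.data.table(prescriptions)
  req <- c("patient_id", "dispense_date", "statin_type", "strength",
           "quantity", "directions")
  miss <- setdiff(req, names(rx))
  if (length(miss)) stop("prescriptions table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!inherits(rx$dispense_date, "Date")) {
    rx[, dispense_date := as.Date(dispense_date)]
  }
  report_bad_rows("non-positive strength in prescriptions", rx$strength <= 0)
  report_bad_rows("quantity below 1 in prescriptions", rx$quantity < 1)
  report_bad_rows("non-positive directions in prescriptions",
                  rx$directions <= 0)
  rx
}

validate_labs <- function(labs) {
  lb <- data.table::as.data.table(labs)
  req <- c("patient_id", "date", "total_cholesterol", "hdl_cholesterol")
  miss <- setdiff(req, names(lb))
  if (length(miss)) stop("labs table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!inherits(lb$date, "Date")) lb[, date := as.Date(date)]
  report_bad_rows("negative HDL cholesterol in labs", lb$hdl_cholesterol < 0)
  report_bad_rows("total cholesterol below HDL in labs",
                  lb$total_cholesterol < lb$hdl_cholesterol)
  lb
}
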