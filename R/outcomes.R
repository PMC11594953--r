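#' Readmission composite event flag
#'
#' The study's headline outcome contrast uses a composite of unplanned
#' cardiovascular admissions (heart-failure admissions included) and
#' death over 12 months. Non-cardiovascular admissions and planned
#' procedures never trigger the flag.
#'
#' @param unplanned_cv_admissions,hf_admissions Non-negative admission
#'   counts.
#' @param died Logical (or 0/1) death indicator.
#' @param include_death Count death as a composite event (default); set
#'   `FALSE` for the stricter admissions-only definition.
#' @return Logical vector.
#' @export
readmission_flag <- function(unplanned_cv_admissions, hf_admissions, died,
                             include_death = TRUE) {
  counts <- cbind(unplanned_cv_admissions, hf_admissions)
  if (any(is.na(counts) | counts < 0)) stop("admission counts must be non-negative")
  flag <- unplanned_cv_admissions + hf_admissions > 0
  if (include_death) flag <- flag | as.logical(died)
  flag
}

#' Worsening renal function (WRF) under treatment
#'
#' WRF is a 25% reduction in eGFR or a rise in serum creatinine between
#' baseline and follow-up. The creatinine rise is quantified as >= 25%
#' by default, mirroring the eGFR criterion; both fractions are
#' configurable. The rule is invariant to measurement units provided
#' both timepoints share them.
#'
#' @param egfr_baseline,egfr_followup eGFR at the two timepoints
#'   (e.g. mL/min); baselines must be positive.
#' @param scr_baseline,scr_followup Serum creatinine at the two
#'   timepoints (e.g. umol/L); baselines must be positive.
#' @param egfr_drop Fractional eGFR reduction defining WRF.
#' @param scr_rise Fractional creatinine rise defining WRF.
#' @return Logical vector.
#' @examples
#' classify_wrf(60, 45, 90, 90) # TRUE: eGFR fell 25%
#' @export
classify_wrf <- function(egfr_baseline, egfr_followup,
                         scr_baseline, scr_followup,
                         egfr_drop = 0.25, scr_rise = 0.25) {
  if (any(is.na(egfr_baseline) | egfr_baseline <= 0) ||
      any(is.na(scr_baseline) | scr_baseline <= 0)) {
    stop("baseline eGFR and creatinine must be positive")
  }
  egfr_followup <= (1 - egfr_drop) * egfr_baseline |
    scr_followup >= (1 + scr_rise) * scr_baseline
}

#' Failure-to-attend (FTA) flag
#'
#' A patient fails to attend when strictly more than `threshold`
#' (default 25%) of pre-booked appointments are missed. Undefined (NA)
#' when nothing was booked.
#'
#' @param booked,attended Appointment counts, `attended <= booked`.
#' @param threshold Missed-appointment fraction that must be exceeded.
#' @return Logical vector, NA where `booked == 0`.
#' @examples
#' fta_flag(4, 3) # FALSE: exactly 25% missed
#' fta_flag(4, 2) # TRUE
#' @export
fta_flag <- function(booked, attended, threshold = 0.25) {
  if (any(is.na(booked) | is.na(attended) | booked < 0 | attended < 0)) {
    stop("appointment counts must be non-negative")
  }
  if (any(attended > booked)) stop("attended cannot exceed booked appointments")
  out <- (booked - attended) / booked > threshold
  out[booked == 0] <- NA
  out
}

# admission bands used in the outcome summary; partition of 0,1,2,...
ADMISSION_BANDS <- c("0", "1", "2-4", ">=5")

admission_band <- function(total_admissions) {
  cut(total_admissions, breaks = c(-Inf, 0, 1, 4, Inf),
      labels = ADMISSION_BANDS, right = TRUE)
}

#' 12-month outcome summary by short-form category
#'
#' Tabulates, per short-form self-management category: patient counts,
#' composite readmission events, deaths, losses to follow-up, the
#' failure-to-attend rate, side-effect counts, and admission-count bands
#' (0 / 1 / 2--4 / >= 5 total unplanned admissions, a partition of the
#' cohort).
#'
#' @param cohort Cohort data frame ([generate_cohort()], [read_cohort()]).
#' @param sf_source Use the nurse-scored short form (`"nurse"`, columns
#'   `sf_ma`/`sf_mx`/`sf_mse`) or the long-form-derived equivalent
#'   (`"derived"`, recomputed from the PIH items).
#' @param include_death Passed to [readmission_flag()].
#' @return A `mace_summary`: per-category table plus band counts.
#' @export
mace_summary <- function(cohort, sf_source = c("nurse", "derived"),
                         include_death = TRUE) {
  sf_source <- match.arg(sf_source)
  if (!is.data.frame(cohort) || nrow(cohort) == 0) stop("empty cohort")
  cat <- cohort_sf_category(cohort, sf_source)
  event <- readmission_flag(cohort$unplanned_cv_admissions, cohort$hf_admissions,
                            cohort$died, include_death = include_death)
  total_adm <- cohort$unplanned_cv_admissions + cohort$hf_admissions +
    cohort$non_cv_admissions
  fta <- fta_flag(cohort$booked_appointments, cohort$attended_appointments)
  side_effect <- as.logical(cohort$dose_reduced) | as.logical(cohort$ceased) |
    classify_wrf(cohort$egfr_baseline, cohort$egfr_followup,
                 cohort$scr_baseline, cohort$scr_followup)
  per_cat <- data.frame(
    category = SM_LEVELS,
    n = as.integer(table(cat)),
    readmission_events = as.integer(tapply(event, cat, sum)),
    deaths = as.integer(tapply(as.logical(cohort$died), cat, sum)),
    ltfu = as.integer(tapply(as.logical(cohort$ltfu), cat, sum)),
    side_effects = as.integer(tapply(side_effect, cat, sum)),
    fta_rate = as.numeric(tapply(fta, cat, function(x) mean(x, na.rm = TRUE)))
  )
  per_cat$readmission_rate <- ifelse(per_cat$n > 0,
                                     per_cat$readmission_events / per_cat$n, NA)
  bands <- table(category = cat, band = admission_band(total_adm))
  structure(
    list(per_category = per_cat,
         admission_bands = matrix(as.integer(bands), 4,
                                  length(ADMISSION_BANDS),
                                  dimnames = list(category = SM_LEVELS,
                                                  band = ADMISSION_BANDS)),
         n = nrow(cohort), sf_source = sf_source),
    class = "mace_summary"
  )
}

#' @export
print.mace_summary <- function(x, ...) {
  cat(sprintf("12-month outcomes by short-form category (%s scores, n = %d)\n",
              x$sf_source, x$n))
  print(x$per_category, row.names = FALSE, digits = 3)
  cat("\nAdmission-count bands:\n")
  print(x$admission_bands)
  invisible(x)
}

# resolve the per-patient SF category from a cohort, nurse-scored or
# recomputed from the PIH items
cohort_sf_category <- function(cohort, sf_source = c("nurse", "derived")) {
  sf_source <- match.arg(sf_source)
  if (sf_source == "nurse") {
    sf_total(cohort)
  } else {
    sf_total(lf_to_sf_equivalent(score_pih(cohort)))
  }
}
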