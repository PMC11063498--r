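# Domain containers: annotated decelerations, labor cases, blood-gas panels.
#
# Cohorts are plain tibbles so the usual data-frame tooling applies:
# one events table (one row per annotated deceleration) and one cases table
# (one row per labor, with timeline marks, covariates and neonatal outcomes).

#' Construct an annotated deceleration-event table
#'
#' One row per deceleration observed on the cardiotocogram. Times are seconds
#' from recording start; intervals are half-open `(start, end]`. Only
#' decelerations are represented — accelerations and baseline segments carry
#' no score and are not events.
#'
#' @param case_id Character; case the event belongs to.
#' @param onset_s Onset, seconds from recording start (non-negative).
#' @param duration_s Duration in seconds (> 0). Prolonged decelerations must
#'   last at least 120 s; those of 600 s or more are flagged at validation as
#'   baseline changes and are excluded from scoring.
#' @param decel_type One of `"early"`, `"late"`, `"variable"`, `"prolonged"`.
#' @param severity One of `"mild"`, `"severe"`.
#' @param baseline_rate Baseline heart-rate category: `"bradycardia"`,
#'   `"normal"`, `"tachycardia"`.
#' @param variability Baseline variability category: `"absent"`, `"minimal"`,
#'   `"moderate"`, `"marked"`.
#' @param level_override Optional clinician-annotated five-tier level (1--5);
#'   takes precedence over the table lookup in [classify_level()].
#' @param level Optional pre-assigned five-tier level (1--5).
#' @return A validated tibble of class `ipreface_events`.
#' @export
deceleration_events <- function(case_id, onset_s, duration_s, decel_type,
                                severity, baseline_rate, variability,
                                level_override = NA_integer_,
                                level = NA_integer_) {
  ev <- tibble::tibble(
    case_id = as.character(case_id),
    onset_s = as.numeric(onset_s),
    duration_s = as.numeric(duration_s),
    decel_type = as.character(decel_type),
    severity = as.character(severity),
    baseline_rate = as.character(baseline_rate),
    variability = as.character(variability),
    level_override = as.integer(level_override),
    level = as.integer(level)
  )
  validate_events(ev)
}

#' Validate a deceleration-event table
#'
#' Enforces the event invariants: positive durations, known categorical axis
#' values, prolonged decelerations of at least 120 s, and any assigned level
#' within 1..5. Prolonged events lasting 600 s or more are retained but
#' trigger a warning: a fall of that length is treated as a baseline change,
#' and scoring excludes it.
#'
#' @param events An events tibble.
#' @return The validated tibble (classed `ipreface_events`), invisibly
#'   usable in pipelines.
#' @export
validate_events <- function(events) {
  events <- tibble::as_tibble(events)
  req <- c("case_id", "onset_s", "duration_s", "decel_type", "severity",
           "baseline_rate", "variability")
  miss <- setdiff(req, names(events))
  if (length(miss))
    ipreface_stop("events", paste("events table is missing column(s):",
                                  paste(miss, collapse = ", ")))
  if (!"level_override" %in% names(events))
    events$level_override <- NA_integer_
  if (!"level" %in% names(events)) events$level <- NA_integer_
  if (nrow(events)) {
    if (any(!is.finite(events$onset_s) | events$onset_s < 0))
      ipreface_stop("events", "event onsets must be finite and non-negative")
    if (any(!is.finite(events$duration_s) | events$duration_s <= 0))
      ipreface_stop("events", "event durations must be positive")
    chk <- function(col, allowed) {
      bad <- which(!events[[col]] %in% allowed & !is.na(events[[col]]))
      if (length(bad))
        ipreface_stop("events", sprintf("event %d has unknown %s `%s`",
                                        bad[1L], col, events[[col]][bad[1L]]))
    }
    chk("decel_type", setdiff(.decel_levels, "none"))
    chk("severity", .severity_levels)
    chk("baseline_rate", .baseline_levels)
    chk("variability", .variability_levels)
    prolonged <- events$decel_type == "prolonged"
    if (any(prolonged & events$duration_s < 120))
      ipreface_stop("events",
                    "prolonged decelerations must last at least 120 s")
    if (any(prolonged & events$duration_s >= 600))
      ipreface_warn("events", paste(
        "prolonged deceleration(s) of >= 600 s present;",
        "treated as baseline change and excluded from scoring"))
    for (col in c("level", "level_override")) {
      v <- events[[col]]
      if (any(!is.na(v) & !(v %in% 1:5)))
        ipreface_stop("events", paste(col, "values must lie in 1..5"))
    }
  }
  class(events) <- unique(c("ipreface_events", class(events)))
  events
}

#' Construct a labor-case table
#'
#' One row per labor: recording bounds, the decision-of-cesarean and
#' transducer-removal time marks, delivery time, maternal covariates, and
#' neonatal outcomes including the umbilical-artery blood-gas panel. All
#' times are seconds from recording start.
#'
#' @param case_id Character identifiers.
#' @param recording_start_s,recording_end_s CTG recording bounds (s).
#' @param decision_time_s Time of the decision for emergency cesarean (s).
#' @param removal_time_s Time of CTG transducer removal (s).
#' @param delivery_time_s Time of delivery (s).
#' @param maternal_age Years.
#' @param parity Prior deliveries (integer).
#' @param gestational_week Completed weeks (numeric, e.g. 40.3).
#' @param induction,vacuum Logical flags: induced labor, vacuum attempt.
#' @param ph,pco2,po2,hco3,be,lactate Umbilical-artery blood-gas panel:
#'   pH (unitless), PCO2 and PO2 (mm Hg), bicarbonate (mmol/L), base excess
#'   (mEq/L), lactate (mmol/L).
#' @param apgar1,apgar5 Apgar scores at 1 and 5 minutes (0--10).
#' @param nicu_asphyxia Logical; NICU admission for neonatal asphyxia.
#' @param coverage_gaps Optional list of 2-column matrices (one per case) of
#'   `(start, end)` intervals where the CTG signal was not interpretable.
#' @return A validated tibble of class `ipreface_cases`.
#' @export
labor_cases <- function(case_id, recording_start_s, recording_end_s,
                        decision_time_s, removal_time_s, delivery_time_s,
                        maternal_age = NA_real_, parity = NA_integer_,
                        gestational_week = NA_real_, induction = NA,
                        vacuum = NA, ph = NA_real_, pco2 = NA_real_,
                        po2 = NA_real_, hco3 = NA_real_, be = NA_real_,
                        lactate = NA_real_, apgar1 = NA_integer_,
                        apgar5 = NA_integer_, nicu_asphyxia = NA,
                        coverage_gaps = NULL) {
  n <- length(case_id)
  cases <- tibble::tibble(
    case_id = as.character(case_id),
    recording_start_s = as.numeric(recording_start_s),
    recording_end_s = as.numeric(recording_end_s),
    decision_time_s = as.numeric(decision_time_s),
    removal_time_s = as.numeric(removal_time_s),
    delivery_time_s = as.numeric(delivery_time_s),
    maternal_age = as.numeric(maternal_age),
    parity = as.integer(parity),
    gestational_week = as.numeric(gestational_week),
    induction = as.logical(induction),
    vacuum = as.logical(vacuum),
    ph = as.numeric(ph),
    pco2 = as.numeric(pco2),
    po2 = as.numeric(po2),
    hco3 = as.numeric(hco3),
    be = as.numeric(be),
    lactate = as.numeric(lactate),
    apgar1 = as.integer(apgar1),
    apgar5 = as.integer(apgar5),
    nicu_asphyxia = as.logical(nicu_asphyxia)
  )
  if (!is.null(coverage_gaps)) {
    stopifnot(length(coverage_gaps) == n)
    cases$coverage_gaps <- coverage_gaps
  }
  validate_cases(cases)
}

#' Validate a labor-case table
#'
#' Enforces the timeline invariant
#' `recording_start <= decision <= removal <= delivery`, blood-gas ranges
#' (pH within 6.5--7.6, positive PCO2 and bicarbonate where present), and,
#' when an events table is supplied, that every event onset lies within the
#' case's recording bounds.
#'
#' @param cases A cases tibble.
#' @param events Optional events tibble checked against the case timelines.
#' @return The validated cases tibble (classed `ipreface_cases`).
#' @export
validate_cases <- function(cases, events = NULL) {
  cases <- tibble::as_tibble(cases)
  req <- c("case_id", "recording_start_s", "recording_end_s",
           "decision_time_s", "removal_time_s", "delivery_time_s")
  miss <- setdiff(req, names(cases))
  if (length(miss))
    ipreface_stop("events", paste("cases table is missing column(s):",
                                  paste(miss, collapse = ", ")))
  if (anyDuplicated(cases$case_id))
    ipreface_stop("events", "case_id values must be unique")
  bad <- which(!(cases$recording_start_s <= cases$decision_time_s &
                   cases$decision_time_s <= cases$removal_time_s &
                   cases$removal_time_s <= cases$delivery_time_s))
  if (length(bad))
    ipreface_stop("events", sprintf(
      "case `%s` violates recording_start <= decision <= removal <= delivery",
      cases$case_id[bad[1L]]))
  bad <- which(cases$recording_end_s < cases$recording_start_s)
  if (length(bad))
    ipreface_stop("events", sprintf("case `%s` has recording_end < start",
                                    cases$case_id[bad[1L]]))
  if ("ph" %in% names(cases)) {
    ph <- cases$ph
    if (any(!is.na(ph) & (ph < 6.5 | ph > 7.6)))
      ipreface_stop("events", "pH outside the plausible 6.5..7.6 range")
  }
  for (col in c("pco2", "hco3")) {
    if (col %in% names(cases)) {
      v <- cases[[col]]
      if (any(!is.na(v) & v <= 0))
        ipreface_stop("events", paste(col, "must be positive"))
    }
  }
  if (!is.null(events) && nrow(events)) {
    idx <- match(events$case_id, cases$case_id)
    if (anyNA(idx))
      ipreface_stop("events", paste("event references unknown case:",
                                    events$case_id[is.na(idx)][1L]))
    lo <- cases$recording_start_s[idx]
    hi <- cases$recording_end_s[idx]
    bad <- which(events$onset_s < lo | events$onset_s > hi)
    if (length(bad))
      ipreface_stop("events", sprintf(
        "event onset outside recording bounds for case `%s`",
        events$case_id[bad[1L]]))
  }
  class(cases) <- unique(c("ipreface_cases", class(cases)))
  cases
}

#' Fetal acidemia predicate
#'
#' Fetal acidemia is defined as an umbilical-artery blood pH below 7.2;
#' the stricter secondary thresholds 7.1 and 7.0 grade its severity.
#'
#' @param ph Numeric vector of umbilical-artery pH values.
#' @param threshold Acidemia threshold, 7.2 by default.
#' @return Logical vector, `TRUE` where `ph < threshold`.
#' @export
is_acidemic <- function(ph, threshold = 7.2) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 6.5 || threshold >= 7.6)
    ipreface_stop("events", "acidemia threshold must lie in (6.5, 7.6)")
  ph < threshold
}
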