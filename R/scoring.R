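# The iPREFACE score.
#
# Over a 30-minute CTG window the score sums the five-tier levels of all
# non-prolonged decelerations, and adds level x duration (rounded to the
# nearest whole minute) for prolonged decelerations. Two anchored variants:
# DCS — window ends at the decision for emergency cesarean; RCT — window
# ends at transducer removal.

#' Build a scoring window for a labor case
#'
#' Returns the half-open window `(end - length, end]` ending at the case's
#' decision-of-cesarean time (`DCS`) or transducer-removal time (`RCT`),
#' together with the fraction of the window covered by interpretable signal
#' (from the case's `coverage_gaps`). A window that starts before the
#' recording does is a coverage error — the corresponding study exclusion is
#' a tracing that could not be measured continuously for the full 30 minutes.
#'
#' @param case A single labor case: one-row cases tibble (or list with the
#'   same fields).
#' @param variant `"DCS"`, `"RCT"`, or `"custom"` (with `end_time` supplied).
#' @param length Window length in seconds; 1800 (30 min) by default.
#' @param end_time Window end for `variant = "custom"`, seconds.
#' @return A list of class `ipreface_window` with `start`, `end_time`,
#'   `length`, `variant`, `coverage_fraction`.
#' @export
#' @examples
#' case <- labor_cases("a", 0, 7000, 5400, 6000, 7000)
#' make_window(case, "DCS")
make_window <- function(case, variant = c("DCS", "RCT", "custom"),
                        length = 1800, end_time = NULL) {
  variant <- match.arg(variant)
  assert_scalar_number(length, "length", "scoring")
  if (length <= 0) ipreface_stop("scoring", "window length must be positive")
  if (is.data.frame(case)) {
    if (nrow(case) != 1L)
      ipreface_stop("scoring", "make_window expects a single case")
    case <- as.list(case)
  }
  end <- switch(variant,
    DCS = case$decision_time_s,
    RCT = case$removal_time_s,
    custom = end_time %||% ipreface_stop(
      "scoring", "custom windows need `end_time`"))
  assert_scalar_number(end, "end_time", "scoring")
  start <- end - length
  rec_start <- case$recording_start_s %||% 0
  if (start < rec_start)
    ipreface_stop("scoring", sprintf(
      paste("window (%g, %g] starts before the recording (%g);",
            "the tracing does not cover the full window"),
      start, end, rec_start))
  gaps <- case$coverage_gaps
  if (is.list(gaps) && length(gaps) == 1L && !is.matrix(gaps)) {
    gaps <- gaps[[1L]]
  }
  gap_s <- interval_overlap(start, end, gaps)
  structure(list(
    start = start, end_time = end, length = length, variant = variant,
    coverage_fraction = (length - gap_s) / length
  ), class = "ipreface_window")
}

# In-window contribution of each event: non-prolonged decelerations count
# their level when their nadir (onset + duration/2 unless a nadir_s column is
# annotated) lies in (start, end]; prolonged decelerations contribute
# level x (in-window overlap rounded half-up to whole minutes). Prolonged
# events of >= 600 s are baseline changes, excluded.
event_contributions <- function(events, start, end) {
  n <- nrow(events)
  contrib <- numeric(n)
  scored <- logical(n)
  excluded <- logical(n)
  if (!n) return(list(contribution = contrib, scored = scored,
                      excluded = excluded))
  prolonged <- events$decel_type == "prolonged"
  too_long <- prolonged & events$duration_s >= 600
  nadir <- if ("nadir_s" %in% names(events) && any(!is.na(events$nadir_s))) {
    ifelse(is.na(events$nadir_s),
           events$onset_s + events$duration_s / 2, events$nadir_s)
  } else events$onset_s + events$duration_s / 2
  in_win <- !prolonged & nadir > start & nadir <= end
  ov <- pmax(0, pmin(events$onset_s + events$duration_s, end) -
               pmax(events$onset_s, start))
  pro_win <- prolonged & !too_long & ov > 0
  hit <- in_win | pro_win
  if (any(hit & is.na(events$level)))
    ipreface_stop("scoring", sprintf(
      "event %d lies in the window but has no five-tier level assigned",
      which(hit & is.na(events$level))[1L]))
  contrib[in_win] <- events$level[in_win]
  contrib[pro_win] <- events$level[pro_win] * round_half_up(ov[pro_win] / 60)
  scored[hit] <- TRUE
  excluded <- too_long & ov > 0
  list(contribution = contrib, scored = scored, excluded = excluded)
}

#' Score a window of deceleration events
#'
#' Computes the iPREFACE score of a window: the sum over non-prolonged
#' decelerations in the window of their five-tier level, plus, for each
#' prolonged deceleration, its level times its in-window duration rounded
#' half-up to the nearest whole minute (an overlap under 30 s rounds to zero
#' and contributes nothing). A non-prolonged deceleration belongs to the
#' window when its nadir does; a prolonged deceleration contributes only its
#' overlap, so adjacent windows never double-count it. Prolonged events of
#' 600 s or more are treated as baseline changes and excluded (with a
#' warning when they touch the window).
#'
#' @param events Events tibble for one case, with `level` assigned (see
#'   [classify_level()]).
#' @param window An `ipreface_window` from [make_window()].
#' @param strict_coverage If `TRUE` (default), a window with
#'   `coverage_fraction < 1` is an error, mirroring the study's exclusion of
#'   incompletely recorded tracings; set `FALSE` for exploratory use (a
#'   warning is logged instead).
#' @return A list of class `ipreface_score` with the `window`, per-event
#'   `contributions`, integer `total`, `n_events_scored`,
#'   `n_events_excluded`.
#' @export
#' @examples
#' ev <- deceleration_events("a", c(4000, 4400), c(60, 60), "variable",
#'                           "severe", "normal", "minimal")
#' ev <- classify_level(ev)
#' w <- make_window(labor_cases("a", 0, 7000, 5400, 6000, 7000), "DCS")
#' score_window(ev, w)$total
score_window <- function(events, window, strict_coverage = TRUE) {
  if (!inherits(window, "ipreface_window"))
    ipreface_stop("scoring", "`window` must come from make_window()")
  if (window$coverage_fraction < 1) {
    if (strict_coverage)
      ipreface_stop("scoring", sprintf(
        "window coverage %.3f < 1 with strict_coverage = TRUE",
        window$coverage_fraction))
    ipreface_warn("scoring", sprintf(
      "scoring a window with coverage %.3f", window$coverage_fraction))
  }
  events <- tibble::as_tibble(events)
  if (!"level" %in% names(events)) events$level <- NA_integer_
  cc <- event_contributions(events, window$start, window$end_time)
  if (any(cc$excluded))
    ipreface_warn("scoring", sprintf(
      "%d prolonged event(s) of >= 600 s excluded from the window",
      sum(cc$excluded)))
  contributions <- tibble::tibble(
    event = which(cc$scored),
    onset_s = events$onset_s[cc$scored],
    decel_type = events$decel_type[cc$scored],
    level = events$level[cc$scored],
    contribution = as.integer(cc$contribution[cc$scored])
  )
  structure(list(
    window = window,
    contributions = contributions,
    total = as.integer(sum(cc$contribution)),
    n_events_scored = sum(cc$scored),
    n_events_excluded = sum(cc$excluded)
  ), class = "ipreface_score")
}

#' Sliding iPREFACE score trajectory
#'
#' Scores a sliding window of fixed length at every `step` seconds, from the
#' earliest window fully inside the recording up to `variant_end`, so the
#' score's build-up over labor can be inspected. The last point, at
#' `variant_end`, equals the corresponding fixed-anchor score.
#'
#' @param case A single labor case (one-row tibble or list).
#' @param events Events tibble for that case with levels assigned.
#' @param variant_end Window end of the last trajectory point (s), e.g. the
#'   removal time.
#' @param step Spacing between window ends (s), > 0.
#' @param length Window length (s), default 1800.
#' @param strict_coverage Passed to [score_window()].
#' @return A tibble with `end_time_s` and `score`.
#' @export
score_trajectory <- function(case, events, variant_end, step = 60,
                             length = 1800, strict_coverage = TRUE) {
  assert_scalar_number(step, "step", "scoring")
  if (step <= 0) ipreface_stop("scoring", "`step` must be positive")
  if (is.data.frame(case)) case <- as.list(case)
  rec_start <- case$recording_start_s %||% 0
  ends <- rev(seq(variant_end, rec_start + length, by = -step))
  if (!length(ends))
    ipreface_stop("scoring", "no fully covered window before `variant_end`")
  totals <- vapply(ends, function(e) {
    w <- make_window(case, "custom", length = length, end_time = e)
    score_window(events, w, strict_coverage = strict_coverage)$total
  }, numeric(1))
  tibble::tibble(end_time_s = ends, score = totals)
}

#' Score every case of a cohort
#'
#' Applies [make_window()] + [score_window()] per case for the requested
#' variant(s) and returns the flat scores table used by the evaluation
#' module.
#'
#' @param cases Cases tibble.
#' @param events Events tibble with levels assigned (rows matched to cases
#'   by `case_id`).
#' @param variant `"DCS"`, `"RCT"`, or `"both"`.
#' @param length Window length (s).
#' @param strict_coverage Passed to [score_window()].
#' @param on_coverage_error `"error"` (default) to fail on a case whose
#'   window is not fully recorded, or `"drop"` to exclude such cases with a
#'   warning, as the study did.
#' @return A tibble with `case_id`, `variant`, `window_end_s`,
#'   `coverage_fraction`, `score`.
#' @export
score_cases <- function(cases, events, variant = c("both", "DCS", "RCT"),
                        length = 1800, strict_coverage = TRUE,
                        on_coverage_error = c("error", "drop")) {
  variant <- match.arg(variant)
  on_coverage_error <- match.arg(on_coverage_error)
  variants <- if (variant == "both") c("DCS", "RCT") else variant
  if (!"level" %in% names(events))
    ipreface_stop("scoring", "events need a `level` column; run classify_level()")
  out <- list()
  for (v in variants) for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    ev <- events[events$case_id == case$case_id, , drop = FALSE]
    res <- tryCatch({
      w <- make_window(case, v, length = length)
      s <- score_window(ev, w, strict_coverage = strict_coverage)
      data.frame(case_id = case$case_id, variant = v,
                 window_end_s = w$end_time,
                 coverage_fraction = w$coverage_fraction,
                 score = s$total, stringsAsFactors = FALSE)
    }, ipreface_scoring_error = function(e) {
      if (on_coverage_error == "error") stop(e)
      ipreface_warn("scoring", sprintf(
        "dropping case `%s` (%s): %s", case$case_id, v, conditionMessage(e)))
      NULL
    })
    out[[length(out) + 1L]] <- res
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(tibble::tibble(case_id = character(), variant = character(),
                          window_end_s = numeric(),
                          coverage_fraction = numeric(), score = integer()))
  tibble::as_tibble(out)
}

#' @export
print.ipreface_score <- function(x, ...) {
  cat(sprintf(
    "iPREFACE score (%s window (%g, %g]): total %d (%d scored, %d excluded)\n",
    x$window$variant, x$window$start, x$window$end_time, x$total,
    x$n_events_scored, x$n_events_excluded))
  invisible(x)
}

#' @export
print.ipreface_window <- function(x, ...) {
  cat(sprintf("%s window (%g, %g], coverage %.3f\n",
              x$variant, x$start, x$end_time, x$coverage_fraction))
  invisible(x)
}
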