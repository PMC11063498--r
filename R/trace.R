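# Signal-level round trip: render an annotated case as a 4 Hz FHR/UC trace,
# and detect decelerations back from such a trace. Detection follows the
# standard criteria: a fall of at least 15 bpm below the running baseline
# sustained for at least 15 s; prolonged when lasting 2 minutes or more;
# late vs variable by the lag of the nadir behind the nearest contraction
# peak and by the abruptness of descent.

#' Render a case as FHR and uterine-activity signals
#'
#' Produces a deterministic (given `seed`) cardiotocogram: a baseline with
#' configurable short-term variability, one trapezoidal dip per annotated
#' deceleration (depth 25 bpm for mild, 45 bpm for severe; descent ramp 5 s
#' for variable, 20 s for early/late, 25 s for prolonged events), and a
#' uterine-activity channel with one contraction per deceleration (peaking
#' 30 s before the nadir for late decelerations, at the nadir otherwise)
#' plus background contractions every 200 s.
#'
#' @param events Events tibble for one case.
#' @param duration_s Length of the rendered record in seconds.
#' @param sampling_rate Samples per second, default 4 (the common CTG
#'   convention).
#' @param baseline_bpm Baseline fetal heart rate, default 140.
#' @param variability_amp_bpm Bandwidth of baseline variability in bpm
#'   (about 6 for moderate variability; small values emulate a quiet trace).
#' @param seed Seed for the variability noise.
#' @return A list of class `ipreface_trace` with `t`, `fhr`, `uc`,
#'   `sampling_rate`.
#' @export
render_trace <- function(events, duration_s, sampling_rate = 4,
                         baseline_bpm = 140, variability_amp_bpm = 6,
                         seed = 1L) {
  n <- floor(duration_s * sampling_rate) + 1L
  t <- (seq_len(n) - 1L) / sampling_rate
  set.seed(as.integer(seed))
  raw <- stats::rnorm(n)
  k <- max(3L, 2L * floor(sampling_rate) + 1L)  # ~2 s smoothing
  kern <- stats::dnorm(seq(-3, 3, length.out = k))
  kern <- kern / sum(kern)
  wig <- stats::filter(raw, kern, sides = 2)
  wig[is.na(wig)] <- 0
  wig <- as.numeric(wig)
  if (stats::sd(wig) > 0)
    wig <- wig / stats::sd(wig) * variability_amp_bpm / 4
  fhr <- baseline_bpm + wig
  uc <- rep(10, n)
  events <- tibble::as_tibble(events)
  if (nrow(events)) {
    ov <- outer(events$onset_s, events$onset_s, \(a, b) abs(a - b))
    diag(ov) <- Inf
    if (any(ov < 30))
      ipreface_warn("synthetic",
                    "overlapping decelerations; rendered dips superimpose")
  }
  nadirs <- numeric(0)
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]; du <- events$duration_s[i]
    type <- events$decel_type[i]
    depth <- if (events$severity[i] == "severe") 45 else 25
    ramp <- switch(type, variable = 5, prolonged = 25, 20)
    ramp <- min(ramp, du / 3)
    rel <- t - on
    shape <- pmin(1, pmax(0, rel / ramp, 0)) * pmin(1, pmax(0, (du - rel) / ramp))
    shape[rel < 0 | rel > du] <- 0
    fhr <- fhr - depth * shape
    nadir <- on + du / 2
    nadirs <- c(nadirs, nadir)
    peak_t <- if (type == "late") nadir - 30 else nadir
    uc <- uc + 50 * exp(-((t - peak_t)^2) / (2 * 15^2))
  }
  bg <- seq(100, duration_s - 100, by = 200)
  for (pk in bg) {
    if (length(nadirs) && min(abs(nadirs - pk)) < 80) next
    uc <- uc + 50 * exp(-((t - pk)^2) / (2 * 15^2))
  }
  structure(list(t = t, fhr = fhr, uc = uc, sampling_rate = sampling_rate),
            class = "ipreface_trace")
}

# Local maxima of the UC channel above half its dynamic range, at least
# 60 s apart.
uc_peaks <- function(uc, sampling_rate) {
  thr <- min(uc) + 0.5 * (max(uc) - min(uc))
  if (max(uc) - min(uc) < 5) return(numeric(0))
  above <- uc > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- vapply(which(r$values), \(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(uc[seg])]
  }, integer(1))
  (idx - 1L) / sampling_rate
}

#' Detect decelerations in an FHR/UC trace
#'
#' Deterministic detector: the running-median baseline (10-minute window) is
#' subtracted, runs where the FHR stays at least `drop_bpm` below baseline
#' for `min_duration_s` or more are kept (gaps under 10 s merged), and each
#' run is extended outward to the 5 bpm deficit crossings. Events of 2
#' minutes or more are prolonged; otherwise the nadir lagging the nearest
#' contraction peak by more than `late_lag_s` marks a late deceleration, an
#' abrupt descent a variable one, and a gradual contraction-synchronous dip
#' an early one. Depth of 35 bpm or more is graded severe.
#'
#' @param fhr,uc Equal-length numeric signals.
#' @param sampling_rate Samples per second of both signals.
#' @param drop_bpm Detection depth threshold, default 15 bpm.
#' @param min_duration_s Minimum sustained duration, default 15 s.
#' @param late_lag_s Nadir-to-contraction-peak lag separating late from
#'   variable/early, default 15 s.
#' @param severe_depth_bpm Depth grading threshold, default 35 bpm.
#' @param case_id Identifier given to the detected events.
#' @return A validated events tibble sorted by onset, with inferred
#'   `decel_type`, `severity`, and baseline/variability context.
#' @export
detect_decelerations <- function(fhr, uc, sampling_rate = 4,
                                 drop_bpm = 15, min_duration_s = 15,
                                 late_lag_s = 15, severe_depth_bpm = 35,
                                 case_id = "trace") {
  if (length(fhr) != length(uc))
    ipreface_stop("synthetic", "FHR and UC signals differ in length")
  if (sampling_rate <= 0)
    ipreface_stop("synthetic", "sampling_rate must be positive")
  n <- length(fhr)
  k <- min(n - (1 - n %% 2L), 2L * floor(300 * sampling_rate) + 1L)
  baseline <- if (k >= 3) stats::runmed(fhr, k, endrule = "median") else fhr
  deficit <- baseline - fhr
  core <- deficit >= drop_bpm
  # merge gaps shorter than 10 s
  r <- rle(core)
  gap <- !r$values & r$lengths < 10 * sampling_rate
  gap[c(1L, length(gap))] <- FALSE
  r$values[gap] <- TRUE
  core <- inverse.rle(r)
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_duration_s * sampling_rate)
  if (!length(keep))
    return(validate_events(tibble::tibble(
      case_id = character(), onset_s = numeric(), duration_s = numeric(),
      decel_type = character(), severity = character(),
      baseline_rate = character(), variability = character(),
      level_override = integer(), level = integer())))
  peaks <- uc_peaks(uc, sampling_rate)
  med_base <- stats::median(baseline)
  base_cat <- if (med_base < 110) "bradycardia" else
    if (med_base > 160) "tachycardia" else "normal"
  in_event <- rep(FALSE, n)
  for (j in keep) in_event[starts[j]:ends[j]] <- TRUE
  resid_amp <- 4 * stats::sd((fhr - baseline)[!in_event])
  var_cat <- if (is.na(resid_amp) || resid_amp < 1) "absent" else
    if (resid_amp < 6) "minimal" else if (resid_amp <= 25) "moderate" else
      "marked"
  rows <- lapply(keep, function(j) {
    a <- starts[j]; b <- ends[j]
    while (a > 1L && deficit[a - 1L] >= 5) a <- a - 1L
    while (b < n && deficit[b + 1L] >= 5) b <- b + 1L
    onset <- (a - 1L) / sampling_rate
    dur <- (b - a + 1L) / sampling_rate
    seg <- a:b
    nadir_t <- (seg[which.max(deficit[seg])] - 1L) / sampling_rate
    depth <- max(deficit[seg])
    type <- if (dur >= 120) "prolonged" else {
      lag <- if (length(peaks)) nadir_t - peaks[which.min(abs(peaks - nadir_t))]
      else Inf
      if (is.finite(lag) && lag > late_lag_s) "late" else {
        slope_win <- max(1L, floor(2 * sampling_rate))
        d1 <- diff(deficit[seg], lag = slope_win) / (slope_win / sampling_rate)
        if (max(d1) >= 2.5) "variable" else "early"
      }
    }
    dur <- if (type == "prolonged") max(dur, 120) else min(dur, 119.9)
    tibble::tibble(
      case_id = case_id, onset_s = onset, duration_s = dur,
      decel_type = type,
      severity = if (depth >= severe_depth_bpm) "severe" else "mild",
      baseline_rate = base_cat, variability = var_cat,
      level_override = NA_integer_, level = NA_integer_)
  })
  out <- do.call(rbind, rows)
  validate_events(out[order(out$onset_s), ])
}
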