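# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# "Rounded to the nearest whole minute" uses half-up rounding, not banker's
# rounding, so 4.5 min -> 5 min.
round_half_up <- function(x) floor(x + 0.5)

# Total overlap of the half-open interval (start, end] with a set of
# (start, end) gap rows given as a 2-column matrix (may be NULL or 0-row).
interval_overlap <- function(start, end, intervals) {
  if (is.null(intervals) || length(intervals) == 0L) return(0)
  intervals <- matrix(as.numeric(intervals), ncol = 2L)
  lo <- pmax(intervals[, 1L], start)
  hi <- pmin(intervals[, 2L], end)
  sum(pmax(hi - lo, 0))
}

# Module-tagged conditions so pipeline callers can surface which stage failed.
ipreface_stop <- function(module, msg, call. = FALSE) {
  cond <- structure(
    class = c(paste0("ipreface_", module, "_error"), "ipreface_error",
              "error", "condition"),
    list(message = paste0("[", module, "] ", msg), call = NULL)
  )
  stop(cond)
}

ipreface_warn <- function(module, msg) {
  warning(paste0("[", module, "] ", msg), call. = FALSE)
}

assert_scalar_number <- function(x, name, module = "events") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ipreface_stop(module, sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
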