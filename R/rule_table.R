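# Five-tier fetal heart-rate level classification, shipped as data.
#
# The five-tier (JSOG) scheme assigns a tracing a risk level from 1 (normal)
# to 5 (severe abnormality) by integrating baseline rate, baseline
# variability, and the deceleration pattern. The level table is deliberately
# data, not code: users can load their own transcription of the chart and all
# downstream scoring is table-agnostic.

#' Categorical axes of the five-tier rule table
#'
#' @name five_tier_axes
#' @keywords internal
NULL

.baseline_levels    <- c("bradycardia", "normal", "tachycardia")
.variability_levels <- c("absent", "minimal", "moderate", "marked")
.decel_levels       <- c("none", "early", "variable", "late", "prolonged")
.severity_levels    <- c("mild", "severe")

#' Default five-tier level rule table
#'
#' Builds the level table used by [classify_level()] when no custom table is
#' supplied. Levels follow an additive transcription of the five-tier chart:
#' risk points for the deceleration pattern (early or mild variable +1,
#' severe variable, mild late or mild prolonged +2, severe late or severe
#' prolonged +3), for degraded variability (minimal or marked +1, absent +3),
#' and for an abnormal baseline (tachycardia +1, bradycardia +2), clamped to
#' the 1--5 range. The anchor cell (normal baseline, moderate variability,
#' no deceleration) is level 1, and the table is monotone both in
#' deceleration severity and in variability degradation.
#'
#' @return A tibble with columns `baseline_rate`, `variability`,
#'   `decel_type`, `severity`, `level`, carrying `table_id` and `version`
#'   attributes.
#' @export
#' @examples
#' tab <- default_rule_table()
#' subset(tab, baseline_rate == "normal" & variability == "moderate")
default_rule_table <- function() {
  grid <- expand.grid(
    baseline_rate = .baseline_levels,
    variability   = .variability_levels,
    decel_type    = .decel_levels,
    severity      = .severity_levels,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  decel_pts <- function(type, sev) {
    base <- c(none = 0, early = 1, variable = 1, late = 2, prolonged = 2)[type]
    bump <- ifelse(sev == "severe" & type %in% c("variable", "late", "prolonged"),
                   1, 0)
    base + bump
  }
  var_pts  <- c(absent = 3, minimal = 1, moderate = 0, marked = 1)
  base_pts <- c(bradycardia = 2, normal = 0, tachycardia = 1)
  pts <- decel_pts(grid$decel_type, grid$severity) +
    var_pts[grid$variability] + base_pts[grid$baseline_rate]
  grid$level <- as.integer(clamp(1 + pts, 1, 5))
  tab <- tibble::as_tibble(grid)
  attr(tab, "table_id") <- "five-tier-default"
  attr(tab, "version") <- "1.0"
  tab
}

#' Validate a five-tier rule table
#'
#' Checks completeness (every combination of the four categorical axes maps
#' to exactly one level), level range, the level-1 anchor for a normal
#' tracing, and the two monotonicity requirements (severe never scores below
#' mild; absent variability never scores below moderate, other axes fixed).
#'
#' @param table A rule table as returned by [default_rule_table()] or
#'   [read_rule_table()].
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending cell.
#' @export
validate_rule_table <- function(table) {
  needed <- c("baseline_rate", "variability", "decel_type", "severity", "level")
  if (!all(needed %in% names(table)))
    ipreface_stop("events", paste(
      "rule table is missing column(s):",
      paste(setdiff(needed, names(table)), collapse = ", ")))
  key <- paste(table$baseline_rate, table$variability, table$decel_type,
               table$severity, sep = "|")
  if (anyDuplicated(key))
    ipreface_stop("events", paste("duplicate rule-table key:",
                                  key[duplicated(key)][1L]))
  full <- expand.grid(.baseline_levels, .variability_levels, .decel_levels,
                      .severity_levels, stringsAsFactors = FALSE)
  full_key <- paste(full[[1L]], full[[2L]], full[[3L]], full[[4L]], sep = "|")
  missing <- setdiff(full_key, key)
  if (length(missing))
    ipreface_stop("events", paste("incomplete rule table; missing key:",
                                  missing[1L]))
  if (!all(table$level %in% 1:5))
    ipreface_stop("events", "rule-table levels must lie in 1..5")
  lvl <- function(b, v, d, s)
    table$level[table$baseline_rate == b & table$variability == v &
                  table$decel_type == d & table$severity == s]
  if (lvl("normal", "moderate", "none", "mild") != 1L)
    ipreface_stop("events",
                  "(normal, moderate, none) must map to level 1")
  for (b in .baseline_levels) for (v in .variability_levels)
    for (d in .decel_levels) {
      if (lvl(b, v, d, "severe") < lvl(b, v, d, "mild"))
        ipreface_stop("events", sprintf(
          "severity monotonicity violated at (%s, %s, %s)", b, v, d))
    }
  for (b in .baseline_levels) for (d in .decel_levels)
    for (s in .severity_levels) {
      if (lvl(b, "absent", d, s) < lvl(b, "moderate", d, s))
        ipreface_stop("events", sprintf(
          "variability monotonicity violated at (%s, %s, %s)", b, d, s))
    }
  invisible(table)
}

#' Read / write a rule table
#'
#' Rule tables are stored as versioned YAML (or JSON) with one record per
#' cell of the four categorical axes.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param table A validated rule table.
#' @return `read_rule_table()` returns a validated rule-table tibble;
#'   `write_rule_table()` returns `path` invisibly.
#' @export
read_rule_table <- function(path) {
  if (!file.exists(path))
    ipreface_stop("events", paste("rule-table file not found:", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- raw$entries
  if (is.null(entries))
    ipreface_stop("events", "rule-table file has no `entries` field")
  tab <- if (is.data.frame(entries)) {
    tibble::as_tibble(entries)
  } else {
    tibble::as_tibble(do.call(rbind, lapply(entries, \(e) {
      e <- as.list(e)
      data.frame(baseline_rate = e$baseline_rate,
                 variability = e$variability, decel_type = e$decel_type,
                 severity = e$severity, level = as.integer(e$level),
                 stringsAsFactors = FALSE)
    })))
  }
  tab$level <- as.integer(tab$level)
  attr(tab, "table_id") <- raw$table_id %||% "custom"
  attr(tab, "version") <- as.character(raw$version %||% "unversioned")
  validate_rule_table(tab)
  tab
}

#' @rdname read_rule_table
#' @export
write_rule_table <- function(table, path) {
  validate_rule_table(table)
  payload <- list(
    table_id = attr(table, "table_id") %||% "custom",
    version  = attr(table, "version") %||% "unversioned",
    entries  = lapply(seq_len(nrow(table)), \(i) list(
      baseline_rate = table$baseline_rate[i],
      variability   = table$variability[i],
      decel_type    = table$decel_type[i],
      severity      = table$severity[i],
      level         = as.integer(table$level[i])
    ))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' Assign five-tier levels to deceleration events
#'
#' Looks up each event's level in the rule table from its four categorical
#' axes. A clinician-annotated `level_override`, when present, takes
#' precedence over the table lookup. The input is not modified; a copy with
#' the `level` column filled is returned.
#'
#' @param events A deceleration-event tibble (see [deceleration_events()]).
#' @param table A five-tier rule table; defaults to [default_rule_table()].
#' @param validate Validate `table` first (default). Callers that validated
#'   the table once may skip revalidation when classifying many batches.
#' @return `events` with an integer `level` column set for every row.
#' @export
#' @examples
#' ev <- deceleration_events(case_id = "a", onset_s = 100, duration_s = 60,
#'                           decel_type = "variable", severity = "mild",
#'                           baseline_rate = "normal", variability = "moderate")
#' classify_level(ev)$level
classify_level <- function(events, table = default_rule_table(),
                           validate = TRUE) {
  if (validate) validate_rule_table(table)
  axes <- c("baseline_rate", "variability", "decel_type", "severity")
  for (ax in axes) {
    if (!ax %in% names(events))
      ipreface_stop("events", paste("events are missing axis column:", ax))
    bad <- which(is.na(events[[ax]]))
    if (length(bad))
      ipreface_stop("events", sprintf(
        "event %d has missing axis value `%s`", bad[1L], ax))
  }
  key <- paste(table$baseline_rate, table$variability, table$decel_type,
               table$severity, sep = "|")
  ev_key <- paste(events$baseline_rate, events$variability,
                  events$decel_type, events$severity, sep = "|")
  idx <- match(ev_key, key)
  if (anyNA(idx))
    ipreface_stop("events", paste("no rule-table entry for key:",
                                  ev_key[is.na(idx)][1L]))
  lev <- as.integer(table$level[idx])
  if ("level_override" %in% names(events)) {
    ov <- suppressWarnings(as.integer(events$level_override))
    bad <- which(!is.na(ov) & !(ov %in% 1:5))
    if (length(bad))
      ipreface_stop("events", sprintf(
        "event %d has level_override outside 1..5", bad[1L]))
    lev <- ifelse(is.na(ov), lev, ov)
  }
  out <- events
  out$level <- as.integer(lev)
  out
}

#' Non-reassuring fetal status predicate
#'
#' Levels 3 to 5 of the five-tier classification define non-reassuring fetal
#' status (NRFS); levels 1 (normal) and 2 (subnormal) do not.
#'
#' @param level Integer vector of five-tier levels (1--5).
#' @return Logical vector, `TRUE` where the level is 3 or above.
#' @export
#' @examples
#' is_nrfs(c(1, 2, 3, 5))
is_nrfs <- function(level) {
  if (!is.numeric(level) || anyNA(level) || any(level != as.integer(level)) ||
      any(level < 1 | level > 5))
    ipreface_stop("events", "level must be an integer in 1..5")
  level >= 3
}
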