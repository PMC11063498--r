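# File I/O for the events and cases schemas.
#
# Events travel as CSV (one row per deceleration). Cases travel as CSV or,
# when coverage gaps must round-trip, as JSON — the CSV cases schema has no
# gap column, so CSV-written cohorts read back with full assumed coverage.
# Reals are serialized with 17 significant digits so write-then-read
# reproduces them exactly.

.events_cols <- c("case_id", "onset_s", "duration_s", "decel_type",
                  "severity", "baseline_rate", "variability",
                  "level_override")

.cases_cols <- c("case_id", "recording_start_s", "recording_end_s",
                 "decision_time_s", "removal_time_s", "delivery_time_s",
                 "maternal_age", "parity", "gestational_week", "induction",
                 "vacuum", "ph", "pco2", "po2", "hco3", "be", "lactate",
                 "apgar1", "apgar5", "nicu_asphyxia")

fmt_real <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

write_schema_csv <- function(df, cols, path) {
  out <- df[, intersect(cols, names(df)), drop = FALSE]
  for (col in setdiff(cols, names(out))) out[[col]] <- NA
  out <- out[, cols, drop = FALSE]
  for (col in cols) {
    v <- out[[col]]
    out[[col]] <- if (is.double(v)) fmt_real(v)
    else if (is.logical(v)) ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE"))
    else ifelse(is.na(v), "", as.character(v))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_schema_csv <- function(path, cols, module) {
  if (!file.exists(path))
    ipreface_stop(module, paste("file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    ipreface_stop(module, paste0("schema violation in ", basename(path),
                                 ": missing column(s) ",
                                 paste(miss, collapse = ", ")))
  for (j in seq_along(df))
    df[[j]][!is.na(df[[j]]) & df[[j]] == ""] <- NA
  tibble::as_tibble(df[, cols, drop = FALSE])
}

#' Read and write deceleration-event tables
#'
#' The events CSV schema has one row per deceleration: `case_id`, `onset_s`,
#' `duration_s`, `decel_type`, `severity`, `baseline_rate`, `variability`,
#' `level_override` (blank when absent). Written then re-read tables are
#' identical: identifiers and integers bit-exactly, reals to full precision.
#'
#' @param path CSV file path.
#' @param events A validated events tibble.
#' @return `read_events()` returns a validated events tibble;
#'   `write_events()` returns `path` invisibly.
#' @export
read_events <- function(path) {
  df <- read_schema_csv(path, .events_cols, "events")
  num <- c("onset_s", "duration_s")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      ipreface_stop("events", sprintf(
        "parse error at record %d of %s: non-numeric `%s`",
        bad[1L], basename(path), col))
    df[[col]] <- v
  }
  df$level_override <- suppressWarnings(as.integer(df$level_override))
  validate_events(df)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  write_schema_csv(events, .events_cols, path)
}

#' Read and write labor-case tables
#'
#' The cases schema carries, per labor: the recording bounds and timeline
#' marks (decision of cesarean, transducer removal, delivery), maternal
#' covariates, and neonatal outcomes including the umbilical-artery blood-gas
#' panel. CSV (`.csv`) follows the flat schema; JSON (`.json`) additionally
#' round-trips the `coverage_gaps` list-column. Timeline invariants are
#' validated on read, so a record with e.g. `removal_time_s <
#' decision_time_s` is rejected.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param cases A validated cases tibble.
#' @return `read_cases()` returns a validated cases tibble; `write_cases()`
#'   returns `path` invisibly.
#' @export
read_cases <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) ipreface_stop("events", paste("file not found:", path))
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- lapply(raw, function(r) {
      r$coverage_gaps <- NULL
      tibble::as_tibble(lapply(r, \(x) if (is.null(x)) NA else x))
    })
    df <- do.call(rbind, rows)
    gaps <- lapply(raw, function(r) {
      g <- r$coverage_gaps
      if (is.null(g) || !length(g)) return(NULL)
      matrix(unlist(lapply(g, as.numeric)), ncol = 2L, byrow = TRUE)
    })
    df <- retype_cases(df)
    df$coverage_gaps <- gaps
    return(validate_cases(df))
  }
  df <- read_schema_csv(path, .cases_cols, "events")
  validate_cases(retype_cases(df))
}

retype_cases <- function(df) {
  num <- c("recording_start_s", "recording_end_s", "decision_time_s",
           "removal_time_s", "delivery_time_s", "maternal_age",
           "gestational_week", "ph", "pco2", "po2", "hco3", "be", "lactate")
  int <- c("parity", "apgar1", "apgar5")
  lgl <- c("induction", "vacuum", "nicu_asphyxia")
  for (col in num) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  for (col in int) df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  for (col in lgl) df[[col]] <- as.logical(df[[col]])
  df$case_id <- as.character(df$case_id)
  df
}

#' @rdname read_cases
#' @export
write_cases <- function(cases, path) {
  cases <- validate_cases(cases)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- lapply(seq_len(nrow(cases)), function(i) {
      r <- lapply(.cases_cols, \(col)
        if (col %in% names(cases)) cases[[col]][i] else NA)
      names(r) <- .cases_cols
      g <- if ("coverage_gaps" %in% names(cases)) cases$coverage_gaps[[i]]
      if (!is.null(g) && length(g))
        r$coverage_gaps <- lapply(seq_len(nrow(g)), \(k) as.numeric(g[k, ]))
      r
    })
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  write_schema_csv(cases, .cases_cols, path)
}
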