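# ROC analysis for the score-vs-acidemia contrast.
#
# The empirical ROC is built from every distinct score threshold with the
# positivity rule "score >= threshold". Its trapezoidal area equals the
# Mann-Whitney probability P(X_pos > X_neg) + 0.5 P(X_pos = X_neg); the
# confidence interval uses the DeLong placement-value variance with a normal
# approximation, clipped to [0, 1].

#' ROC curve and AUC for a diagnostic score
#'
#' @param scores Numeric score vector.
#' @param outcomes Logical vector (or 0/1), `TRUE` for a positive case
#'   (e.g. umbilical-artery pH below the acidemia threshold).
#' @param conf_level Confidence level of the AUC interval, default 0.95.
#' @return A list of class `ipreface_roc`: `thresholds` (ascending, with
#'   `-Inf`/`Inf` sentinels), `sensitivity` and `specificity` per threshold,
#'   `auc`, `auc_ci_low`, `auc_ci_high`, `ci_method`, counts, and the input
#'   data (used by [youden_cutoff()]).
#' @export
#' @examples
#' roc <- roc_analysis(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' roc$auc
roc_analysis <- function(scores, outcomes, conf_level = 0.95) {
  scores <- as.numeric(scores)
  outcomes <- as.logical(outcomes)
  if (length(scores) != length(outcomes))
    ipreface_stop("evaluation", "scores and outcomes differ in length")
  if (anyNA(scores) || anyNA(outcomes))
    ipreface_stop("evaluation", "scores and outcomes must be complete")
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  if (!length(pos) || !length(neg))
    ipreface_stop("evaluation", paste(
      "roc_analysis needs at least one positive and one negative outcome;",
      "the outcome vector is degenerate"))
  thresholds <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thresholds, \(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, \(t) mean(neg < t), numeric(1))
  # DeLong placement values
  v10 <- vapply(pos, \(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, \(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  auc <- mean(v10)
  var_auc <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  if (!is.finite(var_auc)) var_auc <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- clamp(auc + c(-1, 1) * z * sqrt(var_auc), 0, 1)
  structure(list(
    thresholds = thresholds, sensitivity = sens, specificity = spec,
    auc = auc, auc_ci_low = ci[1L], auc_ci_high = ci[2L],
    ci_method = "DeLong", conf_level = conf_level,
    n_pos = length(pos), n_neg = length(neg),
    scores = scores, outcomes = outcomes
  ), class = "ipreface_roc")
}

# Trapezoidal area under the empirical ROC polygon; equal to the
# pair-counting (Mann-Whitney, ties half) estimate.
roc_auc_trapezoid <- function(roc) {
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Youden-index cutoff and confusion metrics
#'
#' Selects the score cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1 over the observed score values, with
#' positivity defined as score >= cutoff. Ties are broken toward the
#' smallest cutoff (the sensitivity-favoring choice). All six confusion
#' metrics are reported at the selected cutoff.
#'
#' @param roc An `ipreface_roc` from [roc_analysis()].
#' @return A list of class `ipreface_cutoff`: `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `fpr`, `fnr`, `youden_j`, and the 2x2
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
youden_cutoff <- function(roc) {
  if (!inherits(roc, "ipreface_roc"))
    ipreface_stop("evaluation", "`roc` must come from roc_analysis()")
  cand <- roc$thresholds[is.finite(roc$thresholds)]
  sens <- roc$sensitivity[is.finite(roc$thresholds)]
  spec <- roc$specificity[is.finite(roc$thresholds)]
  j <- sens + spec - 1
  # smallest cutoff among maximizers; J values closer than 1e-9 are ties
  # (distinct attainable J values differ by at least 1/(n_pos * n_neg)^2)
  best <- which(j >= max(j) - 1e-9)[1L]
  cutoff <- cand[best]
  pos <- roc$scores[roc$outcomes]
  neg <- roc$scores[!roc$outcomes]
  tp <- sum(pos >= cutoff); fn <- sum(pos < cutoff)
  fp <- sum(neg >= cutoff); tn <- sum(neg < cutoff)
  structure(list(
    cutoff = cutoff,
    sensitivity = sens[best], specificity = spec[best],
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    fpr = 1 - spec[best], fnr = 1 - sens[best],
    youden_j = j[best],
    tp = tp, fp = fp, fn = fn, tn = tn
  ), class = "ipreface_cutoff")
}

#' ROC points as a tibble
#'
#' @param roc An `ipreface_roc`.
#' @return A tibble with `threshold`, `sensitivity`, `specificity`, `fpr`.
#' @export
roc_points <- function(roc) {
  tibble::tibble(threshold = roc$thresholds,
                 sensitivity = roc$sensitivity,
                 specificity = roc$specificity,
                 fpr = 1 - roc$specificity)
}

#' @export
print.ipreface_roc <- function(x, ...) {
  cat(sprintf("ROC analysis: AUC %.3f (%d%% CI %.3f-%.3f, %s), %d+/%d-\n",
              x$auc, round(100 * x$conf_level), x$auc_ci_low, x$auc_ci_high,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.ipreface_cutoff <- function(x, ...) {
  cat(sprintf(
    paste0("Youden cutoff: score >= %g positive (J = %.3f)\n",
           "  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f",
           "  FPR %.3f  FNR %.3f\n"),
    x$cutoff, x$youden_j, x$sensitivity, x$specificity, x$ppv, x$npv,
    x$fpr, x$fnr))
  invisible(x)
}
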