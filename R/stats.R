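# Group-comparison statistics, the exact test on 2x2 outcome tables, the
# Hanley-McNeil AUC sample-size calculation, and cohort summary tables.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The table is `rbind(c(a, b), c(c, d))` with rows as groups and columns as
#' outcome present/absent. The two-sided p-value is the sum of the
#' hypergeometric point probabilities not exceeding that of the observed
#' table (the point-probability rule, as in [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The two-sided p-value, in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(7, 4, 3, 99)   # clearly unbalanced -> tiny p
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells)))
    ipreface_stop("evaluation", "cells must be non-negative integers")
  if (sum(cells) == 0)
    ipreface_stop("evaluation", "at least one margin must be positive")
  m <- matrix(as.integer(round(cells)), nrow = 2L, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Hanley-McNeil variance of an AUC estimate
#'
#' `Q1 = A / (2 - A)`, `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param auc The area under the curve, in (0, 1).
#' @param n_pos,n_neg Numbers of positive and negative cases (may be
#'   non-integer during sample-size search).
#' @return The variance of the empirical AUC.
#' @export
hanley_mcneil_var <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Sample size for detecting an AUC above 0.5
#'
#' Solves the one-sample AUC power equation
#' `z_alpha * sd0 + z_beta * sd1 = auc_alt - 0.5`, with both standard
#' deviations from the Hanley-McNeil variance (under the null AUC of 0.5 and
#' under `auc_alt`), for the continuous number of positive cases at the
#' given negative:positive allocation ratio. The continuous solution is
#' rounded to the nearest integer (not the ceiling), and the negatives are
#' scaled by the ratio — at the default design (AUC 0.80, power 0.90,
#' one-sided alpha 0.05, 1:9 allocation) this yields approximately 8
#' positives and 72 negatives, a total of 80.
#'
#' @param auc_alt Alternative-hypothesis AUC, above 0.5.
#' @param power Target power, in (0, 1); default 0.90.
#' @param alpha_one_sided One-sided significance level; default 0.05.
#' @param ratio_neg_per_pos Negatives per positive (9 for a 1:9
#'   present:absent prevalence ratio).
#' @return A list with `n_pos`, `n_neg`, `n_total`, and the unrounded
#'   `n_pos_continuous`.
#' @export
#' @examples
#' auc_sample_size(0.80, 0.90, 0.05, 9)$n_total
auc_sample_size <- function(auc_alt, power = 0.90, alpha_one_sided = 0.05,
                            ratio_neg_per_pos = 1) {
  assert_scalar_number(auc_alt, "auc_alt", "evaluation")
  if (auc_alt <= 0.5 || auc_alt >= 1)
    ipreface_stop("evaluation",
                  "auc_alt must lie in (0.5, 1); no finite n otherwise")
  if (power <= 0 || power >= 1 || alpha_one_sided <= 0 || alpha_one_sided >= 1)
    ipreface_stop("evaluation", "power and alpha must lie in (0, 1)")
  if (ratio_neg_per_pos <= 0)
    ipreface_stop("evaluation", "ratio_neg_per_pos must be positive")
  za <- stats::qnorm(1 - alpha_one_sided)
  zb <- stats::qnorm(power)
  delta <- auc_alt - 0.5
  gap <- function(n_pos) {
    n_neg <- ratio_neg_per_pos * n_pos
    za * sqrt(hanley_mcneil_var(0.5, n_pos, n_neg)) +
      zb * sqrt(hanley_mcneil_var(auc_alt, n_pos, n_neg)) - delta
  }
  sol <- stats::uniroot(gap, lower = 1.0001, upper = 1e7, tol = 1e-10)
  n_pos_cont <- sol$root
  n_pos <- round_half_up(n_pos_cont)
  n_neg <- round_half_up(ratio_neg_per_pos * n_pos)
  list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
       n_total = as.integer(n_pos + n_neg), n_pos_continuous = n_pos_cont)
}

# --- group comparisons (Table-2 shape) -------------------------------------

fmt_mean_sd <- function(x) sprintf("%.1f±%.1f", mean(x), stats::sd(x))
fmt_median_range <- function(x)
  sprintf("%.3g (%.3g–%.3g)", stats::median(x), min(x), max(x))
fmt_prop <- function(x)
  sprintf("%.1f (%d/%d)", 100 * mean(x), sum(x), length(x))

# Normality screen: Shapiro-Wilk in every group at the given level decides
# parametric vs rank-based. Degenerate (constant) samples are non-normal.
groups_normal <- function(values, grp, alpha = 0.05) {
  all(vapply(split(values, grp), function(v) {
    if (length(unique(v)) < 3L || length(v) < 3L || length(v) > 5000L)
      return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }, logical(1)))
}

compare_one <- function(values, grp, type, normality_alpha) {
  k <- nlevels(grp)
  if (type == "proportion") {
    x <- as.logical(values)
    tab <- table(grp, factor(x, levels = c(FALSE, TRUE)))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "Fisher exact"
    } else {
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      test <- "chi-square"
    }
    summaries <- vapply(split(x, grp), fmt_prop, character(1))
    return(list(test = test, p = p, summaries = summaries))
  }
  v <- as.numeric(values)
  if (length(unique(v)) == 1L) {
    # no variation anywhere: every test is uninformative
    test <- if (k == 2L) "Mann-Whitney U" else "Kruskal-Wallis"
    summaries <- vapply(split(v, grp), fmt_median_range, character(1))
    return(list(test = test, p = 1, summaries = summaries))
  }
  parametric <- groups_normal(v, grp, normality_alpha)
  if (parametric) {
    if (k == 2L) {
      sp <- split(v, grp)
      p <- stats::t.test(sp[[1L]], sp[[2L]])$p.value
      test <- "t test (Welch)"
    } else {
      p <- summary(stats::aov(v ~ grp))[[1L]][["Pr(>F)"]][1L]
      test <- "one-way ANOVA"
    }
    summaries <- vapply(split(v, grp), fmt_mean_sd, character(1))
  } else {
    if (k == 2L) {
      sp <- split(v, grp)
      p <- suppressWarnings(stats::wilcox.test(sp[[1L]], sp[[2L]])$p.value)
      test <- "Mann-Whitney U"
    } else {
      p <- stats::kruskal.test(v, grp)$p.value
      test <- "Kruskal-Wallis"
    }
    summaries <- vapply(split(v, grp), fmt_median_range, character(1))
  }
  list(test = test, p = p, summaries = summaries)
}

#' Compare cohort variables between groups
#'
#' Produces a stratified comparison table in the shape of a clinical
#' baseline/outcome table: per variable, a summary per group and the p-value
#' of the appropriate test. Test selection follows the documented rule:
#' continuous variables are screened for normality (Shapiro-Wilk in every
#' group) and compared by the t test (Welch) or one-way ANOVA when the
#' screen passes, otherwise by the Mann-Whitney U or Kruskal-Wallis test;
#' proportions use the chi-square test, or the Fisher exact test when any
#' expected cell count is below 5. P-values are two-sided and reported raw —
#' no multiplicity correction is applied, matching common practice for
#' descriptive clinical tables.
#'
#' @param cases Cases tibble.
#' @param grouping Either a grouping vector/factor of length `nrow(cases)`,
#'   or a predicate `function(cases)` returning one (e.g. score above a
#'   cutoff).
#' @param variables Named character vector mapping case columns to variable
#'   type, `"continuous"` or `"proportion"`; defaults to the standard
#'   covariate and blood-gas panel plus acidemia indicators.
#' @param normality_alpha Level of the Shapiro-Wilk screen, default 0.05.
#' @return A tibble with `variable`, one summary column per group,
#'   `test`, `p_value`.
#' @export
compare_groups <- function(cases, grouping, variables = NULL,
                           normality_alpha = 0.05) {
  if (is.function(grouping)) grouping <- grouping(cases)
  grp <- factor(grouping)
  if (length(grp) != nrow(cases))
    ipreface_stop("evaluation", "grouping length must match the cohort")
  if (nlevels(grp) < 2L || any(table(grp) == 0L))
    ipreface_stop("evaluation", "need at least two non-empty groups")
  if (is.null(variables)) {
    variables <- c(
      maternal_age = "continuous", parity = "continuous",
      gestational_week = "continuous", induction = "proportion",
      vacuum = "proportion", ph = "continuous", pco2 = "continuous",
      po2 = "continuous", hco3 = "continuous", be = "continuous",
      lactate = "continuous", apgar1 = "continuous", apgar5 = "continuous",
      nicu_asphyxia = "proportion"
    )
    variables <- variables[names(variables) %in% names(cases)]
    for (thr in c(7.2, 7.1, 7.0)) {
      nm <- sprintf("ph_lt_%.1f", thr)
      cases[[nm]] <- is_acidemic(cases$ph, thr)
      variables[nm] <- "proportion"
    }
  }
  rows <- lapply(names(variables), function(nm) {
    vals <- cases[[nm]]
    keep <- !is.na(vals) & !is.na(grp)
    if (!all(tapply(keep, grp, any)))
      return(NULL)
    res <- compare_one(vals[keep], droplevels(grp[keep]),
                       match.arg(variables[[nm]],
                                 c("continuous", "proportion")),
                       normality_alpha)
    summ <- as.list(res$summaries)
    names(summ) <- paste0("group_", names(res$summaries))
    tibble::as_tibble(c(list(variable = nm), summ,
                        list(test = res$test, p_value = res$p)))
  })
  do.call(rbind, rows)
}

#' Cohort summary in baseline-characteristics shape
#'
#' Summarizes a cohort per variable — mean±sd, median (range), or % (n/N) —
#' overall and, when a per-case group (e.g. the highest five-tier level
#' observed) is supplied, per group. The acidemia rates at pH thresholds
#' 7.2, 7.1, 7.0 and the NICU-admission rate are always included.
#'
#' @param cases Cases tibble.
#' @param group Optional per-case grouping vector (e.g. integer case level).
#' @return A tibble with `variable`, an `overall` column, and one column per
#'   group level.
#' @export
summarize_cohort <- function(cases, group = NULL) {
  if (!nrow(cases)) ipreface_stop("evaluation", "empty cohort")
  specs <- list(
    list("maternal_age", "mean_sd"), list("parity", "median_range"),
    list("gestational_week", "median_range"),
    list("induction", "prop"), list("vacuum", "prop"),
    list("ph", "mean_sd"), list("pco2", "mean_sd"), list("po2", "mean_sd"),
    list("hco3", "mean_sd"), list("be", "mean_sd"),
    list("lactate", "mean_sd"),
    list("apgar1", "median_range"), list("apgar5", "median_range")
  )
  cases$ph_lt_7.2 <- is_acidemic(cases$ph, 7.2)
  cases$ph_lt_7.1 <- is_acidemic(cases$ph, 7.1)
  cases$ph_lt_7.0 <- is_acidemic(cases$ph, 7.0)
  specs <- c(specs, list(list("ph_lt_7.2", "prop"), list("ph_lt_7.1", "prop"),
                         list("ph_lt_7.0", "prop"),
                         list("nicu_asphyxia", "prop")))
  fmt <- function(v, how) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    switch(how, mean_sd = fmt_mean_sd(as.numeric(v)),
           median_range = fmt_median_range(as.numeric(v)),
           prop = fmt_prop(as.logical(v)))
  }
  grp <- if (!is.null(group)) factor(group)
  rows <- lapply(specs, function(sp) {
    nm <- sp[[1L]]
    if (!nm %in% names(cases)) return(NULL)
    row <- list(variable = nm, overall = fmt(cases[[nm]], sp[[2L]]))
    if (!is.null(grp))
      for (lev in levels(grp))
        row[[paste0("group_", lev)]] <- fmt(cases[[nm]][grp == lev], sp[[2L]])
    tibble::as_tibble(row)
  })
  do.call(rbind, rows)
}
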