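# Independent oracles and small fixture builders used across the suite.

# O(n^2) pair-counting AUC: fraction of positive/negative pairs ranked
# correctly, ties counting one half.
oracle_auc_paircount <- function(scores, outcomes) {
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

# Exhaustive Youden maximization over every observed score value, smallest
# cutoff among ties, positivity rule score >= cutoff.
oracle_youden <- function(scores, outcomes) {
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[outcomes] >= t)
    spec <- mean(scores[!outcomes] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-9)
      best <- list(cutoff = t, j = j, sens = sens, spec = spec)
  }
  best
}

# Two-sided Fisher exact p by direct enumeration of the hypergeometric
# support with choose(): sum of point probabilities not exceeding the
# observed table's (tolerance guard recognises exact ties despite
# floating-point rounding).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# One synthetic case with a clean timeline: recording (0, 9000], decision at
# 5400 s, removal at 6600 s, delivery at 7800 s.
fixture_case <- function(case_id = "fx", gaps = NULL) {
  labor_cases(case_id, 0, 9000, 5400, 6600, 7800,
              maternal_age = 34, parity = 0L, gestational_week = 40.2,
              induction = TRUE, vacuum = FALSE, ph = 7.28, pco2 = 48,
              po2 = 16, hco3 = 22.5, be = -3.2, lactate = 3.0,
              apgar1 = 8L, apgar5 = 9L, nicu_asphyxia = FALSE,
              coverage_gaps = if (!is.null(gaps)) list(gaps))
}

# Events with pre-assigned levels via level_override (so the score is fully
# under the test's control), nadir at onset + duration/2.
fixture_events <- function(case_id, onset_s, duration_s, level,
                           decel_type = "variable") {
  n <- length(onset_s)
  classify_level(deceleration_events(
    case_id = rep_len(case_id, n), onset_s = onset_s,
    duration_s = duration_s, decel_type = rep_len(decel_type, n),
    severity = "mild", baseline_rate = "normal", variability = "moderate",
    level_override = level))
}

# Random leveled event set for property tests.
random_events <- function(case_id, n, t_max, seed) {
  set.seed(seed)
  types <- sample(c("early", "late", "variable", "prolonged"), n,
                  replace = TRUE, prob = c(0.3, 0.25, 0.35, 0.1))
  dur <- ifelse(types == "prolonged", runif(n, 125, 500), runif(n, 30, 115))
  ev <- deceleration_events(
    case_id = rep_len(case_id, n),
    onset_s = runif(n, 0, max(1, t_max - 520)),
    duration_s = dur, decel_type = types,
    severity = sample(c("mild", "severe"), n, TRUE),
    baseline_rate = sample(c("bradycardia", "normal", "tachycardia"), n,
                           TRUE, prob = c(0.05, 0.8, 0.15)),
    variability = sample(c("absent", "minimal", "moderate", "marked"), n,
                         TRUE, prob = c(0.1, 0.3, 0.5, 0.1)))
  classify_level(ev)
}
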