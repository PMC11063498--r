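# Seeded synthetic labor cohorts.
#
# The generator makes the clinical narrative behind the score quantitative:
# repeated decelerations first cause hypoxemia and respiratory acidosis
# (CO2 retention driven by the recent deceleration burden), and continued
# repetition gradually adds a metabolic component (base-excess fall driven
# by the cumulative burden). Each case draws a latent severity class, emits
# a time-inhomogeneous deceleration stream whose five-tier levels come from
# the shipped rule table, and converts its burden into a self-consistent
# umbilical-artery blood-gas panel.

# Van Slyke whole-blood base-excess relation, increasing in pH:
#   BE = 0.02786 * PCO2 * 10^(pH - 6.1) + 13.77 * pH - 124.58
# Given (PCO2, BE) we solve it for pH, then bicarbonate follows from
# Henderson-Hasselbalch, HCO3 = 0.03 * PCO2 * 10^(pH - 6.1), so every
# generated panel satisfies pH = 6.1 + log10(HCO3 / (0.03 * PCO2)) exactly.
van_slyke_be <- function(ph, pco2) {
  0.02786 * pco2 * 10^(ph - 6.1) + 13.77 * ph - 124.58
}

#' Blood-gas panel from PCO2 and base excess
#'
#' Solves the Van Slyke base-excess relation for pH at the given PCO2 and
#' target base excess (clamping the base excess to the value attainable
#' within the physiologic pH range 6.5--7.6), then derives bicarbonate from
#' the Henderson-Hasselbalch relation, so the returned panel is internally
#' consistent.
#'
#' @param pco2 Partial pressure of CO2, mm Hg (vectorized).
#' @param be Target base excess, mEq/L (vectorized).
#' @return A tibble with `ph`, `pco2`, `hco3`, `be` (the attained base
#'   excess after clamping).
#' @export
blood_gas_from_pco2_be <- function(pco2, be) {
  n <- max(length(pco2), length(be))
  pco2 <- rep_len(as.numeric(pco2), n)
  be <- rep_len(as.numeric(be), n)
  if (any(pco2 <= 0)) ipreface_stop("synthetic", "PCO2 must be positive")
  rows <- lapply(seq_len(n), \(i) blood_gas1(pco2[i], be[i]))
  tibble::tibble(ph = vapply(rows, `[[`, numeric(1), "ph"),
                 pco2 = pco2,
                 hco3 = vapply(rows, `[[`, numeric(1), "hco3"),
                 be = vapply(rows, `[[`, numeric(1), "be"))
}

# scalar solver used both by the vectorized exported wrapper and the
# generator's inner loop
blood_gas1 <- function(pco2, be) {
  be <- clamp(be, van_slyke_be(6.5, pco2), van_slyke_be(7.6, pco2))
  ph <- stats::uniroot(\(p) van_slyke_be(p, pco2) - be,
                       lower = 6.5, upper = 7.6, tol = 1e-10)$root
  list(ph = ph, pco2 = pco2, hco3 = 0.03 * pco2 * 10^(ph - 6.1), be = be)
}

#' Configuration of the synthetic labor-cohort generator
#'
#' Defaults emulate a term singleton emergency-cesarean cohort: timeline
#' medians near 69 min decision-to-delivery and 45 min removal-to-delivery,
#' about two thirds induced labors, and roughly 10% of deliveries with an
#' umbilical-artery pH below 7.2. Three latent severity classes (low, mid,
#' high deceleration burden) drive event rates, level mixes and thereby the
#' acid-base outcome; the class mix is solved from `target_prevalence` using
#' the frozen per-class acidemia rates `class_acidemia_rates` (calibrated
#' once against the default mechanism).
#'
#' @param n_cases Number of labors, default 113.
#' @param seed Integer seed; the same configuration and seed always
#'   reproduce the identical cohort, and the first `k` cases do not change
#'   when `n_cases` grows.
#' @param target_prevalence Target fraction of cases with pH < 7.2,
#'   default 0.10.
#' @param event_rate_per_30min Decelerations per 30 minutes by severity
#'   class (low, mid, high).
#' @param ramp Linear intensity ramp over the recording: the deceleration
#'   intensity at the end of monitoring is `1 + ramp` times that at its
#'   start.
#' @param prolonged_prob Probability that an event is a prolonged
#'   deceleration, per class.
#' @param prolonged_meanlog,prolonged_sdlog Log-normal parameters of the
#'   prolonged-deceleration duration in minutes (truncated to 2--9.5 min).
#' @param respiratory_gain mm Hg of PCO2 per point of recent burden (score
#'   accrued in the last 30 recorded minutes).
#' @param metabolic_gain mEq/L of base-excess fall per point of cumulative
#'   burden over the whole recording.
#' @param pco2_base,pco2_sd,be_base,be_sd Baseline and noise scales of the
#'   acid-base coupling.
#' @param class_acidemia_rates Frozen calibration constants: the acidemia
#'   (pH < 7.2) rate of each severity class under the default mechanism,
#'   used to solve the class mix from `target_prevalence`.
#' @param low_frac_of_rest Fraction of the non-high probability mass
#'   assigned to the low class.
#' @return A list of class `ipreface_sim_config`.
#' @export
synthetic_config <- function(n_cases = 113L,
                             seed = 1L,
                             target_prevalence = 0.10,
                             event_rate_per_30min = c(low = 2.5, mid = 3.2, high = 7),
                             ramp = 1.0,
                             prolonged_prob = c(low = 0.01, mid = 0.04, high = 0.08),
                             prolonged_meanlog = log(3),
                             prolonged_sdlog = 0.35,
                             respiratory_gain = 0.4,
                             metabolic_gain = 0.06,
                             pco2_base = 45, pco2_sd = 5,
                             be_base = -1.0, be_sd = 1.5,
                             class_acidemia_rates = c(low = 0.019, mid = 0.138,
                                                      high = 0.918),
                             low_frac_of_rest = 0.70) {
  cfg <- list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    target_prevalence = target_prevalence,
    event_rate_per_30min = event_rate_per_30min, ramp = ramp,
    prolonged_prob = prolonged_prob,
    prolonged_meanlog = prolonged_meanlog, prolonged_sdlog = prolonged_sdlog,
    respiratory_gain = respiratory_gain, metabolic_gain = metabolic_gain,
    pco2_base = pco2_base, pco2_sd = pco2_sd,
    be_base = be_base, be_sd = be_sd,
    class_acidemia_rates = class_acidemia_rates,
    low_frac_of_rest = low_frac_of_rest
  )
  if (cfg$n_cases < 1L) ipreface_stop("synthetic", "n_cases must be >= 1")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    ipreface_stop("synthetic", "target_prevalence must lie in (0, 1)")
  if (any(c(event_rate_per_30min, prolonged_prob, respiratory_gain,
            metabolic_gain, pco2_sd, be_sd) < 0))
    ipreface_stop("synthetic", "rates, gains and noise scales must be >= 0")
  cfg$class_probs <- solve_class_probs(cfg)
  class(cfg) <- "ipreface_sim_config"
  cfg
}

# Class mix (low, mid, high) such that the mixture acidemia rate hits the
# target prevalence given the frozen per-class rates.
solve_class_probs <- function(cfg) {
  r <- cfg$class_acidemia_rates
  m <- cfg$low_frac_of_rest * r[["low"]] +
    (1 - cfg$low_frac_of_rest) * r[["mid"]]
  p_high <- (cfg$target_prevalence - m) / (r[["high"]] - m)
  if (!is.finite(p_high) || p_high <= 0 || p_high >= 1)
    ipreface_stop("synthetic", sprintf(
      paste("target prevalence %.3f is unreachable with the configured",
            "class acidemia rates (attainable range %.3f..%.3f)"),
      cfg$target_prevalence, m, r[["high"]]))
  rest <- 1 - p_high
  c(low = rest * cfg$low_frac_of_rest,
    mid = rest * (1 - cfg$low_frac_of_rest),
    high = p_high)
}

# Deterministic per-case substream: stable when n_cases changes.
case_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 104729) %% 2147483629)
}

# Class-conditional categorical mixes for the event axes (non-prolonged
# deceleration types; prolonged events are governed by config$prolonged_prob).
.axis_mix <- list(
  decel_type = list(low = c(early = 0.35, variable = 0.55, late = 0.10),
                    mid = c(early = 0.22, variable = 0.56, late = 0.22),
                    high = c(early = 0.10, variable = 0.50, late = 0.40)),
  severe_p = c(low = 0.10, mid = 0.22, high = 0.55),
  variability = list(low = c(absent = 0.00, minimal = 0.10, moderate = 0.85,
                             marked = 0.05),
                     mid = c(absent = 0.01, minimal = 0.18, moderate = 0.76,
                             marked = 0.05),
                     high = c(absent = 0.05, minimal = 0.45, moderate = 0.45,
                              marked = 0.05)),
  baseline = list(low = c(bradycardia = 0.00, normal = 0.97,
                          tachycardia = 0.03),
                  mid = c(bradycardia = 0.01, normal = 0.92,
                          tachycardia = 0.07),
                  high = c(bradycardia = 0.03, normal = 0.80,
                           tachycardia = 0.17)))

# Inverse-CDF sampling of event times under intensity proportional to
# 1 + ramp * t/T on (0, T).
ramp_times <- function(n, total, ramp) {
  u <- stats::runif(n)
  t_frac <- if (ramp <= 1e-12) u else {
    (-1 + sqrt(1 + 2 * ramp * u * (1 + ramp / 2))) / ramp
  }
  sort(t_frac) * total
}

#' Generate a synthetic labor cohort
#'
#' Draws `config$n_cases` labors. Per case: a latent severity class; a
#' timeline (decision of cesarean, transducer removal = end of recording,
#' delivery); a deceleration stream with intensity rising toward delivery,
#' levels assigned from the shipped five-tier table; and a blood-gas panel
#' in which PCO2 rises with the burden of the last 30 recorded minutes
#' (respiratory component) and base excess falls with the cumulative burden
#' (metabolic component), pH solving the Van Slyke relation and bicarbonate
#' the Henderson-Hasselbalch relation. Apgar scores and NICU admission are
#' thresholded on pH with noise. Because the transducer is removed before
#' delivery, "recent" burden is measured over the last 30 minutes of
#' recording — no deceleration can be observed after removal.
#'
#' @param config An `ipreface_sim_config` from [synthetic_config()].
#' @param rule_table Five-tier table used to level the generated events.
#' @return A list of class `ipreface_cohort` with `cases` and `events`
#'   tibbles (the schemas of [read_cases()]/[read_events()]) and the
#'   `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_cases = 5, seed = 42))
#' cohort$cases$ph
generate_cohort <- function(config = synthetic_config(),
                            rule_table = default_rule_table()) {
  if (!inherits(config, "ipreface_sim_config"))
    ipreface_stop("synthetic", "`config` must come from synthetic_config()")
  validate_rule_table(rule_table)
  classes <- c("low", "mid", "high")
  case_rows <- vector("list", config$n_cases)
  event_rows <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    set.seed(case_seed(config$seed, i))
    cl <- sample(classes, 1L, prob = config$class_probs)

    # timeline (seconds); recording ends at transducer removal
    pre_decision <- 1800 + stats::rgamma(1L, shape = 1.5, scale = 1200)
    t_dd_min <- clamp(exp(stats::rnorm(1L, log(69), 0.45)), 20, 242)
    frac <- stats::rbeta(1L, 6.5, 3.5)
    t_rd_min <- clamp(frac * t_dd_min, 10, 0.95 * t_dd_min)
    decision <- pre_decision
    delivery <- decision + t_dd_min * 60
    removal <- delivery - t_rd_min * 60
    total <- removal  # recording_start = 0, recording_end = removal

    # deceleration stream
    rate <- config$event_rate_per_30min[[cl]]
    lambda <- rate / 1800 * total * (1 + config$ramp / 2)
    n_ev <- stats::rpois(1L, lambda)
    ev <- NULL
    if (n_ev > 0L) {
      onset <- ramp_times(n_ev, total, config$ramp)
      is_pro <- stats::runif(n_ev) < config$prolonged_prob[[cl]]
      type <- character(n_ev)
      mix <- .axis_mix$decel_type[[cl]]
      mix_np <- mix[c("early", "variable", "late")]
      type[!is_pro] <- sample(names(mix_np), sum(!is_pro), replace = TRUE,
                              prob = mix_np)
      type[is_pro] <- "prolonged"
      dur <- stats::runif(n_ev, 30, 110)
      if (any(is_pro))
        dur[is_pro] <- clamp(60 * stats::rlnorm(sum(is_pro),
                                                config$prolonged_meanlog,
                                                config$prolonged_sdlog),
                             125, 570)
      onset <- clamp(onset, 0, pmax(0, total - dur))
      sev <- ifelse(stats::runif(n_ev) < .axis_mix$severe_p[[cl]],
                    "severe", "mild")
      vab <- sample(names(.axis_mix$variability[[cl]]), n_ev, replace = TRUE,
                    prob = .axis_mix$variability[[cl]])
      bas <- sample(names(.axis_mix$baseline[[cl]]), n_ev, replace = TRUE,
                    prob = .axis_mix$baseline[[cl]])
      ev <- data.frame(
        case_id = sprintf("case_%04d", i), onset_s = onset, duration_s = dur,
        decel_type = type, severity = sev, baseline_rate = bas,
        variability = vab, level_override = NA_integer_,
        level = NA_integer_, stringsAsFactors = FALSE)
      ev <- classify_level(ev, rule_table, validate = FALSE)
    }

    # burden: cumulative over the recording; recent over its last 30 min
    if (!is.null(ev) && nrow(ev)) {
      b_total <- sum(event_contributions(ev, -1, total + 600)$contribution)
      b_recent <- sum(event_contributions(ev, total - 1800,
                                          total)$contribution)
    } else b_total <- b_recent <- 0

    # noise draws precede the gain coupling, so raising a gain with the same
    # seed perturbs nothing else
    z <- stats::rnorm(5L)
    u_nicu <- stats::runif(1L)
    pco2 <- clamp(config$pco2_base + config$respiratory_gain * b_recent +
                    z[1L] * config$pco2_sd, 18, 140)
    be_target <- clamp(config$be_base - config$metabolic_gain * b_total +
                         z[2L] * config$be_sd, -27, 8)
    gas <- blood_gas1(pco2, be_target)
    po2 <- clamp(16.5 - 0.02 * b_recent + z[3L] * 5, 2, 40)
    lactate <- clamp(1.6 + 0.55 * pmax(0, -gas$be) + z[4L] * 0.8, 0.3, 25)
    apgar5 <- clamp(round(9.3 - 12 * pmax(0, 7.28 - gas$ph) + z[5L] * 0.5),
                    0, 10)
    apgar1 <- clamp(apgar5 - 1 + round(z[3L] * 0.4), 0, 10)
    nicu <- u_nicu < stats::plogis(40 * (7.02 - gas$ph))

    # covariates
    age <- clamp(stats::rnorm(1L, 34.4, 5.4), 18, 48)
    parity <- min(stats::rpois(1L, 0.5), 6L)
    gw <- round(stats::runif(1L, 37, 41.9), 1)
    induction <- stats::runif(1L) < 0.673
    vacuum <- stats::runif(1L) < c(low = 0.06, mid = 0.06, high = 0.20)[[cl]]

    case_rows[[i]] <- data.frame(
      case_id = sprintf("case_%04d", i),
      recording_start_s = 0, recording_end_s = total,
      decision_time_s = decision, removal_time_s = removal,
      delivery_time_s = delivery,
      maternal_age = age, parity = as.integer(parity),
      gestational_week = gw, induction = induction, vacuum = vacuum,
      ph = gas$ph, pco2 = gas$pco2, po2 = po2, hco3 = gas$hco3,
      be = gas$be, lactate = lactate,
      apgar1 = as.integer(apgar1), apgar5 = as.integer(apgar5),
      nicu_asphyxia = nicu,
      severity_class = cl, burden_total = b_total, burden_recent = b_recent,
      stringsAsFactors = FALSE)
    event_rows[[i]] <- ev
  }
  cases <- tibble::as_tibble(do.call(rbind, case_rows))
  events <- do.call(rbind, event_rows[!vapply(event_rows, is.null,
                                              logical(1))])
  if (!is.null(events)) events <- tibble::as_tibble(events)
  if (is.null(events))
    events <- validate_events(tibble::tibble(
      case_id = character(), onset_s = numeric(), duration_s = numeric(),
      decel_type = character(), severity = character(),
      baseline_rate = character(), variability = character(),
      level_override = integer(), level = integer()))
  cases <- validate_cases(cases, events)
  structure(list(cases = cases, events = events, config = config),
            class = "ipreface_cohort")
}

#' @export
print.ipreface_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic labor cohort: %d cases, %d decelerations, pH<7.2 in %d (%.1f%%)\n",
    nrow(x$cases), nrow(x$events), sum(x$cases$ph < 7.2),
    100 * mean(x$cases$ph < 7.2)))
  invisible(x)
}
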