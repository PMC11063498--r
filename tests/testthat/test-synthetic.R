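test_that("identical config and seed reproduce the identical cohort", {
  a <- generate_cohort(synthetic_config(n_cases = 12, seed = 5))
  b <- generate_cohort(synthetic_config(n_cases = 12, seed = 5))
  expect_identical(a$cases, b$cases)
  expect_identical(a$events, b$events)
  # per-case substreams: early cases unchanged when the cohort grows
  big <- generate_cohort(synthetic_config(n_cases = 20, seed = 5))
  expect_identical(a$cases, big$cases[1:12, ])
})

test_that("every generated panel satisfies Henderson-Hasselbalch", {
  co <- generate_cohort(synthetic_config(n_cases = 40, seed = 9))
  ph_hh <- 6.1 + log10(co$cases$hco3 / (0.03 * co$cases$pco2))
  expect_true(all(abs(co$cases$ph - ph_hh) < 0.01))
  expect_true(all(co$cases$ph >= 6.5 & co$cases$ph <= 7.6))
  expect_true(all(co$cases$pco2 > 0 & co$cases$hco3 > 0))
})

test_that("with no decelerations there is no burden and no acidemia", {
  cfg <- synthetic_config(n_cases = 40, seed = 3,
                          event_rate_per_30min = c(low = 0, mid = 0, high = 0),
                          prolonged_prob = c(low = 0, mid = 0, high = 0))
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$events), 0L)
  sc <- score_cases(co$cases, co$events, "both")
  expect_true(all(sc$score == 0))
  # pH stays within noise of the burden-free base value
  base_ph <- blood_gas_from_pco2_be(cfg$pco2_base, cfg$be_base)$ph
  expect_lt(abs(mean(co$cases$ph) - base_ph), 0.05)
  expect_lte(mean(co$cases$ph < 7.2), 0.05)
})

test_that("raising the acidosis gains never raises cohort pH (same seed)", {
  base <- generate_cohort(synthetic_config(n_cases = 30, seed = 17))
  harder <- generate_cohort(synthetic_config(
    n_cases = 30, seed = 17, respiratory_gain = 0.6, metabolic_gain = 0.09))
  expect_identical(base$events, harder$events)  # same deceleration streams
  expect_true(all(harder$cases$ph <= base$cases$ph + 1e-12))
})

test_that("acidemia prevalence hits the configured target on average", {
  prev <- vapply(1:100, function(s)
    mean(generate_cohort(synthetic_config(n_cases = 113, seed = s))$cases$ph
         < 7.2), numeric(1))
  # 100 seeds x 113 cases: the pooled estimate must sit within Monte-Carlo
  # tolerance (about 3 binomial standard errors plus calibration slack) of
  # the 0.10 target
  expect_lt(abs(mean(prev) - 0.10), 0.015)
})

test_that("regression of base excess on burden recovers the metabolic gain", {
  cfg <- synthetic_config(n_cases = 1000, seed = 23)
  co <- generate_cohort(cfg)
  keep <- co$cases$be > -26.5  # away from the clamp
  fit <- stats::lm(be ~ burden_total, data = co$cases[keep, ])
  expect_lt(abs(-coef(fit)[["burden_total"]] - cfg$metabolic_gain) /
              cfg$metabolic_gain, 0.10)
})

test_that("unreachable target prevalence is a generation error", {
  expect_error(synthetic_config(target_prevalence = 0.95), "unreachable")
})

test_that("a rendered event set is recovered by the detector", {
  ev <- deceleration_events(
    case_id = "t", onset_s = c(400, 900, 1400, 1900, 2400, 2900, 3400),
    duration_s = c(60, 80, 70, 150, 60, 90, 75),
    decel_type = c("variable", "late", "early", "prolonged", "variable",
                   "late", "variable"),
    severity = c("mild", "severe", "mild", "severe", "severe", "mild",
                 "mild"),
    baseline_rate = "normal", variability = "moderate")
  tr <- render_trace(ev, duration_s = 3800, variability_amp_bpm = 4,
                     seed = 2)
  det <- detect_decelerations(tr$fhr, tr$uc)
  # every event recovered, onsets within 15 s
  expect_equal(nrow(det), nrow(ev))
  matched <- vapply(ev$onset_s, \(on) min(abs(det$onset_s - on)),
                    numeric(1))
  expect_true(all(matched < 15))
  expect_gte(mean(vapply(seq_len(nrow(ev)), \(i) {
    j <- which.min(abs(det$onset_s - ev$onset_s[i]))
    det$decel_type[j] == ev$decel_type[i]
  }, logical(1))), 0.95)
})

test_that("flat and sub-threshold traces yield no detections", {
  empty <- deceleration_events(
    case_id = character(), onset_s = numeric(), duration_s = numeric(),
    decel_type = character(), severity = character(),
    baseline_rate = character(), variability = character())
  tr0 <- render_trace(empty, duration_s = 1000, variability_amp_bpm = 4,
                      seed = 3)
  expect_equal(nrow(detect_decelerations(tr0$fhr, tr0$uc)), 0L)
  # no-event trace stays within the variability band of baseline
  expect_true(all(abs(tr0$fhr - 140) < 4 * 4))
  # a 10 bpm / 10 s dip is below both detection thresholds
  t <- seq(0, 800, by = 0.25)
  dip <- 10 * (t >= 400 & t < 410)
  expect_equal(nrow(detect_decelerations(140 - dip, rep(10, length(t)))),
               0L)
})

test_that("a rendered dip reaches its annotated depth", {
  ev <- deceleration_events("t", 300, 80, "variable", "mild", "normal",
                            "moderate")
  tr <- render_trace(ev, duration_s = 700, variability_amp_bpm = 2,
                     seed = 6)
  expect_lt(abs(min(tr$fhr) - (140 - 25)), 4)
  expect_error(detect_decelerations(tr$fhr, tr$uc[-1]), "length")
})

test_that("the generated timelines respect the labor ordering", {
  co <- generate_cohort(synthetic_config(n_cases = 50, seed = 41))
  cs <- co$cases
  expect_true(all(cs$recording_start_s <= cs$decision_time_s))
  expect_true(all(cs$decision_time_s <= cs$removal_time_s))
  expect_true(all(cs$removal_time_s <= cs$delivery_time_s))
  expect_true(all(cs$decision_time_s >= 1800))  # DCS window always covered
  expect_true(all(co$events$onset_s <= cs$recording_end_s[
    match(co$events$case_id, cs$case_id)]))
})
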