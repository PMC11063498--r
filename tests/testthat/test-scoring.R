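test_that("windows anchor at the decision and removal marks", {
  case <- labor_cases("a", 0, 7000, 5400, 6000, 7000)
  w <- make_window(case, "DCS")
  expect_equal(w$start, 3600)
  expect_equal(w$end_time, 5400)
  expect_equal(w$coverage_fraction, 1)
  w2 <- make_window(case, "RCT")
  expect_equal(w2$end_time, 6000)
})

test_that("coverage gaps shrink the coverage fraction", {
  gaps <- matrix(c(5000, 5200), ncol = 2)
  case <- labor_cases("a", 0, 7000, 5400, 5400, 7000,
                      coverage_gaps = list(gaps))
  w <- make_window(case, "RCT")
  expect_equal(w$coverage_fraction, (1800 - 200) / 1800)
})

test_that("a window reaching before the recording is a coverage error", {
  case <- labor_cases("a", 0, 7000, 1200, 6000, 7000)
  expect_error(make_window(case, "DCS"), "does not cover")
})

test_that("non-prolonged decelerations sum their levels", {
  case <- fixture_case()
  w <- make_window(case, "DCS")  # (3600, 5400]
  ev <- fixture_events("fx", c(3700, 4000, 4300, 4600, 4900),
                       rep(60, 5), c(3L, 3L, 4L, 4L, 3L))
  s <- score_window(ev, w)
  expect_equal(s$total, 17L)
  expect_equal(s$n_events_scored, 5L)
  expect_equal(sum(s$contributions$contribution), s$total)
})

test_that("prolonged decelerations score level x half-up rounded minutes", {
  case <- fixture_case()
  w <- make_window(case, "DCS")
  ev44 <- fixture_events("fx", 4000, 4.4 * 60, 5L, "prolonged")
  expect_equal(score_window(ev44, w)$total, 20L)  # 5 x 4
  ev45 <- fixture_events("fx", 4000, 4.5 * 60, 5L, "prolonged")
  expect_equal(score_window(ev45, w)$total, 25L)  # 5 x 5 under half-up
  mixed <- rbind(
    fixture_events("fx", c(3700, 4600, 5000), rep(60, 3), 2L),
    fixture_events("fx", 4000, 3.2 * 60, 3L, "prolonged"))
  expect_equal(score_window(mixed, w)$total, 15L)  # 6 + 3x3
})

test_that("an empty window scores zero", {
  case <- fixture_case()
  w <- make_window(case, "RCT")
  empty <- fixture_events("fx", numeric(0), numeric(0), integer(0))
  expect_equal(score_window(empty, w)$total, 0L)
})

test_that("scoring demands levels and honors strict coverage", {
  case <- fixture_case()
  w <- make_window(case, "DCS")
  ev <- deceleration_events("fx", 4000, 60, "variable", "mild", "normal",
                            "moderate")
  expect_error(score_window(ev, w), "no five-tier level")
  gaps <- matrix(c(5000, 5100), ncol = 2)
  wg <- make_window(fixture_case(gaps = gaps), "DCS")
  leveled <- fixture_events("fx", 4000, 60, 3L)
  expect_error(score_window(leveled, wg), "coverage")
  expect_warning(s <- score_window(leveled, wg, strict_coverage = FALSE),
                 "coverage")
  expect_equal(s$total, 3L)
})

test_that("prolonged events of ten minutes or more are excluded", {
  case <- fixture_case()
  w <- make_window(case, "DCS")
  suppressWarnings(ev <- deceleration_events(
    "fx", 4000, 650, "prolonged", "severe", "normal", "minimal",
    level_override = 5L))
  ev <- classify_level(ev)
  expect_warning(s <- score_window(ev, w), "excluded")
  expect_equal(s$total, 0L)
  expect_equal(s$n_events_excluded, 1L)
})

test_that("scores are additive over event partitions", {
  case <- fixture_case()
  w <- make_window(case, "RCT")
  set.seed(42)
  ev <- random_events("fx", 14, 6600, seed = 42)
  full <- score_window(ev, w)$total
  split_at <- 7
  s1 <- score_window(ev[seq_len(split_at), ], w)$total
  s2 <- score_window(ev[-seq_len(split_at), ], w)$total
  expect_equal(full, s1 + s2)
})

test_that("adding events or lengthening prolonged ones never lowers a score", {
  case <- fixture_case()
  w <- make_window(case, "DCS")
  for (seed in 1:5) {
    ev <- random_events("fx", 8, 6600, seed = seed)
    base <- score_window(ev, w)$total
    more <- rbind(ev, fixture_events("fx", 4200, 60, 4L))
    expect_gte(score_window(more, w)$total, base)
  }
  pro <- fixture_events("fx", 4000, 150, 4L, "prolonged")
  pro_long <- fixture_events("fx", 4000, 250, 4L, "prolonged")
  expect_gte(score_window(pro_long, w)$total, score_window(pro, w)$total)
})

test_that("totals are integral and non-negative on random cohorts", {
  for (seed in c(7, 19)) {
    co <- generate_cohort(synthetic_config(n_cases = 8, seed = seed))
    sc <- score_cases(co$cases, co$events, "both")
    expect_true(all(sc$score >= 0))
    expect_true(all(sc$score == round(sc$score)))
  }
})

test_that("shifting all times by a constant leaves scores unchanged", {
  shift <- 12345
  ev <- random_events("fx", 10, 6600, seed = 8)
  case <- fixture_case()
  w <- make_window(case, "RCT")
  ev2 <- ev
  ev2$onset_s <- ev2$onset_s + shift
  case2 <- as.list(case)
  for (f in c("recording_start_s", "recording_end_s", "decision_time_s",
              "removal_time_s", "delivery_time_s"))
    case2[[f]] <- case2[[f]] + shift
  w2 <- make_window(case2, "RCT")
  expect_equal(score_window(ev2, w2)$total, score_window(ev, w)$total)
})

test_that("the score trajectory matches independent window scores", {
  case <- fixture_case()
  ev <- fixture_events("fx", 4000, 60, 3L)
  traj <- score_trajectory(case, ev, variant_end = 6600, step = 300)
  # 3 while the nadir is in-window, 0 otherwise
  nadir <- 4030
  expect_equal(traj$score,
               ifelse(traj$end_time_s - 1800 < nadir &
                        nadir <= traj$end_time_s, 3L, 0L))
  # last point at the removal anchor equals the RCT score
  expect_equal(traj$end_time_s[nrow(traj)], 6600)
  expect_equal(traj$score[nrow(traj)],
               score_window(ev, make_window(case, "RCT"))$total)
  # brute-force recomputation on a random case
  ev_r <- random_events("fx", 12, 6600, seed = 31)
  traj_r <- score_trajectory(case, ev_r, variant_end = 6600, step = 240)
  for (k in seq_len(nrow(traj_r))) {
    w <- make_window(case, "custom", end_time = traj_r$end_time_s[k])
    expect_equal(traj_r$score[k], score_window(ev_r, w)$total)
  }
})
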