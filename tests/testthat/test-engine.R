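h10 <- default_h()
cfg <- session_config()

test_that("session start applies the elicitation rule and counts decision 1", {
  s <- start_session(h10, cfg, 6)
  expect_equal(s$suds, 6L)
  expect_equal(s$clock, 0L)
  expect_equal(s$decisions_made, 1L)
  s1 <- start_session(h10, cfg, 1)
  expect_equal(s1$suds, 1L)
  expect_error(start_session(h10, cfg, 12), "not on the hierarchy")
})

test_that("config invariants are enforced", {
  expect_error(session_config(decision_interval_seconds = 40), "multiple")
  expect_error(session_config(habituation_interval_seconds = 100), "multiple")
  expect_error(session_config(suds_min = 10, suds_max = 10), "below")
  expect_error(session_config(band_low_max = 8, band_high_min = 3),
               "strictly increasing")
})

test_that("habituation drops one SUDS point per full interval, floored", {
  s <- start_session(h10, cfg, 6)
  advance(s, 120)
  expect_equal(s$suds, 5L)
  # floor at the bound
  s0 <- start_session(h10, session_config(elicitation = function(p) 0), 5)
  expect_equal(s0$suds, 0L)
  advance(s0, 120)
  expect_equal(s0$suds, 0L)
})

test_that("a cue fires every tick, tagged with the distress band", {
  s <- start_session(h10, cfg, 6)
  evs <- advance(s, 45)
  cues <- Filter(function(e) e$kind == "verbalization_cue", evs)
  expect_length(cues, 3L)
  expect_true(all(vapply(cues, function(e) e$payload$band, "") == "moderate"))
})

test_that("advance rejects misaligned or posthumous calls", {
  s <- start_session(h10, cfg, 6)
  expect_error(advance(s, 20), "multiple")
  expect_error(advance(s, 0), "multiple")
  end_session(s)
  expect_error(advance(s, 45), "terminated")
  expect_error(suds_check(s), "terminated")
})

test_that("decision SUDS rules: up to elicitation, down capped, same unchanged", {
  # habituate at task 4 down to SUDS 2, then move up to 6
  s <- start_session(h10, cfg, 4)
  advance(s, 240)
  expect_equal(s$suds, 2L)
  apply_decision(s, 6)
  expect_equal(s$suds, 6L)
  expect_equal(s$time_on_task, 0L)
  # downward move takes the min of current and entry level
  s2 <- start_session(h10, cfg, 6)
  apply_decision(s2, 5)
  expect_equal(s2$suds, 5L)
  # easing never raises SUDS: habituated below the target's entry level
  s3 <- start_session(h10, cfg, 6)
  advance(s3, 480)
  expect_equal(s3$suds, 2L)
  apply_decision(s3, 4)
  expect_equal(s3$suds, 2L)
  # keep-same leaves SUDS alone and the habituation clock running
  s4 <- start_session(h10, cfg, 6)
  advance(s4, 60)
  apply_decision(s4, 6)
  expect_equal(s4$suds, 6L)
  expect_equal(s4$time_on_task, 60L)
})

test_that("decisions outside the move radius or past the budget error", {
  s <- start_session(h10, cfg, 5)
  expect_error(apply_decision(s, 8), "allowed moves")
  for (k in 2:9) apply_decision(s, 5)
  expect_error(apply_decision(s, 5), "already consumed")
})

test_that("suds_check is pure and matches the hand-stepped oracle", {
  s <- start_session(h10, cfg, 6)
  expect_equal(suds_check(s), 6L)
  advance(s, 240)
  expect_equal(suds_check(s), 4L)
  expect_equal(suds_check(s), suds_check(s))
})

test_that("distress bands partition the scale at the configured edges", {
  expect_equal(distress_band(2, cfg), "low")
  expect_equal(distress_band(3, cfg), "low")
  expect_equal(distress_band(5, cfg), "moderate")
  expect_equal(distress_band(8, cfg), "high")
  expect_equal(distress_band(9, cfg), "high")
  expect_error(distress_band(11, cfg), "bounds")
})

test_that("a full session matches the hold-at-top tick oracle", {
  log <- run_session(h10, cfg, fixed_policy(10))
  traj <- log_suds_trajectory(log)
  ups <- traj[traj$kind == "suds_update", ]
  expect_equal(ups$t, c(120, 240, 360))
  expect_equal(ups$suds, c(9, 8, 7))
  expect_equal(traj$suds[nrow(traj)], 7)
  expect_equal(max(traj$t), 405)
  # closed form agrees at every recorded instant
  expect_equal(traj$suds,
               vapply(traj$t, function(t) oracle_hold_suds(10, t), 1))
})

test_that("decision points land exactly on the 45-second grid", {
  for (pol in list(fixed_policy(4), gradual_titration_policy(4),
                   random_policy(seed = 11))) {
    log <- run_session(h10, cfg, pol, seed = 5)
    expect_equal(decision_times(log), 45 * (0:8))
    expect_length(log_events(log, "decision_point"),
                  cfg$n_decision_points)
  }
})

test_that("SUDS stays in bounds and held tasks decay by the closed form under random play", {
  for (seed in 1:8) {
    log <- run_session(h10, cfg, random_policy(), seed = seed)
    traj <- log_suds_trajectory(log)
    expect_true(all(traj$suds >= cfg$suds_min & traj$suds <= cfg$suds_max))
    expect_true(validate_session_log(log))
  }
  # non-increasing trajectory and exact floor(t/120) decrement when held
  for (p in c(1, 5, 10)) {
    log <- run_session(h10, cfg, fixed_policy(p))
    traj <- log_suds_trajectory(log)
    expect_true(all(diff(traj$suds) <= 0))
    expect_equal(traj$suds,
                 vapply(traj$t, function(t) oracle_hold_suds(p, t), 1))
  }
})

test_that("identical seeds give identical decision sequences and events", {
  a <- run_session(h10, cfg, random_policy(), seed = 42, session_id = "x")
  b <- run_session(h10, cfg, random_policy(), seed = 42, session_id = "x")
  expect_identical(a$events, b$events)
  c <- run_session(h10, cfg, random_policy(), seed = 43, session_id = "x")
  expect_false(identical(decision_choices(a), decision_choices(c)) &&
                 identical(a$events, c$events))
})

test_that("every offered option set in generated logs respects the move radius", {
  for (seed in 1:5) {
    log <- run_session(h10, cfg, random_policy(), seed = seed)
    dps <- log_events(log, "decision_point")
    pos <- dps[[1]]$payload$choice
    for (ev in dps[-1]) {
      expect_setequal(ev$payload$options, allowed_moves(h10, pos))
      pos <- ev$payload$choice
    }
  }
})

test_that("repetition reset forgets everything except hierarchy and config", {
  log1 <- run_session(h10, cfg, random_policy(), seed = 1)
  ctx <- reset_for_repetition(log1)
  s <- start_session(ctx$hierarchy, ctx$config, 6)
  expect_equal(s$suds, 6L)
  expect_equal(s$clock, 0L)
  # mid-session reset is an error
  active <- start_session(h10, cfg, 3)
  expect_error(reset_for_repetition(as_session_log(active)), "incomplete")
})
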