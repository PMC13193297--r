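h10 <- default_h()
cfg <- session_config()

test_that("the rubric classifies the canonical cases", {
  th <- feedback_thresholds()
  expect_equal(classify_decision("decrease", -1, 5, th), "avoidant_retreat")
  expect_equal(classify_decision("same", 0, 8, th), "supported_persistence")
  expect_equal(classify_decision("increase", 1, 2, th), "well_timed_advance")
  expect_equal(classify_decision("increase", 2, 2, th), "aggressive_advance")
  expect_equal(classify_decision("increase", 1, 9, th), "aggressive_advance")
  expect_equal(classify_decision("same", 0, 2, th), "missed_opportunity")
  expect_equal(classify_decision("same", 0, 5, th), "acceptable")
  expect_equal(classify_decision("initial_select", 0, 6, th),
               "start_level_note")
  expect_error(classify_decision("wiggle", 0, 5, th), "unknown action")
})

test_that("classification is total and unique over the full action x SUDS grid", {
  th <- feedback_thresholds()
  cases <- expand.grid(
    action = c("increase", "decrease", "same", "initial_select"),
    magnitude = -2:2, suds = 0:10, stringsAsFactors = FALSE)
  cases <- cases[(cases$action == "increase" & cases$magnitude > 0) |
                   (cases$action == "decrease" & cases$magnitude < 0) |
                   (cases$action %in% c("same", "initial_select") &
                      cases$magnitude == 0), ]
  cls <- mapply(classify_decision, cases$action, cases$magnitude, cases$suds,
                MoreArgs = list(thresholds = th))
  expect_true(all(lengths(cls) == 1L | is.character(cls)))
  expect_true(all(cls %in% c("well_timed_advance", "supported_persistence",
                             "acceptable", "missed_opportunity",
                             "aggressive_advance", "avoidant_retreat",
                             "start_level_note")))
})

test_that("the hold-at-top report matches the tick oracle", {
  log <- run_session(h10, cfg, fixed_policy(10))
  rep <- build_report(log)
  expect_equal(nrow(rep$items), 9L)
  ups <- rep$trajectory[rep$trajectory$kind == "suds_update", ]
  expect_equal(ups$t, c(120, 240, 360))
  expect_equal(ups$suds, c(9, 8, 7))
  expect_equal(rep$items$classification[1], "start_level_note")
  expect_true(all(rep$items$classification[-1] %in%
                    c("supported_persistence", "acceptable")))
  expect_equal(rep$summary$peak_suds, 10)
  expect_equal(rep$summary$habituation_events, 3L)
  expect_equal(min(rep$trajectory$t), 0)
  expect_equal(max(rep$trajectory$t), 405)
})

test_that("reports are pure functions of logs and refuse truncated logs", {
  log <- run_session(h10, cfg, random_policy(), seed = 4)
  expect_identical(build_report(log), build_report(log))
  broken <- log
  broken$events <- broken$events[seq_len(length(broken$events) - 1L)]
  expect_error(build_report(broken), "session_end")
})

test_that("every complete log yields exactly one item per decision point", {
  for (seed in 1:4) {
    log <- run_session(h10, cfg, random_policy(), seed = seed)
    rep <- build_report(log)
    expect_equal(rep$items$decision_index, 1:9)
  }
})

test_that("trajectory rendering writes an image and one text row per decision", {
  log <- run_session(h10, cfg, fixed_policy(10))
  rep <- build_report(log)
  png_file <- tempfile(fileext = ".png")
  txt <- render_trajectory(rep, file = png_file, quiet = TRUE)
  expect_true(file.exists(png_file) && file.size(png_file) > 0)
  expect_length(txt, 9L)
  expect_error(render_trajectory(rep, file = tempfile(fileext = ".bmp"),
                                 quiet = TRUE),
               "unsupported image format")
})

test_that("feedback reports serialize to JSON", {
  log <- run_session(h10, cfg, gradual_titration_policy(4))
  rep <- build_report(log)
  f <- tempfile(fileext = ".json")
  write_feedback_report(rep, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(nrow(parsed$items), 9L)
  expect_equal(parsed$session_id, rep$session_id)
})
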