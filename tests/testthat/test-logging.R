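test_that("write/read round-trips randomized logs across all three schemas", {
  dir <- withr::local_tempdir()
  tasks <- c("inhibitory_control", "working_memory", "cognitive_flexibility")
  for (seed in 1:30) {
    task <- tasks[(seed %% 3L) + 1L]
    log <- random_log(task, n_rows = (seed %% 11L), seed = seed)
    f <- file.path(dir, sprintf("rt_%d.csv", seed))
    write_session_csv(log, f)
    back <- read_session_csv(f)
    expect_identical(back$rows, log$rows)
    expect_identical(back$header, log$header)
  }
})

test_that("the privacy guard refuses any column outside the declared schema", {
  log <- random_log("inhibitory_control", 3L, seed = 1L)
  log$rows$patient_name <- c("a", "b", "c")
  expect_error(write_session_csv(log, tempfile()),
               class = "ef_privacy_error")
})

test_that("malformed rows and unknown schema versions fail with located errors", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "log.csv")
  log <- random_log("working_memory", 4L, seed = 2L)
  write_session_csv(log, f)

  lines <- readLines(f)
  bad <- sub('"yes"', '"maybe"', lines)
  writeLines(bad, f)
  expect_error(read_session_csv(f), "row", class = "ef_parse_error")

  writeLines(sub("# schema_version: 1", "# schema_version: 99", lines), f)
  expect_error(read_session_csv(f), class = "ef_version_error")

  expect_error(read_session_csv(file.path(dir, "absent.csv")),
               class = "ef_io_error")
})

test_that("an empty data section reads back as a valid zero-row log", {
  f <- tempfile(fileext = ".csv")
  log <- random_log("cognitive_flexibility", 0L, seed = 3L)
  write_session_csv(log, f)
  back <- read_session_csv(f)
  expect_identical(nrow(back$rows), 0L)
  expect_identical(back$header$task, "cognitive_flexibility")
})

test_that("task summaries match a hand recomputation from raw rows", {
  # worked example: 1000/2000/3000 ms, 3 of 4 correct
  log <- random_log("inhibitory_control", 4L, seed = 9L)
  log$rows$response_time <- format_response_time(c(1000L, 2000L, 3000L, 2000L))
  log$rows$correct <- c("yes", "yes", "no", "yes")
  s <- summarize_task(log)
  expect_identical(s$proportion_correct, 0.75)
  expect_identical(s$avg_time_per_trial_s, 2)
  expect_identical(s$cumulative_time_s, 8)

  # oracle equivalence on random logs
  for (seed in 4:8) {
    log <- random_log("working_memory", 12L, seed = seed)
    s <- summarize_task(log)
    ms <- parse_response_time(log$rows$response_time)
    expect_identical(s$n_trials_completed, 12L)
    expect_equal(s$proportion_correct, mean(log$rows$correct == "yes"))
    expect_equal(s$avg_time_per_trial_s, round(mean(ms) / 1000, 3))
    expect_equal(s$cumulative_time_s, round(sum(ms) / 1000, 3))
  }
  empty <- random_log("working_memory", 0L, seed = 1L)
  expect_error(summarize_task(empty), class = "ef_validation_error")
})

test_that("questionnaire scoring totals within ranges and rejects out-of-range items", {
  expect_identical(score_ssq(rep(0, 16L)), 0L)
  expect_identical(score_ssq(rep(3, 16L)), 48L)
  expect_error(score_ssq(rep(4, 16L)), class = "ef_validation_error")
  expect_error(score_ssq(rep(1, 15L)), class = "ef_validation_error")

  q <- score_questionnaires(rep(1, 16L), borg = 8L,
                            vr_items = c(fun = 72, realism = 58.8))
  expect_identical(q$ssq_total, 16L)
  expect_identical(q$borg_rating, 8L)
  expect_error(score_questionnaires(rep(1, 16L), borg = 5L),
               class = "ef_validation_error")
  expect_error(score_questionnaires(rep(1, 16L), borg = 21L),
               class = "ef_validation_error")
  expect_error(score_questionnaires(rep(1, 16L), borg = 8L,
                                    vr_items = c(fun = 101)),
               "fun", class = "ef_validation_error")

  # weighted alternative scoring is monotone in the raw items
  k0 <- score_ssq(rep(0, 16L), method = "kennedy")
  k3 <- score_ssq(rep(3, 16L), method = "kennedy")
  expect_identical(k0$total, 0)
  expect_gt(k3$total, k0$total)
})

test_that("batch reports aggregate per task with zero spread for identical logs", {
  cfg <- session_config("B", "inhibitory_control", n_trials = 10L, seed = 2L)
  logs <- replicate(8L, run_session(cfg, fixed_rt_responder(perfect_rule)),
                    simplify = FALSE)
  rep8 <- batch_report(logs)
  expect_identical(nrow(rep8), 1L)
  expect_identical(rep8$avg_time_per_trial_sd_s, 0)
  expect_identical(rep8$percent_correct_sd, 0)
  expect_identical(rep8$percent_correct_mean, 100)

  # one row per distinct task present
  cfg2 <- session_config("B", "working_memory", n_trials = 10L, seed = 2L)
  both <- c(logs[1:2], list(run_session(cfg2, fixed_rt_responder(perfect_rule))))
  expect_identical(nrow(batch_report(both)), 2L)
})

test_that("span-limited cohorts score below ceiling on memory but not on the arrow task", {
  cfg <- session_config("C", "inhibitory_control", n_trials = 25L, seed = 5L)
  specs <- list(list(kind = "perfect"))
  span_specs <- list(list(kind = "span_limited", span = 3L),
                     list(kind = "span_limited", span = 5L))
  stroop_logs <- simulate_cohort(specs, cfg)
  cfg$task <- "working_memory"
  wm_logs <- simulate_cohort(span_specs, cfg)
  rep_all <- batch_report(c(stroop_logs, wm_logs))
  pc <- setNames(rep_all$percent_correct_mean, rep_all$task)
  expect_lt(pc[["working_memory"]], pc[["inhibitory_control"]])
})
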