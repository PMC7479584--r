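test_that("the staircase moves on the second consecutive outcome and resets its counters", {
  s <- staircase_state()
  s$consecutive_correct <- 1L
  up <- update_staircase(s, TRUE)
  expect_identical(up$current_length, 3L)
  expect_identical(up$consecutive_correct, 0L)
  expect_identical(up$consecutive_incorrect, 0L)

  s5 <- staircase_state(start_length = 5L)
  s5$consecutive_incorrect <- 1L
  down <- update_staircase(s5, FALSE)
  expect_identical(down$current_length, 4L)

  # a success zeroes the error counter and vice versa
  s <- staircase_state()
  s <- update_staircase(s, TRUE)
  s <- update_staircase(s, FALSE)
  expect_identical(s$consecutive_correct, 0L)
  expect_identical(s$consecutive_incorrect, 1L)
})

test_that("alternating outcomes never move the staircase", {
  # hand-simulated oracle: counters never reach 2, so length stays put
  s <- staircase_state()
  for (t in 1:20) s <- update_staircase(s, t %% 2L == 1L)
  expect_identical(s$current_length, 2L)
})

test_that("the staircase clamps at its floor and cap", {
  s <- staircase_state(start_length = 1L)
  s$consecutive_incorrect <- 1L
  s <- update_staircase(s, FALSE)
  expect_identical(s$current_length, 1L)
  expect_identical(s$consecutive_incorrect, 0L)

  s <- staircase_state(start_length = 20L, cap_length = 20L)
  s <- update_staircase(s, TRUE)
  s <- update_staircase(s, TRUE)
  expect_identical(s$current_length, 20L)
})

test_that("perfect and always-wrong responders follow the staircase closed forms", {
  # closed form for a perfect responder: min(2 + floor(t/2), cap)
  s <- staircase_state(cap_length = 60L)
  for (t in 1:50) {
    s <- update_staircase(s, TRUE)
    expect_identical(s$current_length, min(2L + t %/% 2L, 60L))
  }
  expect_identical(s$current_length, 27L)

  # always-incorrect: at the floor from t = 2 onward
  s <- staircase_state()
  s <- update_staircase(s, FALSE)
  expect_identical(s$current_length, 2L)
  for (t in 2:10) {
    s <- update_staircase(s, FALSE)
    expect_identical(s$current_length, 1L)
  }
})

test_that("door blocks are contiguous fifths with the remainder at the front", {
  expect_identical(door_for_trial(0L, 50L), 0L)
  expect_identical(door_for_trial(10L, 50L), 1L)
  expect_identical(door_for_trial(49L, 50L), 4L)
  # n = 12 splits as (3, 3, 2, 2, 2)
  doors <- vapply(0:11, door_for_trial, 0L, n_trials = 12L)
  expect_identical(as.integer(table(doors)), c(3L, 3L, 2L, 2L, 2L))
  expect_error(door_for_trial(12L, 12L), class = "ef_validation_error")
  expect_error(door_for_trial(-1L, 12L), class = "ef_validation_error")
})

test_that("generated sequences start at length 2, avoid adjacent repeats, and draw from the door's set", {
  cfg <- session_config("S01", "working_memory", n_trials = 50L, seed = 13L)
  st <- start_session(cfg)
  first <- present_trial(st)
  expect_identical(length(first$presented_sequence), 2L)

  log <- run_session(cfg, make_agent("span_limited", span = 5L,
                                     agent_seed = 13L))
  d <- as.data.frame(log)
  for (i in seq_len(nrow(d))) {
    ids <- as.integer(strsplit(d$presented_sequence[i], "-")[[1L]])
    expect_false(any(ids[-1L] == ids[-length(ids)]))
    expect_true(all((ids - 1L) %/% 8L == d$door[i]))
    expect_identical(length(ids), d$number_of_items[i])
    expect_identical(d$number_of_items[i], d$level[i])
  }
})

test_that("recall order is drawn 50/50 forward/backward", {
  cfg <- session_config("S01", "working_memory", n_trials = 10000L,
                        seed = 77L)
  st <- start_session(cfg)
  ord <- character(10000L)
  for (i in seq_len(10000L)) {
    st$trial_index <- i - 1L
    ord[i] <- generate_memory_trial(st)$order
  }
  expect_lt(abs(mean(ord == "forward") - 0.5), 0.02)
})

test_that("recall scoring is exact-match in the demanded order", {
  trial <- structure(list(trial_index = 0L, door_index = 0L,
                          order = "backward", presented_sequence = c(1L, 2L, 3L),
                          level = 3L), class = "ef_memory_trial")
  expect_true(score_memory(trial, c(3L, 2L, 1L), 100L)$correct)
  expect_false(score_memory(trial, c(1L, 2L, 3L), 100L)$correct)

  trial$order <- "forward"
  expect_true(score_memory(trial, c(1L, 2L, 3L), 100L)$correct)
  expect_false(score_memory(trial, c(1L, 3L, 2L), 100L)$correct)  # partial
  expect_false(score_memory(trial, c(1L, 2L), 100L)$correct)      # truncated
})

test_that("the sequence-length trajectory carries over across door boundaries", {
  # the same correctness stream replayed through a bare staircase (no
  # doors) must reproduce the in-session length trajectory exactly
  cfg <- session_config("S01", "working_memory", n_trials = 50L, seed = 29L)
  log <- run_session(cfg, make_agent("span_limited", span = 4L,
                                     lapse_rate = 0.1, agent_seed = 29L))
  d <- as.data.frame(log)
  s <- staircase_state()
  for (i in seq_len(nrow(d))) {
    expect_identical(d$level[i], s$current_length)
    s <- update_staircase(s, d$correct[i] == "yes")
  }
  # and the trajectory is not constant across the boundary region
  expect_gt(length(unique(d$level)), 1L)
})
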