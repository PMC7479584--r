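test_that("starting a session initializes at trial 0, presenting, with seeded RNG", {
  cfg <- session_config("S01", "working_memory", n_trials = 50L, seed = 7L)
  st <- start_session(cfg)
  expect_identical(st$trial_index, 0L)
  expect_identical(st$phase, "presenting")

  # identical configs present bit-identical first stimuli
  t1 <- present_trial(start_session(cfg))
  t2 <- present_trial(start_session(cfg))
  expect_identical(t1, t2)
})

test_that("invalid configurations are rejected up front", {
  expect_error(session_config("S01", "working_memory", n_trials = 0L),
               class = "ef_config_error")
  expect_error(session_config("S01", "telepathy"), class = "ef_config_error")
  expect_error(session_config("", "working_memory"), class = "ef_config_error")
  expect_error(session_config("S01", "working_memory", seed = -1L),
               class = "ef_config_error")
})

test_that("reset re-presents the same stimulus and logs the trial once", {
  for (task in c("inhibitory_control", "working_memory",
                 "cognitive_flexibility")) {
    cfg <- session_config("S01", task, n_trials = 5L, seed = 11L)
    st <- start_session(cfg)
    first <- present_trial(st)
    reset_trial(st)
    again <- present_trial(st)
    expect_identical(again, first)

    # completing after the reset leaves exactly one record for the index
    submit_response(st, perfect_rule(task, first, list()), 1000L)
    advance_trial(st)
    idx <- vapply(st$records, `[[`, 0L, "trial_index")
    expect_identical(sum(idx == 0L), 1L)
  }
})

test_that("control operations outside their phase raise control errors", {
  cfg <- session_config("S01", "inhibitory_control", n_trials = 1L, seed = 1L)
  st <- start_session(cfg)
  expect_error(submit_response(st, "up", 100L), class = "ef_control_error")
  trial <- present_trial(st)
  expect_error(advance_trial(st), class = "ef_control_error")
  submit_response(st, trial$arrow_direction, 100L)
  expect_error(reset_trial(st), class = "ef_control_error")
  advance_trial(st)
  expect_identical(st$phase, "finished")
  expect_error(reset_trial(st), class = "ef_control_error")
  expect_error(present_trial(st), class = "ef_control_error")
})

test_that("tutorials run the fixed short length and persist nothing", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "tut.csv")
  cfg <- session_config("S01", "inhibitory_control", n_trials = 50L,
                        seed = 3L, output_path = out)
  rep <- run_tutorial(cfg, fixed_rt_responder(perfect_rule))
  expect_identical(rep$n_trials, 5L)
  expect_identical(rep$accuracy, 1)
  expect_false(file.exists(out))
})

test_that("the battery advances through its fixed game order and stops at the end", {
  expect_identical(next_task("inhibitory_control"), "working_memory")
  expect_identical(next_task("working_memory"), "cognitive_flexibility")
  expect_error(next_task("cognitive_flexibility"), class = "ef_control_error")

  cfg <- session_config("S01", "inhibitory_control", seed = 9L)
  nxt <- next_task(cfg)
  expect_identical(nxt$task, "working_memory")
  expect_identical(nxt$seed, cfg$seed)
})

test_that("equal configurations and deterministic responders give byte-identical logs", {
  dir <- withr::local_tempdir()
  for (task in c("inhibitory_control", "working_memory",
                 "cognitive_flexibility")) {
    cfg <- session_config("S01", task, n_trials = 20L, seed = 5L)
    f1 <- file.path(dir, paste0(task, "_1.csv"))
    f2 <- file.path(dir, paste0(task, "_2.csv"))
    run_session(cfg, make_agent("perfect", rt_sigma = 0.3, agent_seed = 2L),
                path = f1)
    run_session(cfg, make_agent("perfect", rt_sigma = 0.3, agent_seed = 2L),
                path = f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("running a session never perturbs the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  run_session(session_config("S01", "working_memory", n_trials = 10L,
                             seed = 1L),
              make_agent("uniform_random", agent_seed = 4L))
  expect_identical(.Random.seed, before)
})

test_that("abandoning flushes an incomplete log that a resumed run completes identically", {
  dir <- withr::local_tempdir()
  for (task in c("inhibitory_control", "working_memory",
                 "cognitive_flexibility")) {
    cfg <- session_config("S01", task, n_trials = 12L, seed = 21L)
    # uninterrupted reference run with a deterministic responder
    full <- run_session(cfg, fixed_rt_responder(perfect_rule))

    # play 5 trials, hit Back, then resume from the flushed partial log
    st <- start_session(cfg)
    for (i in 1:5) {
      trial <- present_trial(st)
      submit_response(st, perfect_rule(task, trial, list()), 1000L)
      advance_trial(st)
    }
    part_path <- file.path(dir, paste0(task, "_part.csv"))
    part <- abandon_session(st, part_path)
    expect_false(part$header$complete)
    expect_identical(nrow(part$rows), 5L)

    resumed <- run_session(cfg, fixed_rt_responder(perfect_rule),
                           resume_from = part_path)
    expect_identical(resumed$rows, full$rows)
    expect_true(resumed$header$complete)
  }
})
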