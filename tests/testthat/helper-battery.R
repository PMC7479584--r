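# Shared fixtures: deterministic responders and independent oracles used
# across test files. Everything here is generated in code at test time.

# A responder built from a bare response rule with a fixed response time,
# bypassing the agent RT model so logs are fully deterministic.
fixed_rt_responder <- function(rule, rt_ms = 1000L) {
  function(task, trial, history) {
    list(response = rule(task, trial, history), elapsed_ms = rt_ms)
  }
}

perfect_rule <- function(task, trial, history) {
  switch(task,
    inhibitory_control = trial$arrow_direction,
    working_memory = if (trial$order == "forward") trial$presented_sequence
                     else rev(trial$presented_sequence),
    cognitive_flexibility =
      which(trial$targets[[trial$active_rule]] ==
              trial$stimulus[[trial$active_rule]]) - 1L)
}

# Deterministic always-wrong rule (wrong direction / corrupted recall /
# a target that does not match on the active rule).
wrong_rule <- function(task, trial, history) {
  switch(task,
    inhibitory_control = setdiff(DIRECTIONS, trial$arrow_direction)[1L],
    working_memory = {
      good <- perfect_rule(task, trial, history)
      if (length(good) >= 2L) c(good[2L], good[1L], good[-(1:2)]) else good + 1L
    },
    cognitive_flexibility = {
      hit <- which(trial$targets[[trial$active_rule]] ==
                     trial$stimulus[[trial$active_rule]])
      setdiff(1:4, hit)[1L] - 1L
    })
}

# Build a session log with randomized content directly (no session run):
# exercises the I/O layer over the full value space of each schema.
random_log <- function(task, n_rows, seed) {
  set.seed(seed)
  n_target <- n_rows
  n_rows <- max(1L, n_rows)  # build at least one row, slice afterwards
  yn <- function(n) sample(c("yes", "no"), n, replace = TRUE)
  rt <- function(n) format_response_time(sample.int(300000L, n) - 1L)
  rows <- switch(task,
    inhibitory_control = data.frame(
      location_of_arrow = sample(DIRECTIONS, n_rows, replace = TRUE),
      direction_of_arrow = sample(DIRECTIONS, n_rows, replace = TRUE),
      condition = sample(c("consistent", "inconsistent"), n_rows, replace = TRUE),
      response = sample(DIRECTIONS, n_rows, replace = TRUE),
      response_time = rt(n_rows),
      correct = yn(n_rows),
      trial = seq_len(n_rows) - 1L,
      character_id = sample(0:4, n_rows, replace = TRUE),
      stringsAsFactors = FALSE),
    working_memory = {
      lens <- sample(1:9, n_rows, replace = TRUE)
      seqs <- vapply(lens, function(l) paste(sample.int(40L, l), collapse = "-"), "")
      data.frame(
        order = sample(c("forward", "backward"), n_rows, replace = TRUE),
        number_of_items = lens,
        level = lens,
        response_time = rt(n_rows),
        correct = yn(n_rows),
        trial = seq_len(n_rows) - 1L,
        door = sample(0:4, n_rows, replace = TRUE),
        presented_sequence = seqs,
        response_sequence = vapply(lens, function(l)
          paste(sample.int(40L, l), collapse = "-"), ""),
        stringsAsFactors = FALSE)
    },
    cognitive_flexibility = data.frame(
      rule_applied = sample(SORT_RULES, n_rows, replace = TRUE),
      stimulus_amount = sample(1:4, n_rows, replace = TRUE),
      stimulus_color = sample(CARD_COLORS, n_rows, replace = TRUE),
      stimulus_shape = sample(CARD_SHAPES, n_rows, replace = TRUE),
      response = paste0(sample(0:3, n_rows, replace = TRUE), ":",
                        sample(c(SORT_RULES, "none"), n_rows, replace = TRUE)),
      response_time = rt(n_rows),
      correct = yn(n_rows),
      trial = seq_len(n_rows) - 1L,
      chosen_target = sample(0:3, n_rows, replace = TRUE),
      unambiguous = yn(n_rows),
      stringsAsFactors = FALSE))
  rows <- rows[seq_len(n_target), , drop = FALSE]
  row.names(rows) <- NULL
  session_log(
    header = list(study_id = sprintf("RND%d", seed), session_number = 1L,
                  task = task, seed = seed, schema_version = "1",
                  complete = TRUE),
    rows = rows)
}

# Independent brute-force run of the elimination strategy, coded from its
# definition with plain vectors over the step API; used as the oracle the
# built-in rule_elimination agent must match trial for trial.
oracle_elimination_run <- function(seed, n_trials = 50L) {
  cfg <- session_config("ORACLE", "cognitive_flexibility",
                        n_trials = n_trials, seed = seed)
  st <- start_session(cfg)
  consistent <- SORT_RULES
  last_used <- NULL
  correct <- logical(0L)
  while (st$phase != "finished") {
    trial <- present_trial(st)
    use <- consistent[1L]
    pick <- which(trial$targets[[use]] == trial$stimulus[[use]]) - 1L
    rec <- submit_response(st, pick, 1000L)
    if (rec$correct) {
      consistent <- use
    } else {
      consistent <- setdiff(consistent, use)
      if (length(consistent) == 0L) consistent <- setdiff(SORT_RULES, use)
    }
    correct <- c(correct, rec$correct)
    advance_trial(st)
  }
  correct
}

# Mean presented sequence length over the last `window` trials of
# working-memory sessions run by a span-limited agent, averaged over
# replicates; the parameter-recovery statistic for the staircase.
span_recovery_mean_length <- function(span, n_trials = 100L, n_reps = 50L,
                                      lapse = 0.05, base_seed = 0L,
                                      window = 40L) {
  means <- vapply(seq_len(n_reps), function(r) {
    cfg <- session_config("SPAN", "working_memory", n_trials = n_trials,
                          seed = base_seed + 31L * span + r)
    agent <- make_agent("span_limited", span = span, lapse_rate = lapse,
                        agent_seed = base_seed + 977L * span + r)
    log <- run_session(cfg, agent)
    lens <- log$rows$number_of_items
    mean(lens[(n_trials - window + 1L):n_trials])
  }, 0)
  mean(means)
}
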