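# Session configuration and the control-flow state machine.
#
# The state machine mirrors the therapist's five controls: Training runs
# the full configured trial count with data collection; Tutorial runs a
# short fixed-length version with nothing persisted; Reset interrupts the
# current trial and re-presents the *same* stimulus with any partial
# response discarded; Next advances through the fixed game order
# (inhibitory control -> working memory -> cognitive flexibility); Back
# abandons the session, flushing a partial log marked incomplete.
#
# Only the study id and session number identify a session; no other
# person-level data is ever carried or persisted.

TASKS <- c("inhibitory_control", "working_memory", "cognitive_flexibility")
TUTORIAL_LENGTH <- 5L
SCHEMA_VERSION <- "1"

#' Session configuration
#'
#' Everything needed to run (and exactly reproduce) one training
#' session of one game. Two sessions with equal configurations and
#' deterministic responders produce byte-identical logs.
#'
#' @param study_id opaque participant/study identifier; with
#'   `session_number` the only identifying fields ever persisted.
#' @param task one of `"inhibitory_control"`, `"working_memory"`,
#'   `"cognitive_flexibility"`.
#' @param session_number positive integer session counter.
#' @param n_trials trials per session in training mode (default 50, the
#'   count used in pilot deployments; tutorial mode always runs
#'   [TUTORIAL_LENGTH] trials instead).
#' @param mode `"training"` (logged) or `"tutorial"` (never logged).
#' @param seed non-negative integer seeding the session RNG stream.
#' @param output_path optional path; when set, [run_session()] writes
#'   the log there.
#' @param staircase working-memory staircase parameters, an
#'   [staircase_state()].
#' @param targets card-sort target set, an `ef_targets` data frame (see
#'   [default_target_set()]).
#' @return an `ef_config` list.
#' @export
session_config <- function(study_id, task, session_number = 1L,
                           n_trials = 50L,
                           mode = c("training", "tutorial"),
                           seed = 0L, output_path = NULL,
                           staircase = staircase_state(),
                           targets = default_target_set()) {
  mode <- match.arg(mode)
  if (!is.character(study_id) || length(study_id) != 1L || is.na(study_id) ||
      !nzchar(study_id)) {
    ef_stop("study_id must be a non-empty string", "ef_config_error")
  }
  if (length(task) != 1L || !task %in% TASKS) {
    ef_stop(sprintf("unknown task '%s'; expected one of: %s",
                    paste(task, collapse = ","), paste(TASKS, collapse = ", ")),
            "ef_config_error")
  }
  if (!is_count(n_trials)) {
    ef_stop("n_trials must be a positive integer", "ef_config_error")
  }
  if (!is_count(session_number)) {
    ef_stop("session_number must be a positive integer", "ef_config_error")
  }
  if (!is_count(seed, min = 0L)) {
    ef_stop("seed must be a non-negative integer", "ef_config_error")
  }
  stopifnot(inherits(staircase, "ef_staircase"))
  validate_target_set(targets)
  structure(
    list(study_id = study_id, session_number = as.integer(session_number),
         task = task, n_trials = as.integer(n_trials), mode = mode,
         seed = as.integer(seed), output_path = output_path,
         staircase = staircase, targets = targets),
    class = "ef_config")
}

#' @export
print.ef_config <- function(x, ...) {
  cat(sprintf("<session config> study %s, session %d: %s, %d trials, %s mode, seed %d\n",
              x$study_id, x$session_number, x$task, x$n_trials, x$mode,
              x$seed))
  invisible(x)
}

#' Start a session
#'
#' Initializes the session state machine at trial 0 in the `presenting`
#' phase, seeds the session RNG stream from the configuration, and
#' pre-draws the schedules that span the whole session (the balanced
#' Stroop congruency schedule or the 7-trial rule schedule). The state
#' is a mutable environment advanced in place by [present_trial()],
#' [submit_response()], [advance_trial()] and [reset_trial()];
#' [run_session()] drives the full loop.
#'
#' @param config an [session_config()].
#' @return an `ef_session` environment.
#' @export
start_session <- function(config) {
  stopifnot(inherits(config, "ef_config"))
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$trial_index <- 0L
  st$phase <- "presenting"
  st$rng <- rng_stream(config$seed)
  st$n_effective <- if (config$mode == "tutorial") TUTORIAL_LENGTH else config$n_trials
  st$records <- list()
  st$current_trial <- NULL
  switch(config$task,
    inhibitory_control = {
      st$condition_schedule <- balanced_condition_schedule(st$n_effective, st$rng)
    },
    working_memory = {
      st$stair <- config$staircase
    },
    cognitive_flexibility = {
      st$targets <- config$targets
      st$rule_schedule <- rule_schedule(st$n_effective, st$rng)
    })
  class(st) <- "ef_session"
  st
}

#' Step a session trial by trial
#'
#' `present_trial()` generates (or, after a reset, re-presents) the
#' current trial's stimulus and moves the session to `awaiting_response`;
#' `submit_response()` scores the response, records it, updates any
#' adaptive state and moves to `feedback`; `advance_trial()` moves to the
#' next trial or finishes the session; `reset_trial()` interrupts the
#' current trial, discarding any partial response, and re-presents the
#' *same* stimulus — the discarded attempt is never logged, so each
#' completed trial index appears exactly once in the log.
#'
#' @param state an `ef_session` from [start_session()].
#' @param response the task-appropriate response: a direction string
#'   (Stroop), an integer sequence (recall), or a 0-based target index
#'   (card sort).
#' @param elapsed_ms response time in milliseconds.
#' @return `present_trial()` the current trial object;
#'   `submit_response()` the scored record (its `correct` field is the
#'   feedback shown to the responder); the others the state, invisibly.
#' @export
present_trial <- function(state) {
  stopifnot(inherits(state, "ef_session"))
  if (state$phase != "presenting") {
    ef_stop(sprintf("cannot present a trial in phase '%s'", state$phase),
            "ef_control_error")
  }
  if (is.null(state$current_trial)) {
    state$current_trial <- switch(state$config$task,
      inhibitory_control = generate_stroop_trial(state),
      working_memory = generate_memory_trial(state),
      cognitive_flexibility = generate_sorting_trial(state))
  }
  state$phase <- "awaiting_response"
  state$current_trial
}

#' @rdname present_trial
#' @export
submit_response <- function(state, response, elapsed_ms) {
  stopifnot(inherits(state, "ef_session"))
  if (state$phase != "awaiting_response") {
    ef_stop(sprintf("cannot accept a response in phase '%s'", state$phase),
            "ef_control_error")
  }
  rec <- switch(state$config$task,
    inhibitory_control = score_stroop(state$current_trial, response, elapsed_ms),
    working_memory = score_memory(state$current_trial, response, elapsed_ms),
    cognitive_flexibility = score_sort(state$current_trial, response, elapsed_ms))
  if (state$config$task == "working_memory") {
    state$stair <- update_staircase(state$stair, rec$correct)
  }
  state$records[[length(state$records) + 1L]] <- rec
  state$phase <- "feedback"
  rec
}

#' @rdname present_trial
#' @export
advance_trial <- function(state) {
  stopifnot(inherits(state, "ef_session"))
  if (state$phase != "feedback") {
    ef_stop(sprintf("cannot advance in phase '%s'", state$phase),
            "ef_control_error")
  }
  state$trial_index <- state$trial_index + 1L
  state$current_trial <- NULL
  state$phase <- if (state$trial_index >= state$n_effective) "finished" else "presenting"
  invisible(state)
}

#' @rdname present_trial
#' @export
reset_trial <- function(state) {
  stopifnot(inherits(state, "ef_session"))
  if (!state$phase %in% c("presenting", "awaiting_response")) {
    ef_stop(sprintf("cannot reset a trial in phase '%s'", state$phase),
            "ef_control_error")
  }
  state$phase <- "presenting"
  invisible(state)
}

#' Run a full session against a responder
#'
#' Drives the state machine from the first trial to the last, asking
#' `responder` for a response to every stimulus, and returns the
#' completed session log. If the configuration (or `path`) names an
#' output file, the log is also written as CSV.
#'
#' Response timing comes from the responder: simulated agents draw it
#' from their own lognormal model, the interactive console responder
#' measures wall-clock time from presentation to committed response.
#'
#' @param config an [session_config()] in training mode.
#' @param responder a responder: a [make_agent()] object, or a plain
#'   `function(task, trial, history)` returning
#'   `list(response =, elapsed_ms =)`. `history` is the list of scored
#'   records so far, through which feedback-driven agents see the
#'   correctness of their previous choices.
#' @param path optional output path overriding the configuration's.
#' @param resume_from optional path to a previously written (possibly
#'   incomplete) log for the same configuration: the logged trials are
#'   replayed through the state machine, reconstructing RNG, staircase
#'   and rule state exactly, and the session continues from the first
#'   missing trial with continued trial numbering.
#' @return an `ef_session_log`.
#' @export
run_session <- function(config, responder, path = NULL, resume_from = NULL) {
  stopifnot(inherits(config, "ef_config"))
  if (config$mode != "training") {
    ef_stop("run_session() runs training mode; use run_tutorial() for tutorials",
            "ef_config_error")
  }
  responder <- as_responder(responder)
  state <- start_session(config)
  responder_reset(responder)
  if (!is.null(resume_from)) {
    replay_log_into(state, read_session_csv(resume_from))
  }
  while (state$phase != "finished") {
    trial <- present_trial(state)
    ans <- responder_respond(responder, config$task, trial, state$records)
    submit_response(state, ans$response, ans$elapsed_ms)
    advance_trial(state)
  }
  log <- session_log_from_state(state, complete = TRUE)
  out <- path %||% config$output_path
  if (!is.null(out)) write_session_csv(log, out)
  log
}

#' Run the tutorial version of a game
#'
#' A short fixed-length run (5 trials) demonstrating the game's
#' mechanics. Nothing is persisted — tutorial data is never collected —
#' and the returned report lives only in memory.
#'
#' @inheritParams run_session
#' @return an `ef_tutorial_report` list: `task`, `n_trials`, `accuracy`,
#'   and the scored `records`.
#' @export
run_tutorial <- function(config, responder) {
  stopifnot(inherits(config, "ef_config"))
  tut <- config
  tut$mode <- "tutorial"
  tut$output_path <- NULL
  responder <- as_responder(responder)
  state <- start_session(tut)
  responder_reset(responder)
  while (state$phase != "finished") {
    trial <- present_trial(state)
    ans <- responder_respond(responder, tut$task, trial, state$records)
    submit_response(state, ans$response, ans$elapsed_ms)
    advance_trial(state)
  }
  correct <- vapply(state$records, `[[`, logical(1L), "correct")
  structure(
    list(task = tut$task, n_trials = length(state$records),
         accuracy = mean(correct), records = state$records),
    class = "ef_tutorial_report")
}

#' Advance to the next game
#'
#' The battery runs its three games in the fixed narrative order
#' inhibitory control, working memory, cognitive flexibility; this
#' returns the configuration for the game after the one just finished,
#' with the same identifying fields and seed.
#'
#' @param x a finished `ef_session`, an `ef_config`, or a task name.
#' @return the `ef_config` for the next game (or the next task name when
#'   `x` is a task name).
#' @export
next_task <- function(x) {
  if (inherits(x, "ef_session")) x <- x$config
  if (inherits(x, "ef_config")) {
    nxt <- next_task(x$task)
    x$task <- nxt
    return(x)
  }
  i <- match(x, TASKS)
  if (is.na(i)) ef_stop(sprintf("unknown task '%s'", x), "ef_config_error")
  if (i == length(TASKS)) {
    ef_stop("already at the last game of the battery", "ef_control_error")
  }
  TASKS[i + 1L]
}

#' Abandon a session ("Back")
#'
#' Models returning to the home screen mid-session: the trials completed
#' so far are flushed to `path` as a log whose header marks it
#' incomplete, and the in-flight trial (if any) is discarded unlogged.
#' An incomplete log can later seed `resume_from` in [run_session()].
#'
#' @param state an `ef_session`.
#' @param path where to flush the partial log.
#' @return the partial `ef_session_log`, invisibly.
#' @export
abandon_session <- function(state, path) {
  stopifnot(inherits(state, "ef_session"))
  log <- session_log_from_state(state, complete = FALSE)
  write_session_csv(log, path)
  state$phase <- "finished"
  invisible(log)
}

# Replays a previously logged prefix of this session through the live
# state machine: stimuli are regenerated from the (identical) session
# seed and the logged responses are fed back in, which restores the RNG
# position, staircase counters and rule-schedule progress exactly.
replay_log_into <- function(state, log) {
  cfg <- state$config
  if (log$header$task != cfg$task || log$header$seed != cfg$seed) {
    ef_stop("resume log does not match the session's task and seed",
            "ef_config_error")
  }
  n <- nrow(log$rows)
  if (n > state$n_effective) {
    ef_stop("resume log has more trials than the session", "ef_config_error")
  }
  for (k in seq_len(n)) {
    row <- log$rows[k, ]
    present_trial(state)
    resp <- switch(cfg$task,
      inhibitory_control = row$response,
      working_memory = parse_id_sequence(row$response_sequence),
      cognitive_flexibility = row$chosen_target)
    submit_response(state, resp, parse_response_time(row$response_time))
    advance_trial(state)
  }
  invisible(state)
}

#' @export
print.ef_session <- function(x, ...) {
  cat(sprintf("<session> %s for study %s: trial %d/%d, phase %s\n",
              x$config$task, x$config$study_id, x$trial_index,
              x$n_effective, x$phase))
  invisible(x)
}

#' @export
print.ef_tutorial_report <- function(x, ...) {
  cat(sprintf("<tutorial> %s: %d trials, accuracy %.2f (data not collected)\n",
              x$task, x$n_trials, x$accuracy))
  invisible(x)
}
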