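# Game 2: adaptive sequence recall for working memory.
#
# Each trial shows an ordered sequence of characters on a door; the
# responder reproduces it in forward or reverse order (drawn 50/50 per
# trial). Difficulty adapts by a 2-up/2-down staircase on sequence length:
# two consecutive correct recalls lengthen the next sequence by one item,
# two consecutive errors shorten it by one. The session progresses through
# five doors (one fifth of the trials at each), each with its own set of 8
# characters; the staircase carries over across door boundaries so
# difficulty never resets mid-session.

DOOR_SET_SIZE <- 8L
N_DOORS <- 5L

#' Working-memory staircase state
#'
#' The adaptive state driving sequence length. `start_length` is the
#' length of the first trial's sequence (default 2). Two consecutive
#' correct responses raise `current_length` by 1 (capped at
#' `cap_length`); two consecutive incorrect responses lower it by 1
#' (floored at `floor_length`). A success zeroes the error counter and
#' vice versa, and any length change zeroes both counters, so three
#' correct responses in a row trigger exactly one increment, not two.
#'
#' @param start_length sequence length of the first trial.
#' @param floor_length smallest allowed length (>= 1).
#' @param cap_length largest allowed length.
#' @return an `ef_staircase` list.
#' @export
staircase_state <- function(start_length = 2L, floor_length = 1L,
                            cap_length = 20L) {
  if (!is_count(floor_length) || !is_count(start_length) ||
      !is_count(cap_length) ||
      floor_length > start_length || start_length > cap_length) {
    ef_stop("need floor_length <= start_length <= cap_length, all >= 1",
            "ef_config_error")
  }
  structure(
    list(current_length = as.integer(start_length),
         consecutive_correct = 0L, consecutive_incorrect = 0L,
         floor_length = as.integer(floor_length),
         start_length = as.integer(start_length),
         cap_length = as.integer(cap_length)),
    class = "ef_staircase")
}

#' Advance the staircase after one trial
#'
#' @param state an [staircase_state()].
#' @param correct logical outcome of the trial just scored.
#' @return the updated `ef_staircase`.
#' @examples
#' s <- staircase_state()
#' s <- update_staircase(s, TRUE)
#' update_staircase(s, TRUE)$current_length  # 3
#' @export
update_staircase <- function(state, correct) {
  stopifnot(inherits(state, "ef_staircase"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    state$consecutive_incorrect <- 0L
  } else {
    state$consecutive_incorrect <- state$consecutive_incorrect + 1L
    state$consecutive_correct <- 0L
  }
  if (state$consecutive_correct == 2L) {
    state$current_length <- min(state$current_length + 1L, state$cap_length)
    state$consecutive_correct <- 0L
    state$consecutive_incorrect <- 0L
  } else if (state$consecutive_incorrect == 2L) {
    state$current_length <- max(state$current_length - 1L, state$floor_length)
    state$consecutive_correct <- 0L
    state$consecutive_incorrect <- 0L
  }
  state
}

door_block_sizes <- function(n_trials) {
  base <- n_trials %/% N_DOORS
  sizes <- rep(base, N_DOORS)
  rem <- n_trials %% N_DOORS
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}

#' Door for a trial
#'
#' The session is split into five contiguous blocks, one per door, each
#' holding one fifth of the trials; when `n_trials` is not a multiple of
#' 5 the remainder goes to the earliest doors, so block sizes never
#' differ by more than 1.
#'
#' @param trial_index 0-based trial index.
#' @param n_trials total trials in the session.
#' @return 0-based door index in `0..4`.
#' @export
door_for_trial <- function(trial_index, n_trials) {
  if (!is_count(n_trials)) {
    ef_stop("n_trials must be a positive integer", "ef_validation_error")
  }
  if (!is_count(trial_index, min = 0L) || trial_index >= n_trials) {
    ef_stop("trial_index must lie in [0, n_trials)", "ef_validation_error")
  }
  sizes <- door_block_sizes(as.integer(n_trials))
  as.integer(rep.int(0:(N_DOORS - 1L), sizes)[trial_index + 1L])
}

# Character identifiers are globally unique per door: door d presents
# characters 8d+1 .. 8d+8.
door_characters <- function(door_index) {
  DOOR_SET_SIZE * as.integer(door_index) + seq_len(DOOR_SET_SIZE)
}

#' Generate one sequence-recall trial
#'
#' Draws a sequence of the staircase's current length from the current
#' door's 8-character set, sampling with replacement but never repeating
#' a character in adjacent positions (an immediate repeat is visually
#' ambiguous in a recall display). Recall order is drawn 50/50
#' forward/backward.
#'
#' @param state an active working-memory session.
#' @param stair the staircase state to read the length from; defaults to
#'   the session's own.
#' @return an `ef_memory_trial` list: `trial_index`, `door_index`,
#'   `order`, `presented_sequence`, `level`.
#' @export
generate_memory_trial <- function(state, stair = state$stair) {
  stopifnot(inherits(state, "ef_session"), inherits(stair, "ef_staircase"))
  if (state$config$task != "working_memory") {
    ef_stop("session is not running the working-memory task",
            "ef_control_error")
  }
  i <- state$trial_index
  door <- door_for_trial(i, state$n_effective)
  chars <- door_characters(door)
  len <- stair$current_length
  seqn <- integer(len)
  seqn[1L] <- rng_sample(state$rng, chars)
  if (len > 1L) {
    for (k in 2:len) {
      seqn[k] <- rng_sample(state$rng, setdiff(chars, seqn[k - 1L]))
    }
  }
  ord <- rng_sample(state$rng, c("forward", "backward"))
  structure(
    list(trial_index = i, door_index = door, order = ord,
         presented_sequence = seqn, level = len),
    class = "ef_memory_trial")
}

#' Score a sequence-recall response
#'
#' Exact-match scoring: the response is correct only if it reproduces
#' the presented sequence in full — in presentation order on `forward`
#' trials, reversed on `backward` trials. Partial matches are incorrect.
#'
#' @param trial a trial from [generate_memory_trial()].
#' @param response integer vector of recalled character identifiers.
#' @param elapsed_ms response time in milliseconds.
#' @return the trial fields plus `response_sequence`, `elapsed_ms`,
#'   `correct`.
#' @export
score_memory <- function(trial, response, elapsed_ms) {
  stopifnot(inherits(trial, "ef_memory_trial"))
  expected <- if (trial$order == "forward") {
    trial$presented_sequence
  } else {
    rev(trial$presented_sequence)
  }
  rec <- unclass(trial)
  rec$response_sequence <- as.integer(response)
  rec$elapsed_ms <- as.integer(elapsed_ms)
  rec$correct <- identical(as.integer(response), as.integer(expected))
  structure(rec, class = "ef_memory_record")
}
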