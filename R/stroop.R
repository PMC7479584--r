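# Game 1: Spatial Stroop for inhibitory control.
#
# An arrow appears at one of four positions relative to an opponent
# character (above, below, left, right) and points in one of the same four
# directions. The correct response is always the arrow's pointing
# direction; its position is a spatial lure that may agree (consistent
# trial) or conflict (inconsistent trial) with it. Congruency is balanced
# 50/50 within a session via a shuffled schedule rather than independent
# per-trial draws, the usual design for conflict paradigms (independent
# uniform sampling over position x direction would give only 25%
# consistent trials).

#' Stimulus directions
#'
#' The four values used for both arrow position and arrow direction.
#' @export
DIRECTIONS <- c("up", "down", "left", "right")

assert_direction <- function(x, what = "direction") {
  if (!is.character(x) || !all(x %in% DIRECTIONS)) {
    ef_stop(sprintf("%s must be one of: %s", what,
                    paste(DIRECTIONS, collapse = ", ")),
            "ef_validation_error")
  }
  invisible(x)
}

#' Classify Stroop congruency
#'
#' A trial is `consistent` when the arrow's position relative to the
#' character equals its pointing direction, `inconsistent` otherwise.
#' Vectorized over both arguments.
#'
#' @param position,direction vectors over the four [DIRECTIONS].
#' @return character vector of `"consistent"`/`"inconsistent"`.
#' @examples
#' classify_condition("right", "up")  # inconsistent
#' classify_condition("up", "up")     # consistent
#' @export
classify_condition <- function(position, direction) {
  assert_direction(position, "position")
  assert_direction(direction, "direction")
  ifelse(position == direction, "consistent", "inconsistent")
}

#' Opponent character for a trial
#'
#' The narrative frames the session as a series of battles; the opponent
#' changes every `period` trials (default 10, so a standard 50-trial
#' session progresses through 5 opponents).
#'
#' @param trial_index 0-based trial index.
#' @param period trials per opponent.
#' @return 0-based opponent id.
#' @export
character_for_trial <- function(trial_index, period = 10L) {
  if (!all(vapply(trial_index, is_count, logical(1L), min = 0L))) {
    ef_stop("trial_index must be a non-negative integer", "ef_validation_error")
  }
  as.integer(trial_index) %/% as.integer(period)
}

# Balanced congruency schedule: floor(n/2) of each condition plus, for odd
# n, one extra drawn 50/50; the whole schedule is then shuffled. Guarantees
# |#consistent - #inconsistent| <= 1 in every session.
balanced_condition_schedule <- function(n, rng) {
  base <- rep(c("consistent", "inconsistent"), n %/% 2L)
  if (n %% 2L == 1L) {
    base <- c(base, rng_sample(rng, c("consistent", "inconsistent")))
  }
  rng_shuffle(rng, base)
}

#' Generate one Spatial Stroop trial
#'
#' Draws the arrow position uniformly over the four placements, takes the
#' trial's congruency condition from the session's balanced schedule, and
#' — on inconsistent trials — draws the pointing direction uniformly over
#' the three non-matching values. All draws come from the session RNG
#' stream, so equal session configurations yield identical stimuli.
#'
#' @param state an active session (see [start_session()]) running the
#'   inhibitory-control task.
#' @return a `ef_stroop_trial` list: `trial_index`, `arrow_position`,
#'   `arrow_direction`, `condition`, `character_id`.
#' @export
generate_stroop_trial <- function(state) {
  stopifnot(inherits(state, "ef_session"))
  if (state$config$task != "inhibitory_control") {
    ef_stop("session is not running the inhibitory-control task",
            "ef_control_error")
  }
  i <- state$trial_index
  position <- rng_sample(state$rng, DIRECTIONS)
  condition <- state$condition_schedule[i + 1L]
  direction <- if (condition == "consistent") {
    position
  } else {
    rng_sample(state$rng, setdiff(DIRECTIONS, position))
  }
  structure(
    list(trial_index = i, arrow_position = position,
         arrow_direction = direction, condition = condition,
         character_id = character_for_trial(i)),
    class = "ef_stroop_trial")
}

#' Score a Spatial Stroop response
#'
#' The response is correct exactly when it equals the arrow's pointing
#' direction; the positional lure is never rewarded.
#'
#' @param trial a trial from [generate_stroop_trial()].
#' @param response one of [DIRECTIONS].
#' @param elapsed_ms response time in milliseconds.
#' @return the trial fields plus `response`, `elapsed_ms`, `correct`.
#' @export
score_stroop <- function(trial, response, elapsed_ms) {
  stopifnot(inherits(trial, "ef_stroop_trial"))
  assert_direction(response, "response")
  rec <- unclass(trial)
  rec$response <- response
  rec$elapsed_ms <- as.integer(elapsed_ms)
  rec$correct <- identical(response, trial$arrow_direction)
  structure(rec, class = "ef_stroop_record")
}
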