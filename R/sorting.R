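# Game 3: rule-switching card sort for cognitive flexibility.
#
# A card-sorting paradigm in the Wisconsin Card Sorting tradition: a
# stimulus card (color, shape, amount) must be matched to one of four
# fixed target cards under an undisclosed rule — match by color, by
# shape, or by amount. The rule changes every 7 trials without warning;
# only the correct/incorrect feedback after each choice lets the
# responder infer the active rule. Targets satisfy the key-card
# property (all four colors, shapes and amounts distinct across
# targets) so every stimulus matches exactly one target per dimension,
# and stimuli are rejection-sampled to be unambiguous (their three
# dimension-matching targets are three different cards), which keeps
# feedback informative about the rule.

#' Sorting rules and stimulus attributes
#'
#' The three matching rules, and the four levels of each card attribute.
#' @export
SORT_RULES <- c("color", "shape", "amount")

#' @rdname SORT_RULES
#' @export
CARD_COLORS <- c("red", "blue", "green", "yellow")

#' @rdname SORT_RULES
#' @export
CARD_SHAPES <- c("circle", "square", "triangle", "star")

RULE_BLOCK_LENGTH <- 7L

#' Default target cards
#'
#' A fixed Latin-square assignment — target i has the i-th color, the
#' i-th shape and amount i — shipped as a constant so that sessions are
#' comparable across runs; any set satisfying the key-card property may
#' be substituted via the session configuration.
#'
#' @return an `ef_targets` data frame with columns `color`, `shape`,
#'   `amount` and one row per target.
#' @export
default_target_set <- function() {
  structure(
    data.frame(color = CARD_COLORS, shape = CARD_SHAPES, amount = 1:4,
               stringsAsFactors = FALSE),
    class = c("ef_targets", "data.frame"))
}

validate_target_set <- function(targets) {
  ok <- is.data.frame(targets) && nrow(targets) == 4L &&
    all(c("color", "shape", "amount") %in% names(targets)) &&
    !anyDuplicated(targets$color) && !anyDuplicated(targets$shape) &&
    !anyDuplicated(targets$amount) &&
    all(targets$color %in% CARD_COLORS) &&
    all(targets$shape %in% CARD_SHAPES) &&
    all(targets$amount %in% 1:4)
  if (!ok) {
    ef_stop(paste("target set must contain 4 cards with pairwise-distinct",
                  "colors, shapes and amounts (key-card property)"),
            "ef_config_error")
  }
  invisible(targets)
}

#' Rule schedule for a session
#'
#' The active rule is constant within each block of 7 trials and changes
#' at every block boundary: the first block's rule is drawn uniformly
#' over the three rules, each subsequent block's uniformly over the two
#' rules not currently active (the rule always actually changes). A
#' session of `n_trials` has `ceiling(n_trials / 7)` blocks; the last
#' may be shorter.
#'
#' @param n_trials session length.
#' @param rng a session RNG stream.
#' @return character vector of length `n_trials`, the active rule per
#'   trial, with the per-block rules as attribute `"block_rules"`.
#' @export
rule_schedule <- function(n_trials, rng) {
  if (!is_count(n_trials)) {
    ef_stop("n_trials must be a positive integer", "ef_validation_error")
  }
  n_blocks <- ceiling(n_trials / RULE_BLOCK_LENGTH)
  blocks <- character(n_blocks)
  blocks[1L] <- rng_sample(rng, SORT_RULES)
  if (n_blocks > 1L) {
    for (b in 2:n_blocks) {
      blocks[b] <- rng_sample(rng, setdiff(SORT_RULES, blocks[b - 1L]))
    }
  }
  per_trial <- rep(blocks, each = RULE_BLOCK_LENGTH)[seq_len(n_trials)]
  attr(per_trial, "block_rules") <- blocks
  per_trial
}

# Index (1..4) of the target matching the stimulus on one dimension.
# Exactly one match exists whenever the targets satisfy the key-card
# property.
matching_target <- function(targets, stimulus, rule) {
  which(targets[[rule]] == stimulus[[rule]])
}

stimulus_is_unambiguous <- function(targets, stimulus) {
  m <- vapply(SORT_RULES, function(r) matching_target(targets, stimulus, r),
              integer(1L))
  length(unique(m)) == 3L
}

#' Generate one card-sort trial
#'
#' Draws a stimulus uniformly from the 4 x 4 x 4 attribute product and
#' redraws until it is unambiguous with respect to the session's target
#' set. The active rule comes from the session's rule schedule.
#'
#' @param state an active cognitive-flexibility session.
#' @param targets target set; defaults to the session's.
#' @return an `ef_sorting_trial` list: `trial_index`, `stimulus` (list
#'   with `color`, `shape`, `amount`), `active_rule`, `unambiguous`,
#'   `targets`.
#' @export
generate_sorting_trial <- function(state, targets = state$targets) {
  stopifnot(inherits(state, "ef_session"))
  if (state$config$task != "cognitive_flexibility") {
    ef_stop("session is not running the cognitive-flexibility task",
            "ef_control_error")
  }
  validate_target_set(targets)
  i <- state$trial_index
  for (attempt in seq_len(1000L)) {
    stim <- list(color = rng_sample(state$rng, CARD_COLORS),
                 shape = rng_sample(state$rng, CARD_SHAPES),
                 amount = rng_sample(state$rng, 1:4))
    if (stimulus_is_unambiguous(targets, stim)) {
      return(structure(
        list(trial_index = i, stimulus = stim,
             active_rule = state$rule_schedule[i + 1L],
             unambiguous = TRUE, targets = targets),
        class = "ef_sorting_trial"))
    }
  }
  ef_stop("target set admits no unambiguous stimulus", "ef_config_error")
}

#' Score a card-sort choice
#'
#' The choice is correct when the chosen target's attribute on the
#' active rule's dimension equals the stimulus's. The correctness bit is
#' the feedback the responder uses to infer the (undisclosed) rule.
#'
#' @param trial a trial from [generate_sorting_trial()].
#' @param chosen_target 0-based target index in `0..3`.
#' @param elapsed_ms response time in milliseconds.
#' @return the trial fields plus `chosen_target`, `matched_dimension`
#'   (the dimension on which the chosen target matches the stimulus, or
#'   `"none"`), `elapsed_ms`, `correct`.
#' @export
score_sort <- function(trial, chosen_target, elapsed_ms) {
  stopifnot(inherits(trial, "ef_sorting_trial"))
  if (!is_count(chosen_target, min = 0L) || chosen_target > 3L) {
    ef_stop("chosen_target must lie in 0..3", "ef_validation_error")
  }
  chosen_target <- as.integer(chosen_target)
  row <- chosen_target + 1L
  matched <- SORT_RULES[vapply(SORT_RULES, function(r) {
    trial$targets[[r]][row] == trial$stimulus[[r]]
  }, logical(1L))]
  rec <- unclass(trial)
  rec$chosen_target <- chosen_target
  rec$matched_dimension <- if (length(matched) == 0L) "none" else matched[1L]
  rec$elapsed_ms <- as.integer(elapsed_ms)
  rec$correct <-
    trial$targets[[trial$active_rule]][row] == trial$stimulus[[trial$active_rule]]
  structure(rec, class = "ef_sorting_record")
}
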