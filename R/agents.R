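# Simulated responders.
#
# Parameterized synthetic agents stand in for child participants so the
# battery can be validated without human data: a perfect responder, a
# uniform guesser, a Stroop position-lure responder, a span-limited
# recaller, a feedback-driven rule-elimination sorter, and a
# perseverative sorter. Each agent owns its own RNG stream (independent
# of the session's stimulus stream) and a lognormal response-time model —
# the standard positively skewed RT family — whose parameters are
# user-set, never fitted to any human data.

AGENT_KINDS <- c("perfect", "uniform_random", "stroop_lure", "span_limited",
                 "rule_elimination", "perseverative")

#' Create a simulated responder
#'
#' @param kind one of `"perfect"` (answers every task's correctness rule
#'   exactly), `"uniform_random"` (guesses uniformly over the response
#'   options), `"stroop_lure"` (answers with the arrow's *position* with
#'   probability `p_lure`, otherwise its direction; Stroop only),
#'   `"span_limited"` (recalls correctly iff the sequence is no longer
#'   than `span` and no lapse occurs; working memory only),
#'   `"rule_elimination"` (maintains the set of sorting rules consistent
#'   with all feedback since its last error, discards the rule it was
#'   using on an error, and always plays the lowest-indexed consistent
#'   rule; card sort only), `"perseverative"` (repeats its previous
#'   rule choice with probability `perseveration_prob`, otherwise
#'   switches to one of the other two rules at random; card sort only).
#' @param span span-limited capacity, a positive integer.
#' @param lapse_rate probability in `[0,1]` of an error even below span.
#' @param p_lure probability in `[0,1]` of following the positional lure.
#' @param perseveration_prob probability in `[0,1]` of repeating the
#'   previous rule.
#' @param rt_median_ms,rt_sigma lognormal response-time model: the
#'   median in milliseconds and the log-scale sigma (`rt_sigma = 0`
#'   makes timing deterministic at the median).
#' @param agent_seed seed of the agent's own RNG stream, independent of
#'   the session seed.
#' @return an `ef_responder` that [run_session()] can drive.
#' @export
make_agent <- function(kind, span = 4L, lapse_rate = 0, p_lure = 1,
                       perseveration_prob = 0.9, rt_median_ms = 1500,
                       rt_sigma = 0.35, agent_seed = 0L) {
  if (length(kind) != 1L || !kind %in% AGENT_KINDS) {
    ef_stop(sprintf("unknown agent kind '%s'; expected one of: %s",
                    paste(kind, collapse = ","),
                    paste(AGENT_KINDS, collapse = ", ")),
            "ef_config_error")
  }
  probs <- c(lapse_rate = lapse_rate, p_lure = p_lure,
             perseveration_prob = perseveration_prob)
  if (any(probs < 0 | probs > 1)) {
    ef_stop("agent probabilities must lie in [0, 1]", "ef_config_error")
  }
  if (!is_count(span)) {
    ef_stop("span must be a positive integer", "ef_config_error")
  }
  if (rt_median_ms <= 0 || rt_sigma < 0) {
    ef_stop("rt_median_ms must be positive and rt_sigma non-negative",
            "ef_config_error")
  }
  a <- new.env(parent = emptyenv())
  a$kind <- kind
  a$params <- list(span = as.integer(span), lapse_rate = lapse_rate,
                   p_lure = p_lure, perseveration_prob = perseveration_prob,
                   rt_median_ms = rt_median_ms, rt_sigma = rt_sigma)
  a$seed <- as.integer(agent_seed)
  a$rng <- rng_stream(a$seed)
  a$mem <- new.env(parent = emptyenv())
  class(a) <- "ef_responder"
  a
}

#' @export
print.ef_responder <- function(x, ...) {
  cat(sprintf("<responder> %s (agent seed %d)\n", x$kind, x$seed))
  invisible(x)
}

# Accept either a built agent or a plain function(task, trial, history).
as_responder <- function(x) {
  if (inherits(x, "ef_responder")) return(x)
  if (is.function(x)) {
    a <- new.env(parent = emptyenv())
    a$kind <- "custom"
    a$fn <- x
    a$mem <- new.env(parent = emptyenv())
    class(a) <- "ef_responder"
    return(a)
  }
  ef_stop("responder must be an ef_responder or a function", "ef_config_error")
}

# Fresh within-session memory and a re-seeded RNG stream at session
# start: agents are stateless across sessions.
responder_reset <- function(a) {
  a$mem <- new.env(parent = emptyenv())
  if (!is.null(a$seed)) a$rng <- rng_stream(a$seed)
  invisible(a)
}

responder_rt <- function(a) {
  rng_rt_ms(a$rng, a$params$rt_median_ms, a$params$rt_sigma)
}

responder_respond <- function(a, task, trial, history) {
  if (a$kind == "custom") return(a$fn(task, trial, history))
  response <- switch(a$kind,
    perfect = respond_perfect(task, trial),
    uniform_random = respond_uniform(a, task, trial),
    stroop_lure = respond_lure(a, task, trial),
    span_limited = respond_span(a, task, trial),
    rule_elimination = respond_elimination(a, task, trial, history),
    perseverative = respond_perseverative(a, task, trial))
  list(response = response, elapsed_ms = responder_rt(a))
}

expected_recall <- function(trial) {
  if (trial$order == "forward") trial$presented_sequence else rev(trial$presented_sequence)
}

respond_perfect <- function(task, trial) {
  switch(task,
    inhibitory_control = trial$arrow_direction,
    working_memory = expected_recall(trial),
    cognitive_flexibility =
      matching_target(trial$targets, trial$stimulus, trial$active_rule) - 1L)
}

respond_uniform <- function(a, task, trial) {
  switch(task,
    inhibitory_control = rng_sample(a$rng, DIRECTIONS),
    working_memory = rng_sample(a$rng, door_characters(trial$door_index),
                                size = length(trial$presented_sequence),
                                replace = TRUE),
    cognitive_flexibility = rng_sample(a$rng, 0:3))
}

respond_lure <- function(a, task, trial) {
  if (task != "inhibitory_control") {
    ef_stop("stroop_lure agent only plays the inhibitory-control task",
            "ef_config_error")
  }
  if (rng_runif(a$rng) <= a$params$p_lure) {
    trial$arrow_position
  } else {
    trial$arrow_direction
  }
}

# Correct iff the sequence fits within span and no lapse fires; a wrong
# answer is the correct one corrupted so it never matches by accident.
respond_span <- function(a, task, trial) {
  if (task != "working_memory") {
    ef_stop("span_limited agent only plays the working-memory task",
            "ef_config_error")
  }
  good <- expected_recall(trial)
  fits <- length(good) <= a$params$span
  lapse <- a$params$lapse_rate > 0 && rng_runif(a$rng) < a$params$lapse_rate
  if (fits && !lapse) return(good)
  corrupt_recall(a, good, trial$door_index)
}

corrupt_recall <- function(a, good, door_index) {
  bad <- good
  if (length(bad) >= 2L) {
    # adjacent items always differ, so swapping the first two changes it
    bad[1:2] <- bad[2:1]
  } else {
    bad <- rng_sample(a$rng, setdiff(door_characters(door_index), good))
  }
  bad
}

# Elimination strategy: plays the lowest-indexed rule in its consistent
# set. With unambiguous stimuli a correct trial identifies the played
# rule as active (set collapses to it); an error removes the played rule
# from the set, and an error that empties the set starts over from the
# two rules other than the one just disproved. At a rule change this
# costs at most two errors before the new rule is found.
respond_elimination <- function(a, task, trial, history) {
  if (task != "cognitive_flexibility") {
    ef_stop("rule_elimination agent only plays the cognitive-flexibility task",
            "ef_config_error")
  }
  mem <- a$mem
  if (is.null(mem$consistent)) {
    mem$consistent <- SORT_RULES
    mem$seen <- 0L
  }
  if (length(history) > mem$seen) {
    # feedback accrued since our last choice; only our own last choice is
    # informative (resumed sessions may replay history the agent never saw)
    if (!is.null(mem$last_used)) {
      last <- history[[length(history)]]
      if (last$correct) {
        mem$consistent <- mem$last_used
      } else {
        mem$consistent <- setdiff(mem$consistent, mem$last_used)
        if (length(mem$consistent) == 0L) {
          mem$consistent <- setdiff(SORT_RULES, mem$last_used)
        }
      }
    }
    mem$seen <- length(history)
  }
  use <- mem$consistent[1L]
  mem$last_used <- use
  matching_target(trial$targets, trial$stimulus, use) - 1L
}

respond_perseverative <- function(a, task, trial) {
  if (task != "cognitive_flexibility") {
    ef_stop("perseverative agent only plays the cognitive-flexibility task",
            "ef_config_error")
  }
  mem <- a$mem
  use <- if (is.null(mem$last_rule)) {
    rng_sample(a$rng, SORT_RULES)
  } else if (rng_runif(a$rng) < a$params$perseveration_prob) {
    mem$last_rule
  } else {
    rng_sample(a$rng, setdiff(SORT_RULES, mem$last_rule))
  }
  mem$last_rule <- use
  matching_target(trial$targets, trial$stimulus, use) - 1L
}

#' Simulate a cohort of agents
#'
#' Runs independent seeded sessions for every (agent, replicate) pair
#' under a shared base configuration, emulating a pilot cohort at scale.
#' Session and agent seeds are derived deterministically from the base
#' configuration's seed and each spec's `agent_seed`, so the whole
#' cohort is reproducible from the inputs. The logs are identical in
#' schema to human session logs.
#'
#' @param agent_specs list of argument lists for [make_agent()], e.g.
#'   `list(list(kind = "perfect"), list(kind = "span_limited", span = 4))`.
#' @param config base [session_config()]; each run gets a derived seed
#'   and a study id suffixed with the agent and replicate indices.
#' @param n_replicates sessions per agent.
#' @return list of `ef_session_log`, one per (agent, replicate).
#' @export
simulate_cohort <- function(agent_specs, config, n_replicates = 1L) {
  stopifnot(inherits(config, "ef_config"), is_count(n_replicates))
  logs <- vector("list", length(agent_specs) * n_replicates)
  k <- 0L
  for (ai in seq_along(agent_specs)) {
    spec <- agent_specs[[ai]]
    for (r in seq_len(n_replicates)) {
      spec_r <- spec
      spec_r$agent_seed <- (spec$agent_seed %||% 0L) + 1000L * ai + r
      agent <- do.call(make_agent, spec_r)
      cfg <- config
      cfg$seed <- config$seed + 7919L * ai + r
      cfg$study_id <- sprintf("%s_a%d_r%d", config$study_id, ai, r)
      cfg$output_path <- NULL
      k <- k + 1L
      logs[[k]] <- run_session(cfg, agent)
    }
  }
  logs
}

#' Interactive console responder
#'
#' A text-mode responder for running a session by hand at the R console
#' or through the command-line runner: prints each stimulus, reads the
#' response from `stdin`, and measures response time as wall-clock from
#' presentation to committed input.
#'
#' @return an `ef_responder`.
#' @export
console_responder <- function() {
  as_responder(function(task, trial, history) {
    t0 <- Sys.time()
    cat(describe_trial(task, trial), "\n")
    line <- readline("response> ")
    elapsed <- max(1L, as.integer(round(
      as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000)))
    response <- switch(task,
      inhibitory_control = trimws(line),
      working_memory = as.integer(strsplit(trimws(line), "[ ,-]+")[[1L]]),
      cognitive_flexibility = as.integer(trimws(line)))
    list(response = response, elapsed_ms = elapsed)
  })
}

describe_trial <- function(task, trial) {
  switch(task,
    inhibitory_control = sprintf(
      "[trial %d] arrow at the %s of character %d — enter the direction it POINTS (up/down/left/right)",
      trial$trial_index, trial$arrow_position, trial$character_id),
    working_memory = sprintf(
      "[trial %d] door %d shows: %s — enter the sequence in %s order (space-separated ids)",
      trial$trial_index, trial$door_index,
      paste(trial$presented_sequence, collapse = " "), trial$order),
    cognitive_flexibility = sprintf(
      "[trial %d] card: %d %s %s(s) — choose a target 0-3 (targets: %s)",
      trial$trial_index, trial$stimulus$amount, trial$stimulus$color,
      trial$stimulus$shape,
      paste(sprintf("%d=%d %s %s", 0:3, trial$targets$amount,
                    trial$targets$color, trial$targets$shape),
            collapse = "; ")))
}
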