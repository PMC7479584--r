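---
title: "Design and validation of the executive-function training battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and validation of the executive-function training battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efbattery)
```

# Overview

`efbattery` is a headless implementation of a three-game cognitive
training battery aimed at the core executive functions, of the kind
deployed in virtual-reality rehabilitation systems for pediatric
traumatic brain injury. The rendering layer of such a system (headset,
3D scenes, narration) is deliberately out of scope; what this package
implements is everything a scientist needs to exercise, validate and
extend the *training logic*: stimulus generation, adaptive difficulty,
scoring, session control, trial-level logging, and simulated responders
that stand in for participants.

The three games are classical psychophysics paradigms dressed in game
narrative:

* **Inhibitory control — Spatial Stroop.** An arrow appears at one of
  four positions relative to an opponent character (above, below, left,
  right) and points in one of the same four directions. The correct
  response is the *direction* the arrow points; its *position* is a
  prepotent spatial lure that either agrees with the direction
  (consistent trial) or conflicts with it (inconsistent trial).
* **Working memory — adaptive sequence recall.** A sequence of
  characters is shown on a door and must be reproduced in forward or
  reverse order (drawn 50/50 per trial). Sequence length follows a
  2-up/2-down staircase: two consecutive correct recalls lengthen the
  next sequence by one item, two consecutive errors shorten it by one.
* **Cognitive flexibility — rule-switching card sort.** A stimulus card
  defined by color, shape and amount must be matched to one of four
  target cards under an undisclosed rule (match by color, shape or
  amount) that silently changes every 7 trials; only trial-by-trial
  correct/incorrect feedback reveals the active rule. This is the
  Wisconsin Card Sorting design.

# Session control

A session is configured by `session_config()` (study id, session
number, task, trial count, seed, mode) and driven either trial by trial
(`start_session()`, `present_trial()`, `submit_response()`,
`advance_trial()`) or in one call by `run_session()`. The state machine
mirrors the five controls a therapist console exposes:

* **Training** — the full configured run with data collection
  (`run_session()`).
* **Tutorial** — a short demonstration run; `run_tutorial()` returns an
  in-memory report and never persists anything. The tutorial length is
  fixed at 5 trials: enough to demonstrate the mechanics of each game
  without fatiguing a child, while staying well under a minute.
* **Reset** — `reset_trial()` interrupts the current trial and
  re-presents it *in its initialized state*: the same stimulus returns
  and any partial response is discarded unlogged. We read "initialized
  state" as same-stimulus re-presentation (the alternative — drawing a
  fresh stimulus — would let a therapist reroll difficult trials, which
  defeats the purpose of a reset). A completed trial index therefore
  appears exactly once in the log no matter how many resets preceded it.
* **Next** — `next_task()` advances through the fixed narrative order
  inhibitory control → working memory → cognitive flexibility, and
  refuses to advance past the last game.
* **Back** — `abandon_session()` models returning to the home screen:
  completed trials are flushed to a log marked incomplete.

**Randomness contract.** Each session owns a single RNG stream seeded
from its configuration, and each simulated agent owns a second,
independent stream. Consequences that the test suite asserts: identical
configurations present bit-identical stimuli; identical (configuration,
agent) pairs produce byte-identical log files; and running a session
never perturbs the caller's RNG state.

**Response-time epoch.** Timing is supplied by the responder: simulated
agents draw from their lognormal model, and the interactive console
responder measures wall clock from stimulus presentation to committed
response — the stimulus-onset-to-selection convention of computerized
psychophysics. Times are stored as integer milliseconds and serialized
as `minutes:seconds:milliseconds` text, a format that round-trips
losslessly.

**Resume.** Deployments sometimes split a session's trials across
visits. `run_session(resume_from = )` replays a previously written
(possibly incomplete) log through the live state machine — regenerating
stimuli from the same seed and feeding the logged responses back in —
which reconstructs the RNG position, staircase counters and rule
progress exactly, then continues with the live responder and continued
trial numbering. For deterministic responders the resumed log is
identical to an uninterrupted run; for stochastic agents the stimulus
stream is still identical but the agent's own random draws restart at
the resume point.

# Task parameters and the choices behind them

## Spatial Stroop

* **Congruency policy: balanced 50/50.** "Random" stimulus placement is
  under-determined: independent uniform draws over position × direction
  give only 25% consistent trials. The package pre-draws a shuffled
  schedule of exactly half consistent, half inconsistent trials (odd
  counts differ by at most one), the norm in conflict paradigms, and
  logs the per-trial condition so the realized schedule is auditable.
  Position is uniform over the four placements; on inconsistent trials
  the direction is uniform over the three non-matching values.
* **Opponent rotation: every 10 trials.** The narrative progresses
  through a series of battles "after a few rounds"; 10 trials per
  opponent gives 5 opponents in a default 50-trial session.
* **No response deadline.** Trials wait indefinitely and record the
  time supplied; no timeout policy is imposed.

## Sequence recall

* **Start length 2.** The first trial of a session always presents two
  characters.
* **Floor 1, cap 20.** The floor must sit below the start length for
  the decrement rule to be observable; length 0 is meaningless, so the
  floor is 1. No ceiling is inherent to the design; 20 is a generous
  bound (human spans rarely exceed 8–9 items) that keeps memory and log
  size bounded. Both are parameters of `staircase_state()`, so analyses
  that need the unclamped closed form can raise the cap.
* **Counter semantics.** A correct outcome zeroes the error counter and
  vice versa; a length change zeroes both. The "2 consecutive" rule
  forces the reset-on-change reading — otherwise three correct responses
  in a row would trigger two increments.
* **Doors.** Five doors, one contiguous fifth of the trials each
  (remainder to the earliest doors), each door with its own set of 8
  characters. The staircase carries over across door boundaries — doors
  are cosmetic, and the tests assert the length trajectory is
  door-invariant.
* **Sequences.** Drawn with replacement from the door's 8 characters
  but never repeating a character in adjacent positions, since an
  immediate repeat is visually ambiguous in a recall display. Scoring
  is exact-match against the presented sequence (forward) or its
  reversal (backward); partial credit is not awarded. The log records
  both the staircase level and the realized item count (identical by
  construction, kept separately for schema fidelity) plus the presented
  and response sequences for replay.

## Card sort

* **Three rules.** Color, shape, amount.
* **Rule blocks of 7, always switching.** The rule is constant within
  each block of 7 trials; at each boundary the new rule is drawn
  uniformly from the two rules *not* currently active (a "change" that
  re-draws the same rule would not be a change). The first rule is
  uniform over all three. A 50-trial session thus has 8 blocks — seven
  of length 7 and a final block of length 1, kept rather than truncated
  so the 7-trial period is exact.
* **Key-card targets.** The default four targets are a Latin-square
  assignment (target *i* has the *i*-th color, *i*-th shape, amount
  *i*), so all colors, shapes and amounts are distinct across targets
  and every stimulus matches exactly one target per dimension. The set
  is a shipped constant for comparability and overridable in the
  configuration; invalid sets are rejected.
* **Unambiguous stimuli.** Stimuli are rejection-sampled until their
  color-, shape- and amount-matching targets are three *different*
  cards (24 of the 64 attribute combinations qualify under the default
  targets). Without this constraint, feedback cannot identify the
  active rule — a standard card-sorting design consideration. The
  ambiguity status is logged per trial.

# Simulated responders

`make_agent()` builds parameterized agents that stand in for child
participants: `perfect`, `uniform_random`, `stroop_lure` (follows the
positional lure with probability `p_lure`), `span_limited` (correct iff
the sequence fits within `span` and no lapse fires), `rule_elimination`
and `perseverative`. Response times are drawn from a lognormal with
user-set median and log-sigma — the standard positively skewed RT
family. The parameters are validation knobs, not cognitive models, and
are never fitted to human data.

The elimination agent plays the lowest-indexed rule in its consistent
set; a correct trial (on an unambiguous stimulus) identifies the played
rule as active, an error removes the played rule from the set, and an
error that empties the set restarts it at the two rules other than the
one just disproved. After the first block this strategy makes at most
two errors per block, and the test suite checks the built-in agent
against an independently coded brute-force replay of this definition,
trial for trial over 100 seeds.

`simulate_cohort()` runs (agent × replicate) grids of sessions with
deterministically derived seeds, producing logs schema-identical to
human sessions for the reporting layer.

# Logging and metrics

Logs are plain CSV with `#`-prefixed header lines (study id, session
number, task, seed, schema version, completeness flag) and one row per
completed trial. The column sets are fixed per task; the writer refuses
any undeclared column, so no code path can leak person-identifying data
beyond the study id and session number. `read_session_csv()` is the
exact inverse of `write_session_csv()`, validated property-style over
randomized logs of all three schemas.

`summarize_task()` reports completed trials, average time per trial,
proportion correct, and cumulative completion time. The denominator of
proportion correct is completed trials only — attempts discarded by
Reset or Back never enter the log. Cumulative time sums logged per-trial
response times; inter-trial loading and feedback time is not captured
and therefore not included. `batch_report()` aggregates across sessions
per task (summarize each session first, then take mean/SD across
sessions), reporting seconds to one decimal and accuracy as percent
while the logs retain millisecond precision.

Questionnaire scoring covers the post-session usability instruments:
the 16-item simulator-sickness questionnaire scored as the raw 0–3 sum
(range 0–48) with the standard Kennedy-weighted subscale scoring
available as a labeled alternative (`score_ssq(method = "kennedy")`),
the 6–20 perceived-exertion rating, and 0–100 experience items.
Out-of-range input is rejected with the offending item named — never
clamped, since a clamp would silently fabricate data.

# Validation strategy, and what it does not show

There is no human data in this package and none of its validation
claims concern humans. The simulated agents emulate *contracts*
(a span limit, a lure preference, an inference strategy), not children;
real responders exhibit fatigue, learning, posterror slowing and mixed
strategies that no agent here models. What the test suite establishes
is that the battery's mechanics are exactly as specified — that the
staircase, schedules, scoring and logging do what they claim under
agents whose behaviour is known by construction:

* **Closed forms.** A perfect responder's staircase length after $t$
  trials is $\min(2 + \lfloor t/2 \rfloor, \text{cap})$ — 27 at
  $t = 50$ when the cap permits; an always-wrong responder reaches the
  floor at $t = 2$ and stays. Checked exactly, both on the bare
  staircase and through full sessions.
* **Parameter recovery.** For span-limited agents with spans 3–8 and a
  5% lapse rate, the mean presented length over the last 40 of 100
  trials recovers the span within ±1 item (50 replicates per span) —
  the staircase converges where it should.
* **Oracle equivalence.** The elimination agent matches its brute-force
  re-implementation seed for seed; congruency classification matches
  plain equality on all 16 position × direction pairs; summaries match
  hand recomputation from raw rows.
* **Frequencies.** Positions, recall orders and rule assignments hit
  their nominal uniform frequencies within Monte-Carlo tolerance at
  10,000 draws.
* **Round trips.** Response-time strings, log files and full seeded
  sessions reproduce byte-for-byte.

Problem sizes in the default test run are chosen to keep the suite
fast while leaving Monte-Carlo margins comfortable: 10,000-draw
frequency checks, 100-seed oracle comparisons, 300 staircase-recovery
sessions, 1000 round-trip logs. `scripts/acceptance.R` recomputes the
same quantities from scratch against the installed package and writes
them as JSON.

# Known limitations

* The interactive console responder is a development tool, not a
  clinical interface; no graphics or timing-accurate presentation is
  attempted.
* Exact-match recall scoring awards no partial credit; systems that
  score partial sequence overlap will report higher accuracy for the
  same behaviour.
* The battery's reporting layer stops at means, SDs and ranges; it
  performs no inferential statistics.
* Resume reconstructs session state exactly but not a stochastic
  agent's private RNG position (see above); human resumption has no
  such caveat since humans carry no seed.
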