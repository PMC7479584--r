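# efbattery

A headless, deterministic R implementation of a three-game cognitive
training battery targeting the core executive functions, of the kind
used in virtual-reality rehabilitation for pediatric traumatic brain
injury. The package contains no graphics: it is the training *logic* —
stimulus generation, adaptive difficulty, scoring, session control,
trial-level logging and simulated responders — packaged so the battery
can be exercised, validated and extended without any VR hardware. It is
aimed at researchers who need a reproducible task engine: to pilot
protocol variants, to validate adaptive rules by simulation, or to
analyze logs the same battery produced.

## The three games

| Game | Executive function | Paradigm |
|---|---|---|
| Arrow battle | Inhibitory control | Spatial Stroop: respond to the arrow's pointing direction while ignoring its position (the spatial lure). Congruency is balanced 50/50 per session. |
| Door unlock | Working memory | Sequence recall, forward or reverse (50/50), with sequence length driven by a 2-up/2-down staircase: two consecutive correct recalls add an item, two consecutive errors remove one. Starts at length 2. |
| Card sort | Cognitive flexibility | Wisconsin-style card sorting: match a (color, shape, amount) stimulus to one of four key cards under an undisclosed rule that changes every 7 trials; only correct/incorrect feedback reveals it. |

The staircase on sequence length follows the standard up/down logic:
after two consecutive correct responses the length `L` becomes
`min(L + 1, cap)`, after two consecutive errors `max(L - 1, floor)`,
with each outcome zeroing the opposite counter and each length change
zeroing both. For a perfect responder the length after `t` trials is
`min(2 + floor(t/2), cap)`; the staircase converges near the
responder's span for fallible ones.

## Worked example

Run a 50-trial working-memory session played by a simulated agent with
a span of 4 items and a 5% lapse rate, then summarize it:

```r
library(efbattery)

cfg <- session_config(study_id = "S01", task = "working_memory",
                      session_number = 1, n_trials = 50, seed = 7)
agent <- make_agent("span_limited", span = 4, lapse_rate = 0.05,
                    agent_seed = 11)
log <- run_session(cfg, agent, path = "s01_wm.csv")
summary(log)
#> <working_memory> 50 trials, 1.6 s/trial, 54% correct, 77.5 s total
head(as.data.frame(log), 3)
#>      order number_of_items level response_time correct trial door presented_sequence response_sequence
#> 1  forward               2     2     00:00:476     yes     0    0                2-4               2-4
#> 2 backward               2     2     00:00:882      no     1    0                4-8               4-8
#> 3 backward               2     2     00:01:236     yes     2    0                7-2               2-7
```

The summary line reads: the agent completed all 50 trials, averaged
1.6 s per trial, recalled 54% of sequences exactly, and spent 77.5 s of
cumulative response time (inter-trial time is not part of the log). A
span-4 agent hovers near 50–60% because the staircase keeps pushing the
sequence length to the edge of its span — that convergence is the
point of the adaptive rule. Each row is one trial of the fixed log
schema; the response time column is `minutes:seconds:milliseconds`
(trial 2 shows a lapse: the backward recall of `4-8` should be `8-4`).

Sessions are fully seeded: rerunning the chunk above writes a
byte-identical `s01_wm.csv`. The same API drives the other two games
(`task = "inhibitory_control"`, `"cognitive_flexibility"`), tutorials
(`run_tutorial()`, never persisted), cohort simulation
(`simulate_cohort()`), batch summaries (`batch_report()`) and
usability-questionnaire scoring (`score_questionnaires()`). A thin
command-line runner with `run` / `simulate` / `report` /
`score-questionnaire` verbs is installed at `inst/cli/efbattery.R`.

See `vignette("efbattery-methods")` for the design rationale of every
parameter (balancing policy, staircase floor/cap, rule-block draws,
key-card targets, privacy-guarded log schema) and for what the
simulation-based validation does and does not establish.

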