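Package: efbattery
Title: Executive-Function Training Task Battery with Adaptive Difficulty
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless, deterministic implementation of a three-game
    executive-function training battery for cognitive rehabilitation:
    a Spatial Stroop task for inhibitory control, an adaptive
    sequence-recall task for working memory (2-up/2-down staircase on
    sequence length), and a rule-switching card-sort task for cognitive
    flexibility. Includes a session state machine mirroring a therapist
    control interface (tutorial, reset, next-task), parameterized
    simulated responders for validation without human subjects,
    trial-level CSV logging with a privacy-guarded schema, and
    performance/usability scoring (per-task summaries, simulator
    sickness and perceived-exertion questionnaires).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
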