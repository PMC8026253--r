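Package: oculoforage
Title: Working-Memory Foraging Model for Oculomotor Search Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and fitting of a stochastic memory-guided search
    ("foraging") agent for oculomotor foraging tasks in which a subject
    searches 15 identical on-screen objects for a hidden reward target by
    sequential saccades. The agent is defined by three working-memory
    parameters (memory capacity, memory decay, utility rate). The package
    computes the three 25-bin behavioral summary distributions (revisit
    proportion by saccade ordinal, revisit distance in intervening
    saccades, and per-trial saccade count), fits them by exhaustive
    Monte-Carlo grid search over 6,120 parameter sets using a
    coefficient-of-determination statistic, and provides bootstrap
    significance intervals, sliding-window time-course fits, and a
    parameter-distance statistic. It also implements the accompanying
    oculomotor analyses (saccade detection on 1-kHz gaze traces, choice
    registration, postsaccadic drift, intersaccadic intervals,
    main-sequence fitting, saccade gain, virtual-window trial exclusion)
    and a synthetic-data generator producing complete sessions and eye
    traces with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
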