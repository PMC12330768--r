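Package: naptwitch
Title: Infant Nap EEG Analysis of Twitches, Sleep Spindles, and Delta Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for daytime-nap recordings in human infants:
    sleep-spindle detection from the 11-15 Hz Hilbert envelope with
    median-relative thresholds, delta-band (0.5-4 Hz) power in one-minute
    NREM windows, stage-conditional twitch metrics (rates, bursts,
    inter-twitch intervals, log-survivor curves), twitch-spindle coupling
    against interval-preserving shuffle nulls with Monte-Carlo confidence
    bands, and a random-intercept mixed model of twitch counts on
    person-mean-centered delta power. Includes a seeded synthetic-cohort
    generator that plants all of these quantities so every pipeline stage
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    car,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
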