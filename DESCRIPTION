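Package: shoalresp
Title: Carbonate Chemistry, Intermittent-Flow Respirometry and Shoal-Choice
    Analysis for Ocean-Acidification Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain of an ocean-acidification study
    on a shoaling coral-reef fish: solving the seawater CO2 system for pCO2
    from NBS-scale pH and total alkalinity (CO2SYS-style constants), turning
    raw intermittent-flow respirometry oxygen traces into background-corrected
    oxygen-uptake rates, summarising them into the standard metabolic
    statistics (minimal metabolic rate, routine and maximum metabolic rate,
    aerobic scope, initial stress response, the social calming effect, and
    allometric mass correction), scoring two-choice shoal-association trials,
    and fitting the study's mixed-effects inference layer. A synthetic-data
    generator with recorded ground truth simulates complete studies (oxygen
    traces, chase recoveries, choice trajectories) so every estimator can be
    validated by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    car,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
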