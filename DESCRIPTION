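Package: omispike
Title: Spiking-Level Analysis of Stimulus-Omission Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-unit spiking responses to omitted
    stimuli in regular visual stimulus trains, as recorded in change-detection
    paradigms. Provides a synthetic session generator (stimulus schedules with
    stochastic omissions, inhomogeneous-Poisson units built from functional
    response archetypes, running/pupil traces), unit quality filtering and
    cell-type rules, event-aligned rate estimation with omission-modulation
    scoring and ramping indices, linear-versus-sigmoidal population response
    fitting with cross-validated model comparison, functional clustering with
    dual elbow/gap selection of the number of clusters, population-coupling and
    behaviour scores, jitter-corrected cross-correlogram inference of putative
    monosynaptic connections, cross-area ridge and canonical-correlation
    interaction measures, and time-resolved image-identity decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
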