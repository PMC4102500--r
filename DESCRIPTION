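Package: pulsewk
Title: Pulse-Contour Stroke Volume from Aortic Pressure via Windkessel
    Reservoir-Excess Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-to-beat left-ventricular stroke volume estimation from a
    continuous aortic pressure waveform alone. Each beat's pressure is
    decomposed into reservoir and excess components under a three-element
    Windkessel model: the diastolic decay identifies the RC time constant and
    mean systemic filling pressure, a zero-net-flow condition during late
    systole identifies the proximal time constant R_prox*C, and fixing any one
    of R, C or R_prox closes the system so that stroke volume follows from the
    integral of excess pressure. Includes a forward Windkessel simulator with
    known per-beat stroke volume (PEEP-recruitment-like staircases, measurement
    noise) so every inverse step is verifiable by parameter and stroke-volume
    recovery, grid-search calibration of the fixed parameter against measured
    stroke volume, and Bland-Altman and trend-correlation evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
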