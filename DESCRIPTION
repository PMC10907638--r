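Package: chanreg
Title: Homeostatic Regulation of L-Type Calcium Channel Expression in
    Cardiomyocyte Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates calcium-feedback regulation of L-type calcium channel
    expression coupled to a spontaneously beating human induced pluripotent
    stem cell-derived cardiomyocyte (hiPSC-CM) action-potential model.
    Implements the two-equation mRNA/protein regulation model, its bounded
    scalar refinement with smooth expression gates, drug-block experiments
    that reproduce the time-dependent loss of calcium-channel-blocker
    efficacy, action-potential biomarker extraction (APD50, APD80, beat
    rate) from voltage traces, a protein-type sensitivity panel, and a
    synthetic optical-recording generator for validation without external
    data. A slow-fast cycle-averaged accelerator makes multi-hour coupled
    simulations practical on a desktop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
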