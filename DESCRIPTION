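Package: aquapso
Title: Canopy-Coverage Inversion and AquaCrop-Style Data Assimilation by
    Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating tea-canopy coverage from multispectral
    imagery and assimilating it into a water-driven crop model. Implements
    Otsu-threshold soil-background removal and pixel-ratio canopy coverage,
    ten standard vegetation indices, a canopy-coverage inversion suite
    (linear, logarithmic, exponential and power regressions plus NIPALS
    partial least squares with RMSEP component selection), a self-contained
    daily-step canopy / layered soil-water / biomass-yield simulator in the
    AquaCrop tradition, and a particle swarm optimizer that tunes nine crop
    parameters so simulated canopy coverage matches remote-sensing
    observations. A synthetic-data module generates reflectance scenes with
    known canopy masks, weather series, vegetation-index samples and noisy
    coverage trajectories so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
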