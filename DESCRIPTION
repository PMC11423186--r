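Package: optobeat
Title: Analysis of Optogenetically Modulated Cardiomyocyte Recordings on
    Multi-Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for multi-electrode array (MEA) recordings of beating
    cardiomyocyte monolayers under optogenetic control of intracellular
    cAMP. Provides Chebyshev band-pass filtering, per-channel quality
    control by signal-to-noise ratio, extracellular spike detection,
    segment-wise beating rates and fold-change series, rise/decay kinetics
    (t50/t90), isochronal activation mapping with inverse-gradient
    conduction velocities, and Hill-model dose-response (EC50) fitting of
    beating-rate plateaus against irradiance. A forward simulator
    generates recordings with a propagating activation wavefront, biphasic
    extracellular spikes, Gaussian noise, dead channels, and a
    light-driven cAMP-to-rate cascade, so the full pipeline is exercisable
    without laboratory data.
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
    minpack.lm,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
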