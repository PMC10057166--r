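Package: fluoroquant
Title: Chlorophyll Fluorescence Imaging Analysis of Fv/Fm for Plant Stress Phenotyping
Version: 0.1.0
Authors@R:
    person("Fluoroquant", "Developers", email = "fluoroquant@example.org", role = c("aut", "cre"))
Description: Tools for camera-based chlorophyll fluorescence imaging (CFI) of
    dark-adapted plants. Computes per-pixel maximum quantum efficiency of
    photosystem II, Fv/Fm = (Fm - Fo)/Fm, from paired minimum (Fo) and maximum
    (Fm) fluorescence frames; segments the plant by intensity thresholding
    (Otsu or fixed); summarizes each plant by the histogram-peak (mode) Fv/Fm
    and classifies health against the 0.79 rule for unstressed leaves; renders
    pseudocolor maps on a fixed [0, 1] scale. Also provides
    excitation-emission matrix (EMEX) peak localization and multi-day peak
    stability testing, a from-first-principles statistical layer (one-way
    ANOVA, Student-Newman-Keuls step-down multiple comparisons with compact
    letter displays, studentized-range quantiles by numerical integration,
    Pearson correlation, mean +/- SE), a synthetic experiment generator with
    known ground truth standing in for the camera, and an end-to-end pipeline
    that aggregates group trajectories, tests period means, and correlates
    imaging results with SPAD chlorophyll-meter readings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    digest,
    viridisLite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
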