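Package: icswave
Title: Calcium Transients, Intercellular Waves, and Stress-Gene Expression
    in Cochlear Live Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of GCaMP time-lapse recordings of the cochlear sensory
    epithelium and of the accompanying unfolded-protein-response qPCR panels.
    Extracts ROI-grid fluorescence traces from movies, detects Ca2+ transients
    at a multiple of the baseline standard deviation, measures rise and decay
    kinetics and steady-state amplitude, clusters transients into intercellular
    Ca2+ signaling waves with propagation speed and distance estimates,
    classifies hair-cell transients as fast or slow from cell-area dynamics,
    and implements 2^-dCt relative-expression statistics with robust outlier
    removal and normality-dispatched group comparisons. A synthetic-data
    generator with exact ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    tiff,
    EBImage,
    multcomp,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
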