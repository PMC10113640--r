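Package: laminarec
Title: Layer-Resolved Stability Analysis of Intracortical Recordings and
    Depth-Tracked Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the layer-dependent stability of chronic
    intracortical microelectrode recordings and the surrounding tissue response.
    Includes a spike-band processing pipeline (Butterworth filtering, robust
    median-based noise estimation, artifact invalidation, threshold detection,
    PCA/k-means unit sorting, amplitude and signal-to-noise metrics), parsing and
    summarisation of electrochemical impedance sweeps, a depth-tracked
    serial-section histology pipeline (slide/slice depth tracking, trainable
    pixel classification of neuronal nuclei, concentric-ring density and
    circularity profiles, neuronal cell-loss area estimation), laminar
    statistics (ANOVA, ANCOVA with time, Kruskal-Wallis, depth trends), and
    seeded synthetic-data generators that emulate the statistical structure of
    an in-vivo laminar implant study for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    nnet,
    cluster,
    car,
    tiff,
    withr,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
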