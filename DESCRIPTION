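Package: circuitsync
Title: Synchrony, Colocalization and Rhythm Analysis for Neuronal Circuit Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of neuronal circuit function across three
    classic preparations: multi-neuron calcium imaging of cultured clusters
    (baseline-normalized fluorescence, transient onset detection, synchrony-size
    and active-fraction histograms, per-neuron response-frequency distributions
    with log-log power-law fits, Mann-Whitney group comparisons), two-channel
    puncta colocalization along close-running neurites (spot detection, neurite
    pairing, one-to-one matching, density and survival-ratio tables with
    ANOVA/Tukey comparisons), and left-right ventral-root rhythm classification
    (envelope extraction, burst detection, cycle phases, circular-statistics
    labelling as alternating, synchronous or arrhythmic). A seeded synthetic-data
    generator produces wired-cluster calcium recordings on configurable network
    topologies, two-channel puncta scenes with known colocalized fractions, and
    rhythmic ventral-root trace pairs, so every stage of the pipeline is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
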