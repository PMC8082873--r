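Package: mockval
Title: Validation of Microbiome Measurements Against Mock-Community Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative validation of metagenomics-based microbiome
    measurements against mock communities of known composition. Provides
    Aitchison-geometry primitives (closure, centred log-ratio transform,
    compositional mean, variation matrix, metric variance, Aitchison
    distance, compositional PCA), agreement metrics against ground truth
    (geometric mean and maximum of taxon-wise absolute fold-differences,
    trueness and accuracy, best-practice threshold evaluation),
    precision metrics (quadratic-mean coefficient of variation, directly
    and via the metric variance), distance-based one-way random-effects
    analysis of variance for intermediate precision and interlaboratory
    reproducibility, GC-content and fragmentation bias summaries, limits
    of detection and quantification from probability-of-detection and
    CV-versus-abundance regressions, and a synthetic-data generator that
    emulates the statistical structure of mock-community sequencing
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
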