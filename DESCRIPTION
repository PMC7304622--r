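Package: otolrp
Title: Explaining Convolutional Age Predictions from Otolith Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully introspectable pipeline for studying how
    convolutional classifiers read age from fish otolith (ear stone) images.
    It generates synthetic otolith-like images whose morphology varies with
    age in three variants (baseline, binary silhouette, size-standardized),
    trains a small convolutional network on them, explains individual
    predictions with layer-wise relevance propagation under the alpha-beta
    rule, clusters the resulting relevance maps with a spectral relevance
    analysis pipeline (k-nearest-neighbour affinity graph, normalized-Laplacian
    spectral clustering, t-SNE embedding, F1 cluster-recovery scoring),
    summarizes them as per-age average maps, and quantifies model/reader
    agreement with RMSE and the mean age-reading coefficient of variation
    with interquartile-range outlier exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
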