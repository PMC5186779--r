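Package: linkbrain
Title: Link Prediction of Resting-State Functional Brain Networks with
    Local Information Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds binary functional brain networks from regional
    time series by Pearson correlation and sparsity thresholding,
    predicts their edges from anatomical (Euclidean) distance combined
    with seven local-information similarity indices (common neighbours,
    hub depressed, hub promoted, Leicht-Holme-Newman, preferential
    attachment, resource allocation, Sorensen), and evaluates the
    predictions through topological-property relative errors, an energy
    score, and a prediction-power statistic with FDR-corrected paired
    tests.  Includes a synthetic-data generator producing spatially
    embedded modular small-world networks and correlated regional time
    series so the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
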