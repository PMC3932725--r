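Package: metricmine
Title: Multi-Metric Evaluation and Rank-Based Mining of Image Registration Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates candidate images (typically registration outputs) against a
    reference under a battery of eleven intensity-based and statistical similarity
    metrics (mean square and absolute intensity differences, entropy of the
    difference image, mutual information and its normalized variants, normalized
    cross-correlation, the correlation ratio and the Woods criterion), logs every
    value to an embedded relational store, and mines the resulting n x p metric
    table with principal component analysis of the Spearman rank correlation
    matrix to rank candidates and diagnose metric inconsistency. Includes a
    synthetic phantom generator with graded, ground-truth perturbations for
    benchmarking, parameter-grid campaign bookkeeping, and parallel-coordinates,
    correlation-heatmap and principal-component visualisations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    DBI,
    RSQLite,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
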