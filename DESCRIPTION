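Package: hemilat
Title: Hemispheric Laterality Analysis of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying hemispheric lateralisation of
    resting-state fMRI connectivity. From multi-subject BOLD timeseries
    (synthetic or user supplied) it computes node-level graph metrics (global
    and local efficiency, betweenness centrality, average path length,
    clustering coefficient, degree, cost), voxel-based metrics (intrinsic
    connectivity, local correlation, fALFF) aggregated to atlas regions, the
    laterality index over homologous left/right region pairs, paired and
    one-sample t-tests with Bonferroni correction and signed Cohen's d, and a
    two-cohort direction-concordance report. Includes timeseries-level
    denoising (motion outlier detection, CompCor-style nuisance components,
    confound regression, band-pass filtering) and a synthetic-data generator
    with configurable lateralisation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    rlang,
    yaml,
    signal,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
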