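Package: rsedegree
Title: Region-Size-Corrected Degree Metrics for Voxel-Wise Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise degree centrality in resting-state functional
    brain networks while correcting for the size of the functional region each
    voxel belongs to. Functional regions are estimated per voxel by adaptive
    threshold region growing on temporal and spatial Pearson correlation
    matrices; region-growing quality is quantified by an error rate and by the
    agreement of two cluster-size maps. Four traditional degree metrics
    (unweighted, weighted, squared-weight, Fisher-z weighted) and their four
    region-size-effect corrected counterparts are provided, together with
    voxel-wise test-retest intra-class correlation, Gaussian smoothing of
    masked maps, synthetic phantom generators, and a pipeline driver with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
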