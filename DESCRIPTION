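Package: scnwta
Title: Winner-Take-All Structural Covariance Networks of Cortico-Subcortical
    Gray Matter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structural covariance network (SCN) analysis of gray-matter
    volume for cortico-striato-thalamo-cerebellar circuits. Maps every
    striatal, thalamic and cerebellar voxel to one of five cortical lobes by
    winner-take-all partial correlation across subjects, compares the
    resulting maps and a 20-node covariance network between groups by
    group-label permutation, and fits linear interaction models quantifying
    how disease duration modulates covariance strength. Includes a synthetic
    cohort generator with planted covariance territories and ground truth for
    calibration and parameter-recovery studies, voxel-based morphometry
    statistics with permutation cluster-extent correction, and a pipeline
    driver emitting report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    MASS,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
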