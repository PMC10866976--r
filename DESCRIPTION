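Package: brainpadlab
Title: Sex-Stratified Brain-Age and Brain-PAD Analysis on Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for structural-MRI brain-age analysis
    in Parkinson's disease, exercisable end-to-end on synthetic cohorts with
    known ground truth. Generates cohorts of tissue probability maps with
    linear age-related atrophy, sex and scanner offsets, and a sex-specific
    accelerated-aging gap in the disease group; provides deterministic
    voxel-based-morphometry style operators (Gaussian smoothing, block-average
    resampling, tissue volumes, striatal binding ratio); trains and
    cross-validates a linear support-vector age regressor with post-hoc bias
    adjustment and Brain-PAD computation; performs propensity-score matching
    with balance diagnostics; runs the sex-stratified regression battery with
    Benjamini-Hochberg false-discovery-rate control; and fits mass-univariate
    voxelwise regressions with max-statistic permutation family-wise-error
    control and cluster tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    RNifti,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
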