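Package: aslrel
Title: Test-Retest Reliability of Arterial Spin Labelling CBF Maps and
    Concurrent Pain Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-level test-retest reliability analysis for voxelwise
    cerebral blood flow (CBF) maps from arterial spin labelling together
    with concurrent visual analogue scale (VAS) ratings, in a
    repeated-measures pre/post-surgical design with two pre and two post
    sessions of six scans each. Provides the consistency intraclass
    correlation ICC(3,1) from a two-way mean-squares decomposition with
    coefficient of variation, standard error of measurement and
    qualitative reliability bands; a voxelwise two-way blocked ANOVA state
    contrast that defines a pain-network mask; four baseline-subtraction
    schemes for change-in-CBF images; inter-subject voxelwise ICC maps
    with median summaries and distribution profiles; within-subject
    inter- and intra-session intra-voxel ICC; and reliability tables for
    VAS pain and alertness ratings including the floor-effect refusal for
    change-in-VAS. A synthetic-data module simulates studies with known
    variance components and closed-form expected ICCs, so every stage is
    verifiable against analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    graphics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
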