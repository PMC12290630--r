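Package: relimap
Title: Voxel-Wise Test-Retest Reliability of Repeated-Measure 3D Statistical Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the test-retest reliability of
    repeated-measure 3D statistical images such as subject-level task-fMRI
    contrast maps. Implements voxel-wise intraclass correlation coefficients
    (ICC(1), ICC(2,1), ICC(3,1)) from the two-way ANOVA decomposition with
    F-based confidence bounds and between-/within-subject variance component
    maps; binary (Jaccard, Dice) and continuous (Spearman) similarity between
    thresholded and unthresholded group maps; bootstrap subsampling curves
    describing how median reliability stabilises with sample size;
    specification-curve (multiverse) aggregation across analytic pipelines;
    precision-weighted fixed-effects averaging, GLM contrast efficiency and
    t-to-Cohen's-d conversion; and a synthetic NIfTI volume generator with
    known variance components so every stage can be exercised without real
    imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
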