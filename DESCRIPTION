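Package: cardiocurve
Title: Regional Morphometrics and Actomyosin Polarity Profiling for the
    Embryonic Zebrafish Ventricle
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying curvature formation in the embryonic
    zebrafish ventricle. Implements landmark-based delineation of the
    ventricular outer curvature (OC) and inner curvature (IC) at 36-37 and
    48 hours post-fertilization, per-cardiomyocyte 3D morphometrics (apical
    surface area with curved-cell stitching, circularity, apicobasal length,
    and the L x W x H volume estimator), membrane-domain F-actin/pMyosin
    intensity profiling from cell cross-sections (band tracing with corner
    exclusion, domain percentages, basal ratio), whole-myocardium intensity
    summaries with outlier screening and 1-10 rfu min-max normalization, and
    the statistical reporting layer (SuperPlot-style hierarchical summaries,
    two-sided Wilcoxon comparisons, cross-experiment Z-score normalization of
    group means). A seeded generator of synthetic ventricles with known
    ground truth supports end-to-end testing without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    igraph,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
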