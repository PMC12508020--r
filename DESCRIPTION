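Package: movetrack
Title: Processing and Analysis of Mouse- and Hand-Tracking Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Import, transform, and analyze movement trajectories recorded
    during two-option choice tasks (mouse-, finger- or hand-tracking).
    Provides a trial-by-point-by-feature dataset container with long/wide
    tabular import and export; spatial remapping and alignment; time,
    length, and constant-interval resampling; per-sample kinematics
    (distance, velocity, acceleration, movement angles); trial-level
    curvature, complexity, and temporal indices including sample entropy;
    homogeneity diagnostics (bimodality coefficient, Hartigan's dip
    statistic, density heatmaps and difference maps); type-based analysis
    via hierarchical clustering and prototype mapping with chi-square
    frequency tests and ordinal exports; per-time-step aggregation and
    regression with cluster-robust errors; and a fully parameterized
    synthetic trajectory generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust,
    sandwich,
    lmtest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
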