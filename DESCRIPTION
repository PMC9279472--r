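Package: scdmap
Title: Grid-Based Subchondral Cortical Distance Mapping for Varus Stress MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational measurement of lateral femorotibial compartment
    opening from multi-label knee segmentations. Builds joint-specific
    Cartesian coordinate systems from labelled femur/tibia volumes, extracts
    opposing subchondral surface height fields, measures vertical subchondral
    cortical distances (SCDs) on a baseline-referenced measurement grid with a
    transepicondylar lateral-exclusion rule, and derives loading-difference
    heat maps. Includes a voxelized knee phantom generator with analytic
    ground truth for validating the measurement chain, a two-reader
    pooling/ICC layer, repeated-measures two-way ANOVA with Tukey post hocs,
    and condition-versus-intact contrast tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    data.table,
    jsonlite,
    png,
    emmeans,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
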