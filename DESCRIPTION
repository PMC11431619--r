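Package: twistca
Title: TWISTER Randomization and Temporal Consistency Asymmetry for
    Model-Free fMRI Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and analysis tools for run-level, model-free
    fMRI mapping. Generates TWISTER-randomized experimental designs (four
    synchronized runs whose event labels are twisted along two experimental
    dimensions), simulates BOLD datasets with known ground-truth voxel
    selectivity under configurable response kernels (including inverted and
    saturating-nonlinear shapes that violate linear-model assumptions), and
    computes per-voxel Temporal Consistency Asymmetry (TCA): between-run
    correlation triples, autocorrelation-corrected effective sample sizes,
    the Hotelling-Williams test for dependent correlations, false discovery
    rate control, and NIfTI statistical parametric maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
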