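Package: phbold
Title: Pharmacological MRI Activation and Resting-State Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for awake-rodent pharmacological MRI (phMRI)
    and resting-state functional connectivity (rsFC). Provides per-voxel
    BOLD percent-change statistics with windowed Welch t-tests and a
    rank-based step-up false-positive filter, atlas-based volume-of-activation
    tables compared across dose groups with Kruskal-Wallis tests, group
    composite percent-change maps assembled through inverse affine transforms
    with trilinear interpolation, and a resting-state arm with band-pass
    filtering, nuisance regression, node-wise Pearson/Fisher-Z connectivity,
    group edge statistics, graph thresholding, degree centrality and
    subnetwork comparisons. Includes synthetic 4D BOLD phantom generators
    with known ground truth so the full pipeline is testable without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    igraph,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
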