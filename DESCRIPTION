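Package: fcnmapper
Title: Coordinate-Based Functional Connectivity Network Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps heterogeneous voxel-based morphometry findings onto common
    large-scale functional brain networks by functional connectivity network
    mapping (FCNM): sphere seeds around reported coordinates, seed-to-voxel
    resting-state correlation in a normative cohort, voxelwise one-sample
    t-tests with voxel-level FDR correction, overlap-probability network
    thresholding, canonical-atlas overlap quantification, and permutation-tested
    spatial correlation with neurotransmitter receptor and transporter maps.
    Includes a synthetic-data generator (planted coherent networks, motion
    traces, label atlases, study foci tables, receptor parcel maps) so the full
    pipeline is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
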