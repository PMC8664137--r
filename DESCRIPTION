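Package: beamskin
Title: C-Arm X-Ray Beam Geometry and Skin Dose Field Mapping on Body Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A geometry engine for patient radiation dosimetry in fluoroscopy-guided
    cardiac interventions. Given a body-surface triangle mesh, a heart-center point
    and a set of C-arm gantry angulations, it solves the table panning that centres
    the heart on the central beam axis, the source-to-image-receptor distance (SID)
    under a detector clearance rule, the source-to-surface distance (SSD) along the
    central axis, the beam area in the plane perpendicular to the axis at the skin
    entrance (Ap), the beam-field area on the actual skin surface (As) by mesh
    clipping with entrance-visibility selection, and pairwise As overlaps across
    views. Entrance-surface air-kerma corrections from incident air kerma or
    kerma-area product are included, together with study-level summary statistics
    and Pearson correlations. Ships a deterministic synthetic torso phantom
    generator so the full pipeline is testable without proprietary phantom scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    igraph,
    ggplot2,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
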