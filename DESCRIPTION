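Package: allomorph
Title: Interdomain Motion and NMR State Analysis for Two-Domain Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterises cap/core interdomain motion in two-domain proteins
    using a principal-axes intrinsic Euler-angle framework (pitch = closing,
    roll = twisting, yaw = lateral rotation), with Kabsch superposition, RMSD
    and hinge-angle calculation, and conformer classification against labelled
    reference states. Complements the geometry with solution-NMR analysis:
    weighted backbone-amide chemical-shift perturbations, reporter-residue
    state classification (peptide-bond isomer, hinge-closure state, transient
    metal occupancy), species populations from peak intensities, two-state
    dissociation-constant estimation, and correlation-based species matching
    with Fisher z-tests. Ships a ground-truthed synthetic-data generator so
    every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
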