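Package: dbsvta
Title: Volume of Tissue Activated Modeling for Directional Deep Brain Stimulation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Patient-specific volume-conductor modeling of deep brain
    stimulation (DBS) on voxelized head models. Builds synthetic
    multi-compartment head phantoms with literature tissue conductivities,
    reconstructs a directional 8-contact lead axis from a hyperdense
    pseudo-CT artifact, solves the quasi-static potential around the lead
    with a finite-volume conjugate-gradient solver, calibrates gray-matter
    conductivity against a measured electrode-IPG impedance, estimates the
    volume of tissue activated (VTA) by thresholding the primary eigenvalue
    of the Hessian of the extracellular potential, and scores VTA overlap
    with a target nucleus against clinical outcome scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
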