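Package: aortapath
Title: Automated 3D Aortic Centreline Tracking and Pulse Wave Velocity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for automated extraction of aortic centrelines from 3D
    magnetic resonance volumes and for computing aortic pulse wave velocity
    (PWV) from phase-contrast flow waveforms. The tracking pipeline combines
    a multi-scale Hessian vesselness filter, bidirectional fast marching on
    a vesselness-derived speed map, and open-active-contour refinement.
    Companion modules measure centreline length, split centrelines at the
    descending aorta, project 3D centrelines to oblique-sagittal planes for
    2D-vs-3D length comparison, extract volumetric flow waveforms by
    ray-cast circle fitting of the lumen, estimate transit times with the
    foot-to-foot method, and summarise agreement with Bland-Altman analysis,
    exact Wilcoxon signed-rank tests and Kolmogorov-Smirnov normality
    screening. Synthetic tube phantoms with analytic centrelines and flow
    waveform pairs with known foot delays make every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
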