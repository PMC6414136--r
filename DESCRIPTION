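Package: boluscap
Title: Patient-Specific 3D-Printable Bolus Caps from CT Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated design and quality assurance of uniform-thickness,
    patient-specific bolus caps for total scalp irradiation. Reads an axial
    CT series, segments the external body contour, builds a uniform-thickness
    bolus shell by exact Euclidean distance transform, extracts a watertight
    triangle mesh and exports binary STL for 3D printing. Ships volumetric
    conformality (air gap) and wall-thickness metrics, Hounsfield-unit to
    density calibration utilities, planned-versus-measured dose agreement
    statistics for thermoluminescent dosimeter (TLD) readings, and a
    synthetic head-phantom generator with closed-form ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
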