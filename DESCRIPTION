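Package: lungcand
Title: Lung Nodule and Ground-Glass Opacity Candidate Detection from CT
Version: 0.1.0
Authors@R: person("Lungcand", "Developers", role = c("aut", "cre"),
    email = "maintainers@lungcand.org")
Description: Candidate detection pipeline for pulmonary nodules and
    ground-glass opacities (GGO) on chest CT: morphological lung parenchyma
    segmentation (threshold binarization, largest-component extraction,
    airway filling, contour corrosion and mending), candidate component
    filtering, 64x64 tri-slice region-of-interest extraction with RGB
    pseudo-color superposition, a deterministic sphere-vs-vessel coincidence
    scorer, and the full detection evaluation calculus (sensitivity,
    precision, F-score, specificity, false-positive rate, threshold sweeps,
    size-stratified reports, average false positives per patient). Includes
    a synthetic CT phantom generator with known lung geometry, tilted
    vessels, solid and GGO nodules and matching ground-truth annotations so
    every stage is testable without external data, plus readers and writers
    for NIfTI-1 volumes, LIDC-style XML nodule annotations and PNG
    composites.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
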