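Package: lungfx
Title: CT Ventilation and Perfusion Biomarkers for Regional Radiotherapy
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes CT-derived regional lung-function biomarkers and
    compares them with ordinal histopathology findings. Ventilation is
    estimated voxel-wise from multi-phase breathing CT via the Jacobian
    determinant of deformable registrations to end exhale (the local
    expansion ratio, LER-N), with tidal-volume effort correction and
    threshold classification of ventilation level and pre- to
    post-treatment change. Perfusion is summarised from dynamic
    contrast-enhanced time-attenuation curves (baseline, peak
    enhancement, area under the curve) in dose-binned vessel and
    parenchyma regions. The nine standard analysis contours (maximum
    dose, low/no dose crossed with fed/not-fed vessel topology,
    contralateral control, and three ventilation-selected points) are
    constructed programmatically, and biomarker change classes are
    tabulated against collagen grades and histologic diagnoses in a
    concordance table. A synthetic-data module generates breathing
    phantoms with closed-form Jacobians, gamma-variate contrast
    kinetics, dose distributions, vessel trees and coupled pathology
    outcomes so every stage can be verified against known ground truth.
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
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
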