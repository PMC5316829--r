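Package: tsysquant
Title: Quantification of Skeletal Muscle T-System Structure and Calcium
    Handling
Version: 0.1.0
Authors@R:
    person("Riley", "Chen", email = "riley.chen@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the tubular (t-) system of skeletal
    muscle fibres from 3D confocal volumes and for analysing calcium
    handling by the t-system lumen. Includes a ground-truthed synthetic
    phantom generator (tubular lattices, peripheral longitudinal tubules,
    vacuole series, bead stacks, two-compartment calcium dynamics),
    Richardson-Lucy deconvolution with bead-estimated point spread
    functions, 3D skeletonization with transverse/longitudinal segment
    classification, structure-tensor directionality histograms, vacuole
    segmentation and morphometrics, fluorescence-to-calcium calibration
    for low-affinity trapped indicators, flux extraction, store-operated
    calcium entry regression, and luminal calcium-content budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
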