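Package: wbrt
Title: Automated Whole-Brain Radiotherapy Planning by Database Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated treatment planning for whole-brain radiation therapy.
    Segments brain, eyes and lenses from a head CT with a chain of
    mathematical-morphology operators (soft-tissue windowing, Sobel bone
    edges, erosion/largest-component selection, roundness ranking, H-convex
    lens detection, level-set refinement), evaluates segmentations with Dice
    and surface-distance metrics, ranks a database of prior cases by
    anatomical similarity using translations-only iterative closest point
    alignment and a direction-selective root-mean-square surface score, and
    retargets the best-matching template plan to the new patient. Includes a
    synthetic head-phantom generator with ground-truth masks and template
    plans so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
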