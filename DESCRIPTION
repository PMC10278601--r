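Package: HenlePS
Title: Henle Fiber Layer Analysis for Polarization-Sensitive OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of Henle's fiber layer (HFL) birefringence
    from polarization-sensitive optical coherence tomography (PS-OCT) en-face
    Stokes data. Implements bias-free Stokes-vector averaging, retardation and
    optic-axis extraction, degree-of-polarization-uniformity (DOPU) maps,
    Poincare-sphere compensation of anterior-segment birefringence, the
    azimuthal mean-deviation (MD) statistic that detects the radial Henle
    fiber axis pattern, the four-step correction pipeline (rotation, fovea
    center, compensation offsets, re-centering), lateral HFL extension
    estimation, circumferential retardation profiles, and cohort-level
    statistics. A ground-truthed synthetic PS-OCT generator drives all stages
    so the pipeline runs and is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'HenlePS-package.R'
    'cohort.R'
    'geometry.R'
    'henle.R'
    'io.R'
    'pipeline.R'
    'plots.R'
    'polarization.R'
    'preprocessing.R'
    'retardation.R'
    'synthetic.R'
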