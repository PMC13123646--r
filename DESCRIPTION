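Package: hsisas
Title: Hyperspectral Imaging Soft Abundance Scoring for Treatment Response
Version: 0.1.0
Authors@R:
    person("HSISAS", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies treatment-related spectral change in short-wave
    infrared (900-1700 nm) hyperspectral wrist images of rheumatoid
    arthritis patients.  Provides flat-field reflectance calibration from
    white and dark references, band-ratio/Otsu wrist segmentation,
    intra- and inter-subject spectral correlation estimation, constrained
    energy minimization (CEM) abundance scoring, power-Doppler ultrasound
    quantification, nonparametric paired cohort statistics, and a fully
    synthetic SWIR cohort generator so that the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
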