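Package: corneamech
Title: In Vivo Estimation of Corneal Young's Modulus from Clinical Tonometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the Young's modulus of the human cornea in vivo from
    routine clinical measurements (keratometry, ultrasonic pachymetry, Goldmann
    applanation and Pascal dynamic contour tonometry) using a thin spherical
    shell applanation model. Provides the calculated-true-IOP correction, two
    modulus estimators (one using both tonometers, one using Goldmann readings
    plus a calibration-cornea assumption), corneal structural stiffness, a
    decomposition of Goldmann tonometry error into thickness- and
    modulus-driven components, a cohort analysis pipeline with the standard
    clinical statistical battery (Pearson correlations, regression, paired t,
    Bland-Altman agreement), and a seeded synthetic-cohort generator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    jsonlite
Config/testthat/edition: 3
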