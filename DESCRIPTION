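Package: retcomp
Title: Weighted Composite Endpoints for Retinal Degeneration Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multimodal composite endpoints
    of macular degeneration progression in Stargardt disease and related
    retinal dystrophies. Standardizes best-corrected visual acuity, fundus
    autofluorescence lesion areas and OCT-derived transverse band loss to a
    common retinal-eccentricity scale (degrees); fits a zero-intercept
    random-slope mixed model of composite change from baseline with
    patient- and eye-level slope deviations; optimizes biomarker weights on
    an exhaustive simplex grid by the mean-to-standard-deviation ratio
    (MSDR); validates by leave-last-visit-out prediction calibration; and
    estimates clinical-trial power by Monte-Carlo simulation of paired-eye
    designs. Includes a synthetic longitudinal cohort generator emulating
    the statistical structure of early-onset Stargardt cohorts, plus
    inter-grader agreement statistics (intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    lme4,
    readxl,
    jsonlite
Config/testthat/edition: 3
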