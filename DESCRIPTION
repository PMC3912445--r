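Package: lengthlaw
Title: Time-Free Length-Increment Growth Law for Fish Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the time-free fish growth law dL = k * (Lmax - L), in
    which the length increment of a cohort over one observation step is
    proportional to the gap between its current mean length and a fixed
    maximal length. Extracts year-class (cohort) length-at-age series from
    year-by-age survey tables, estimates the environmental growth coefficient
    k and the maximal length Lmax by ordinary least squares on
    (length, increment) pairs, compares the linear law against a second-order
    polynomial alternative with the extra-sum-of-squares F-test, detects
    deviating young ages and assigns them their own per-age k, projects
    cohort length and stock biomass forward under time-varying k using
    Fulton's condition factor, and generates synthetic age-length tables with
    known parameters for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
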