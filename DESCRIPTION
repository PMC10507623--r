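Package: gtnest
Title: Generalizability Theory for Unbalanced Nested Rater Designs with
    Unit Non-Response
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generalizability (G) and decision (D) study analysis for the
    two-facet partially nested random design in which raters are nested in
    the objects of measurement and crossed with items, the design that
    arises when different students rate different course-instructors on a
    common evaluation instrument.  Variance components of the unbalanced
    design are estimated by analogous ANOVA (Henderson Method 1), equating
    observed sums of squares to their exact expectations under the observed
    rater counts.  D-study projections give absolute and relative error
    variances and the generalizability (g) and dependability (phi)
    coefficients over hypothetical rater and item counts, including
    rater-count optimization schedules for studying how unit non-response
    degrades score reliability.  Includes data screening and
    response-prevalence analytics for expected-versus-received response
    rosters, and a seeded synthetic rating-data generator with completely
    random (MCAR) and selection-bias (response-propensity) unit
    non-response mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
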