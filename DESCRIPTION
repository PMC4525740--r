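Package: ahpcohort
Title: Analytic Hierarchy Process for Cohorts of Survey Respondents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for running the Analytic Hierarchy Process (AHP) over a
    cohort of survey respondents: construction of positive reciprocal
    pairwise-comparison matrices from Saaty-scale judgments, priority
    vectors by the principal eigenvector (power iteration) or row geometric
    mean, consistency ratios with Saaty's random-index table, screening of
    respondents at a consistency threshold, log-median aggregation of the
    consistent judgments into a group matrix, and ranking of criterion
    weights.  Includes readers and writers for survey forms, hierarchy
    configurations, comparison matrices and study reports, plus a
    synthetic-respondent generator with controlled judgment noise for
    end-to-end testing of the pipeline, built around a five-criterion
    family-physician selection hierarchy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
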