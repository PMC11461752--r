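Package: obsconf
Title: Confidence Scoring for Citizen-Science Species Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns a confidence level (low, medium, high, or unscorable) to
    citizen-science species observations, such as iNaturalist records, via a
    three-step rubric that scores uncertainty arising from the species being
    identified, the quality of the uploaded media, and the georeferencing.
    Stop points mark observations that cannot be scored (molecular
    identification required, unusable media, diagnostic features not shown,
    or coordinates absent). Includes tie-corrected Kendall rank correlation
    (tau-b) with concordant/discordant pair counts for validating confidence
    against expert accuracy labels and platform quality grades,
    cross-tabulation and marginal summaries, a synthetic observation-set
    generator with tunable association between record quality and true
    identification accuracy, and a packaged case-study fixture for a marine
    alien and cryptogenic species survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
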