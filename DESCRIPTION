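Package: dentagree
Title: Observer Reliability Analysis for Dental Age Estimation Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chance-corrected agreement analysis for multi-observer dental
    age estimation studies. Implements weighted Cohen's kappa, Fleiss'
    kappa and Gwet's AC1/AC2 with missing-tolerant multi-rater variance
    estimation, intraclass correlation for continuous third molar maturity
    measurements, agreement on not-assessable (NA) responses after binary
    recoding, a correlated ordinal-rating simulator with exact marginal
    preservation, Monte Carlo power and minimum-sample-size search for
    Gwet's AC2, Bonett's closed-form ICC precision sample size, and a
    synthetic multi-observer study generator emulating a 50-radiograph,
    nine-observer, two-session third molar staging design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
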