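Package: earlyonset
Title: Early-Onset Cancer Signatures in Small Areas via a Bayesian Standard Curve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects small areas whose median age at lung-cancer onset diverges
    from what their population age structure predicts. Fits a Bayesian simple
    linear regression ("standard curve") of median onset age on median
    population age across reference cancer registries using a conjugate Gibbs
    sampler, derives 95% posterior predictive intervals, and flags study areas
    whose observed onset median is improbably early or late, with
    Bonferroni-corrected posterior-probability thresholds and map-ready
    residual categories. Includes grouped-median estimation from quinquennial
    age-binned counts, registry table input/output, a seeded synthetic-data
    generator for end-to-end validation, and report rendering (CSV, JSON,
    GeoJSON attribute join).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    coda
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rjags
Config/testthat/edition: 3
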