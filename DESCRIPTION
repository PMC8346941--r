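Package: hbref
Title: Population-Based Hemoglobin Reference Cutoffs from Multi-Survey Biomarker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives population-specific hemoglobin (Hb) anemia cutoffs from
    multi-survey individual-level biomarker data. Defines an apparently
    healthy subpopulation from ferritin, vitamin A, inflammation, and malaria
    criteria; estimates survey-specific fifth-percentile Hb with
    Woodruff-type confidence intervals; pools surveys by restricted
    maximum likelihood random-effects meta-analysis with Cochran Q
    heterogeneity; decomposes between-survey versus between-individual
    variance at a quantile with an asymmetric-Laplace linear quantile mixed
    model; and locates physiological Hb-sTfR inflection points via
    restricted cubic splines with bias-corrected accelerated bootstrap
    confidence intervals. Includes a synthetic multi-survey cohort
    generator with a planted truth table so every stage is testable
    without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    splines,
    withr
Config/testthat/edition: 3
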