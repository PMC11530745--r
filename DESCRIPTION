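Package: gestage
Title: Trends in Gestational Age at Live Birth from Aggregate Registry Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies pregnancy-level birth records by gestational age
    category (preterm, term, post-term, with preterm sub-categories) and by
    onset of labour (spontaneous or provider-initiated) using a hierarchical
    ICD-10-driven rule set, aggregates records into year-by-stratum count
    tables with explicit known-denominator handling, and estimates secular
    trends: endpoint absolute and relative differences in percentages with
    Wald and delta-method confidence intervals, and per-year odds ratios from
    a birth-weighted aggregate (events/trials) binomial logistic regression
    fitted by iteratively reweighted least squares. Includes a synthetic
    cohort generator emulating a national maternity discharge registry and a
    pipeline that reproduces the standard published table layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
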