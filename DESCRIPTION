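Package: soclisten
Title: Graph-Based Semisupervised Social Listening Analytics for Public Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics core for taxonomy-driven social listening during health
    emergencies. Social posts are categorized into a public-health taxonomy by
    keyword-seeded measure propagation over a text-similarity graph built from
    word co-occurrences, with a Boolean-query baseline, macro
    precision/recall/F1 evaluation and a paired Hotelling T-squared method
    comparison, author-type/gender and question-intent segmentation, and
    weekly velocity aberration alerts. Includes a synthetic corpus generator
    with planted categories, noise, demographic structure and spike schedules
    so the full pipeline is testable without platform data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
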