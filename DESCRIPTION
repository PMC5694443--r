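Package: daindex
Title: Digital Arthritis Index from Home-Cage Activity Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to derive a per-animal, per-day Digital Arthritis Index
    (DAI) from continuous home-cage activity traces of rats in
    collagen-induced arthritis (CIA) studies, to call disease incidence,
    onset and severity against fixed thresholds alongside standard clinical
    measures (ankle joint size, arthritis score, histopathology), and to
    rank candidate compounds by therapeutic response.  A seeded synthetic
    cohort simulator reproduces the statistical structure the pipeline
    assumes so every stage can be tested without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
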