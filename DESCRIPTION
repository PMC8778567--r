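Package: malolda
Title: Heart-Disease Screening with Ant Lion Feature Selection and
    Linear Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary modified ant lion optimization (MALO) for wrapper
    feature selection around a from-scratch Fisher linear discriminant
    classifier, with rule-based vital-sign screening, Cleveland-schema
    preprocessing, confusion-matrix metrics, and a synthetic-data
    generator for planted-signal benchmarking. Tibble-first interfaces
    throughout, with tidy()/glance() methods and ggplot2 autoplot()
    support for fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
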