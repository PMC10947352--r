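Package: algrowth
Title: Meta-Regression of Axial Length Growth in Emmetropes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aggregate-data meta-regression of axial-length (AL)
    growth in emmetropic eyes. Reads study-level summary tables, imputes
    missing means and standard deviations from medians, interquartile ranges
    and ranges, screens studies against eligibility rules (emmetropia window,
    cycloplegia, optical biometry), weights studies by the precision of their
    AL and age summaries, and fits a weighted nonlinear mixed-effects
    asymptotic growth curve AL = a + b * exp(-c * age), combined and with
    ethnicity as a two-level grouping variable. Provides Wald tests on
    between-group parameter contrasts, delta-method confidence bands,
    age-specific growth tables, a study-level synthetic-data generator for
    end-to-end validation, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    MASS,
    minpack.lm,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
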