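Package: cotgrow
Title: Regional Cotton Growth Models Driven by Thermal Time and Reference Evapotranspiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling regional cotton growth with relative logistic
    curves driven by cumulative growing degree days (CGDD) or cumulative
    FAO-56 Penman-Monteith reference evapotranspiration (CETo). Computes
    daily and seasonal drivers from weather tables, fits and evaluates
    sigmoid growth models for plant height, leaf area index and dry matter,
    converts model parameters between the two driver bases through a linear
    driver link, and implements quadratic yield and leaf-area responses to
    irrigation together with their closed-form optima and irrigation water
    use efficiency. Includes a seasonal weather and growth-observation
    simulator so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
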