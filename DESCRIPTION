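Package: metdriver
Title: Metabolic Driver Discovery with Constraint-Based Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-step discovery pipeline for candidate metabolic tumor
    suppressors. Step one is a genomic screen combining differential
    expression, copy-number loss and Kaplan-Meier survival-curve area
    differences; step two scores each surviving gene by its ability to
    transform a healthy context-specific metabolic flux state into the
    tumor state, using constraint-based modeling: flux balance and flux
    variability analysis, GIMME and iMAT context-specific state inference,
    hit-and-run flux sampling, minimization of metabolic adjustment (MOMA),
    and a mixed-integer quadratic search for transforming knockouts whose
    outcomes are aggregated into oncogenic transformation scores. Includes
    a synthetic-data generator (toy metabolic networks with implanted
    driver genes, paired expression, copy-number and survival cohorts) so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    quadprog,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
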