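Package: fhrmr
Title: Quantitation, Association and Mendelian Randomization for
    Complement Factor H Family Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline from stable-isotope-dilution selected
    reaction monitoring (SRM) peak areas to circulating complement
    factor H family protein concentrations, case-control association
    with age-related macular degeneration, protein quantitative trait
    locus (pQTL) genome scans, and one- and two-sample Mendelian
    randomization (Wald ratio, fixed-effect inverse-variance weighting,
    Cochran's Q and I-squared). Includes a synthetic cohort generator
    with linkage-disequilibrium-blocked genotypes, cis/trans pQTL
    effects, logistic case-control sampling and noisy light/heavy peak
    areas, so every stage of the pipeline can be exercised and tested
    without access to individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
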