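Package: phenogrs
Title: Sensitivity of Genetic Risk Score Associations to EMR Phenotyping Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how electronic-medical-record (EMR) phenotyping
    decisions affect genetic association results for a quantitative lab trait,
    using HDL cholesterol as the worked case. Provides a seeded synthetic-EMR
    generator (longitudinal labs, clinical-note drug mentions, SNP genotypes),
    a lipid-lowering-medication lexicon scanner for dated notes, five per-subject
    HDL-C phenotype definitions (median of all, first, last, pre-medication,
    post-medication, with an adult-age filter), unweighted and weighted seven-SNP
    genetic risk scores with a non-missing-SNP denominator, sex-adjusted linear
    regression per phenotype definition, and a cross-definition effect-size
    comparison with forest-plot output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    lubridate,
    ggplot2,
    jsonlite,
    yaml,
    vcfR,
    digest,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
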