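Package: pedseg
Title: Family-Based Exome Variant Prioritization for Nuclear Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing exome variants in a nuclear family
    segregating a disease phenotype: hard quality-control filters for
    called variants (SNP clusters, mapping ambiguity, depth, quality,
    quality-by-depth, strand bias), a novelty/nonsynonymous segregation
    cascade contrasting affected and unaffected members, a
    functional-prediction consensus over five algorithm scores, a
    candidate-gene rare-allele burden test (Pearson chi-square with
    Woolf-interval odds ratios), and read-depth-based de novo mutation
    quality control. Includes a synthetic nuclear-family data generator
    with planted truth so every stage is testable without sequencing
    data, plus tidy() and glance() methods and ggplot2 visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
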