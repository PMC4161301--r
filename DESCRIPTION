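Package: bifanr
Title: Discovery of Cooperating eSNP Quartets (Bi-Fan Motifs) from
    Genotype and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers bi-fan regulatory motifs ("quartets") in which two
    expression-associated SNPs (eSNPs) cooperatively regulate the same pair
    of transcripts.  From a genotype matrix and a normalized expression
    matrix the pipeline maps single-SNP single-gene associations by additive
    linear regression, classifies SNP-gene-gene triplets as mutually or
    directionally independent via conditional regressions, assembles and
    filters quartets (cooperating sources, no better intermediate SNP,
    unique gene targets), calibrates counts against a sample-permutation
    null with an empirical false discovery rate, and characterizes quartets
    by genomic annotation, cis/trans class, dependency structure and the
    sign algebra of direction-of-effect configurations.  A synthetic-data
    module generates genotype and expression datasets with planted motif
    structure so every stage of the analysis is verifiable end to end.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
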