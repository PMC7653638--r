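Package: digenicscan
Title: Digenic Variant Prioritization in Family Exomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Prioritizes trans digenic candidate variant pairs in small
    family pedigrees from multi-sample exome VCFs. Implements rarity
    filtering against population allele frequencies, ensemble
    deleteriousness classification by majority vote over seven in-silico
    predictors, pedigree segregation scans (de novo, autosomal recessive,
    shared monoallelic with parental origin by transmission), cross-parental
    pairing of candidates into trans digenic gene pairs with gene-set
    membership restriction, and a synthetic family-exome generator with a
    planted causal pair for end-to-end benchmarking.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
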