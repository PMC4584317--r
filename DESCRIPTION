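Package: kinliab
Title: Liability-Threshold Heritability of Binary Traits in Twin Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the heritability of binary (threshold)
    traits such as hair colour from extended twin-family data and from
    genome-wide SNP data. Implements liability-threshold arithmetic and
    maximum-likelihood tetrachoric correlations; expected relative-pair
    correlations under sex-specific ADE/ACE/AE variance decompositions with
    phenotypic assortative mating; weighted-least-squares and full
    maximum-likelihood model fitting with likelihood-ratio tests; a pedigree
    simulator with the matching generative structure; and GREML
    (genetic-relationship-matrix restricted maximum likelihood) estimation of
    SNP heritability with GCTA-compatible GRM input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
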