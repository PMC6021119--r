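Package: diallelkit
Title: Combining-Ability Analysis of Half-Diallel Crosses and
    SNP-Based Prediction of Hybrid Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of half-diallel mating designs with
    parents (Griffing Method 2, Model 1 fixed effects): randomized
    complete block ANOVA with the GCA/SCA partition, estimation of
    general and specific combining abilities, variance components,
    GCA/SCA ratios, narrow- and broad-sense heritabilities, relative SCA
    percentages and mid-parent heterosis. Also provides Bonferroni-screened
    Pearson correlations among traits, identity-by-state and Hamming
    genetic distances from SNP genotypes in VCF files, UPGMA clustering
    with locus bootstrap support and Newick export, and correlation of
    parental genetic distance with hybrid trait values, heterosis and
    SCA. Includes synthetic-data generators for diallel phenotypes and
    cluster-structured SNP panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils,
    vcfR
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
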