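Package: vntrassoc
Title: VNTR Allele-Size Association, Linkage Disequilibrium, and
    Haplotype Score Analysis for Case/Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit linking variable number tandem repeat
    (VNTR) length polymorphisms to a binary disease-severity phenotype in
    extreme-phenotype case/control cohorts. Provides allele-spectrum
    construction and rank-sum comparison between severity groups,
    designated-allele genotype contingency tables with Freeman-Halton
    exact tests and a Bonferroni test ledger, carrier odds ratios,
    two-component mixture fitting for short/long allele dichotomization,
    two-locus haplotype-frequency EM from unphased genotypes for
    multiallelic VNTR x SNP pairs with r-squared and chi-square linkage
    disequilibrium maps, a nested allele-partition likelihood-ratio test
    for differential LD, permutation haplotype score tests, a synthetic
    cohort generator with known ground truth, and a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
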