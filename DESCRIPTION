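Package: autozyg
Title: Runs of Homozygosity, Autozygosity Statistics, and
    Inbreeding-Depression Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in SNP-array genotypes with a
    PLINK-style sliding-window scan, computes per-individual autozygosity
    statistics (F_ROH, with a long/short tract partition, and excess
    SNP-by-SNP homozygosity F_SNP), and fits nested covariate-adjusted
    regression model sets that test quantitative and binary traits for
    inbreeding depression while partitioning recessive effects into common-
    versus rare-variant homozygosity. Includes variant and sample quality
    control (exact Hardy-Weinberg test, minor-allele-frequency and
    missingness filters, variance-inflation-factor LD pruning, kinship-based
    unrelated-subset selection), PLINK 1 binary genotype input/output, and a
    synthetic-cohort generator that plants autozygous tracts, fully
    recessive phenotypes, and sociodemographic confounding so every stage of
    the pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
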