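Package: adpgx
Title: Pharmacogenetic Association Analysis of Antidepressant Treatment
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacogenetic analysis of
    antidepressant treatment response. Derives remission, response,
    percent symptom change and stem-depressed phenotypes from 21-item
    Hamilton Rating Scale for Depression (HRSD-21) trajectories; handles
    missing visits by chained-equation multiple imputation with Rubin-rules
    pooling; performs marker and sample genotype quality control (exact
    Hardy-Weinberg test, missingness, minor allele frequency, identity-by-
    state kinship, multidimensional-scaling outliers); runs covariate-
    adjusted additive single-marker association scans; aggregates marker
    signal into a permutation-based gene-level association test with
    linkage-disequilibrium pruning; and combines cohorts by inverse-gamma
    (Fisher) meta-analysis and pooled mega-analysis with effective-number-
    of-tests thresholds. Includes a synthetic two-cohort trial generator
    with known ground truth and PLINK 1.9 bed/bim/fam read/write support.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
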