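Package: melscreen
Title: FACS-Sorted CRISPR Screen Analysis and Population-Genetic
    Follow-Up for Melanin-Promoting Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide CRISPR knockout screens read
    out by two-bin FACS sorting (low/high side scatter as a proxy for
    cellular melanin), together with the population-genetic and expression
    follow-up analyses used to characterise screen hits. Provides a
    maximum-likelihood gene-effect estimator for sorted sgRNA counts with a
    control-guide empirical null, likelihood-ratio scores, profile
    confidence intervals and permutation-based false discovery rates;
    per-SNP Hudson F_ST and population branch statistic (PBS) selection
    scans with genome-wide empirical p-values and gene-window annotation;
    eQTL-GWAS effect-direction concordance and Fisher enrichment tests;
    Spearman correlation screening of expression against melanin content
    with Benjamini-Hochberg q-values; and seeded synthetic-data generators
    with known ground truth for every input type, supporting calibration
    and recovery testing of each stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
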