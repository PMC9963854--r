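Package: biallele
Title: Genotype-Free Allele-Specific Expression Screening from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens genomic imprinting loci for mono- versus bi-allelic
    expression directly from aligned RNA-seq reads, without parental
    genotypes. Implements a pileup-based variant caller with
    VarScan-style thresholds, the bi-allelic evidence filter chain
    (site depth, variant-frequency window, minimum SNPs per transcript,
    per-gene read gate), the SNP-per-kilobase transcript statistic, and
    a factorial ANOVA with Tukey post-hoc comparison of SNP frequency
    across treatment group and imprinting status with categorical
    covariates. Also provides the longitudinal differential-expression
    set comparison (CPM filtering, FDR thresholding, unique/common DEG
    set algebra with high-confidence subsets) and a synthetic-data
    module that simulates diploid transcripts, allele-aware aligned
    reads, count matrices and DEG tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    car,
    dplyr (>= 1.1.0),
    emmeans,
    generics,
    ggplot2,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Rsamtools,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
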