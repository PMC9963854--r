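# biallele

Genotype-free allele-specific expression screening from RNA-seq.

`biallele` asks, for each gene at a genomic imprinting locus, whether both
parental alleles are transcribed — using nothing but aligned RNA-seq reads.
Parental genotypes are never required: at a heterozygous site of a
bi-allelically expressed transcript, roughly half the reads carry the
non-reference base, so confident intermediate-frequency SNPs are the
footprint of bi-allelic expression. The package is aimed at embryo and
early-development transcriptomics, where samples (single blastocysts) come
from unknown parent pairs and imprinting status is the question.

## What it computes

For a transcript of mature length $L$ bp carrying $n$ confident SNPs, the
screen's statistic is the SNP frequency

$$\mathrm{SNP/kb} = \frac{1000\,n}{L},$$

low for mono-allelic (imprinted-like) and high for bi-allelic expression.
A SNP is *confident* when it survives the filter chain: a VarScan-style
caller (mean alt base quality ≥ 20, variant frequency ≥ 1%, alt reads
≥ 10), a site filter (depth > 25 and variant frequency within 20–80%), a
retention rule (≥ 3 such SNPs per transcript), and a per-gene gate of at
least 5000 reads summed over samples. SNP/kb is then compared across
treatment group × imprinting status by Type II ANOVA with sex and batch
covariates, with Tukey HSD on the four cell means
(`anova_snp_frequency()`).

Alongside, the package implements a longitudinal differential-expression
set comparison (`compare_transitions()`): CPM-filtered DEG tables from two
developmental transitions are intersected at FDR < 0.1, split into common
and transition-unique sets, and unique genes at FDR < 0.01 are flagged as
high-confidence — pure set algebra over tables fitted upstream.

A synthetic-data module (`simulate_allelic_reads()`,
`simulate_allelic_sites()`, `simulate_counts_and_degs()`) generates
diploid transcripts with planted parental SNPs, allele-aware aligned reads
(SAM/FASTA/BED), count matrices and truth-labelled DEG tables, so the
whole pipeline is testable without any sequencing download.

## A worked example

Simulate the study design — two groups of five blastocysts, imprinted
genes plus neighbours at shared loci, with imprinted genes mono-allelic
only in the supplemented (`MT+`) group — then call, filter, score and
test:

```r
library(biallele)

cfg <- sim_config(n_imprinted_genes = 10, n_neighbour_genes = 10, n_loci = 4,
                  n_samples_per_group = 5, transcript_len_range = c(2000L, 4000L),
                  mean_coverage = 200, parental_snp_density = 1,
                  imprinted_monoallelic_in = "MT+", seed = 42)
sim       <- simulate_allelic_sites(cfg)
calls     <- call_variants(sim$pileup)
summaries <- score_allelic_expression(calls, sim$models, sim$gene_read_counts)
anova_snp_frequency(summaries, sim$meta)
#> Factorial ANOVA of SNP frequency (SNP/kb)
#>           term   sumsq  df statistic   p_value
#>          group  3.2433   1    7.0120 8.766e-03
#>         status 12.0090   1   25.9630 8.258e-07
#>            sex  1.2869   1    2.7823 9.693e-02
#>  sampling_date  0.2739   1    0.5923 4.425e-01
#>   library_date  0.8194   1    1.7715 1.848e-01
#>   group:status  9.5311   1   20.6060 9.912e-06
#>      Residuals 89.2705 193        NA        NA
#>
#> Tukey HSD on group x status cell means:
#>  group_1      status_1 group_2      status_2 estimate     se adj_p_value
#>      MT-     imprinted     MT+     imprinted  0.70023 0.1384   5.824e-06
#>      MT-     imprinted     MT- non-imprinted -0.05348 0.1360   9.793e-01
#>      MT-     imprinted     MT+ non-imprinted -0.22645 0.1384   3.610e-01
#>      MT+     imprinted     MT- non-imprinted -0.75371 0.1384   9.336e-07
#>      MT+     imprinted     MT+ non-imprinted -0.92668 0.1360   7.114e-10
#>      MT- non-imprinted     MT+ non-imprinted -0.17297 0.1384   5.961e-01
```

Read it bottom-up: within the supplemented group the imprinted class sits
0.93 SNP/kb below its neighbour genes (adjusted p ≈ 7×10⁻¹⁰) — the
mono-allelic signature — while within the non-supplemented group the same
contrast is flat (p ≈ 0.98), and the interaction term captures exactly
this asymmetry. The per-transcript statistic underneath is plain
arithmetic:

```r
snp_frequency(3, 7560)          # a 7,560 bp transcript with 3 SNPs
#> [1] 0.3968254
round(snp_frequency(3, 7560), 2)
#> [1] 0.4
```

`plot_snp_frequency(summaries, sim$meta)` draws the jittered per-class
boxplots, and `tidy()`/`glance()` methods expose every result as a tibble.

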