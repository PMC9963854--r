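---
title: "Screening imprinting loci for bi-allelic expression without parental genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening imprinting loci for bi-allelic expression without parental genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biallele)
library(dplyr)
```

## The problem

Imprinted genes are expressed predominantly from one parental allele. With
parental genotypes in hand, allele-specific expression is read off directly
by phasing; without them — the situation for embryos derived from abattoir
oocytes fertilised by commercial semen — allelic expression has to be
inferred from the RNA-seq reads alone. The inference `biallele` implements
rests on a simple signal: at a site where the two parental alleles differ
and *both* are transcribed, roughly half the reads carry the non-reference
base, so the site shows an intermediate variant frequency. A transcript
expressed from one allele only presents no such site: every position is
effectively homozygous in the read pool (apart from sequencing error).
Counting *confident heterozygous sites per kilobase of transcript*
(SNP/kb) therefore separates mono-allelic (low) from bi-allelic (high)
expression, and doing so across imprinted genes and their non-imprinted
neighbours at the same loci controls for regional differences in parental
heterozygosity.

## The filter chain

Candidate sites come from a pileup of coordinate-mapped reads and a
VarScan-style caller, and pass through four successive filters. All of the
thresholds are exposed; the defaults are the screen's published operating
point.

| stage | rule | default | boundary |
|---|---|---|---|
| caller | mean Phred of alt bases | ≥ 20 | inclusive |
| caller | alt fraction of depth | ≥ 0.01 | inclusive |
| caller | alt-supporting reads | ≥ 10 | inclusive |
| site filter | site depth | > 25 | strict |
| site filter | variant frequency | 20–80% | inclusive both ends |
| transcript filter | confident SNPs per transcript | ≥ 3 | inclusive |
| gene gate | reads summed over all samples | ≥ 5000 | inclusive |

Three boundary conventions deserve comment, since the verbal rules leave
them open. The caller thresholds are inclusive because that is the
documented behaviour of the tool whose options they mirror. The site-depth
rule is strict (`> 25`, i.e. keep 26) while the read gate is inclusive
("5000 or more"), preserving the distinction between ">" and "or more" in
the source descriptions. Retention at *exactly* three SNPs per transcript
is deliberate: the IGF2R worked example reports a transcript with exactly
three SNPs *and* a computed SNP frequency, so three must be kept even
though the verbal rule ("more than three kept … fewer than three
discarded") never states the case. Transcripts below the rule are not
silently dropped: they are reported with `retained = FALSE`, because a
transcript whose candidate SNPs were all discarded is exactly what
mono-allelic expression looks like.

The statistic itself is trivial — `snp_frequency(n, L) = 1000 n / L` — and
is computed at full precision; rounding to two decimals happens only in
display. Sites are treated as strictly bi-allelic: only the most frequent
non-reference base is evaluated (ties broken A < C < G < T) and indels are
ignored throughout, since the screen concerns SNPs in mature transcripts.
The mean variant frequency of a transcript is the unweighted mean over its
confident SNPs; a read-weighted mean would be dominated by the deepest
site, and nothing in the published numbers lets the two be distinguished.

Coordinates follow the two conventions of the formats involved: gene
annotation is 0-based half-open (BED), pileup positions are 1-based
inclusive (mpileup). `bed_to_pileup()` is the single point of conversion.
Base-quality floors for tallying default to 0 — every base counts, and
quality enters only through the caller's mean-quality rule; no BAQ-style
adjustment is applied.

## Locus aggregation

A locus-level SNP frequency sums confident SNPs and transcript lengths
over member genes of a class (imprinted vs neighbours) and recomputes
SNP/kb from the totals. The accounting matters: in the published locus
totals, the summed transcript length spans *all* analysed members while
discarded transcripts contribute no SNPs (ten neighbour genes, 27 SNPs,
29,281 bp — impossible if only ≥3-SNP transcripts counted toward the
length, as ten such transcripts would carry at least 30 SNPs). The default
`members = "analysed"` reproduces that accounting; `members = "retained"`
restricts both sums to retained transcripts.

## The group comparison

`anova_snp_frequency()` fits

```
snp_per_kb ~ group * status + sex + sampling_date + library_date
```

on the per-transcript, per-sample summaries, where `group` is the
treatment (mtDNA-supplemented `MT+` vs non-supplemented `MT-`) and
`status` is imprinted vs non-imprinted. Design choices, each switchable:

* **Non-retained transcripts enter the response as 0 SNP/kb** (default
  `nonretained = "zero"`). Dropping them would delete precisely the
  observations that carry the mono-allelic signature and can empty an
  entire design cell — with supplemented-group imprinted genes
  mono-allelic, the imprinted × `MT+` cell would contain almost no
  retained transcript and the contrast of interest could not be formed.
* **Type II sums of squares** (via `car::Anova`), robust to the unbalance
  that dropped genes introduce; `ss_type = 3` switches.
* **Covariates as additive categorical main effects only.** Five samples
  per group cannot support covariate interactions. Single-level covariates
  are dropped with a message; sex calls that remain ambiguous should be
  passed as their own level rather than removing the sample.
* **Tukey HSD on the four `group × status` cell means** (through
  `emmeans`), giving the two within-group imprinted-vs-neighbour
  contrasts at a family-wise error controlled over the six cell pairs.
* A constant response (e.g. everything filtered to zero) returns an
  object flagged `constant_response` with `NA` statistics rather than an
  error; a rank-deficient design errors, naming the aliased terms.

Sex itself is called from the counts: a sample is male iff its mean CPM
over user-supplied Y-linked markers reaches 1 CPM (`determine_sex()`), a
rule that is monotone in the threshold and recovers simulated sexes
exactly at realistic library sizes.

## The longitudinal DEG comparison

The second, independent analysis consumes two differential-expression
tables — one per oocyte→blastocyst transition — and performs pure set
algebra; it never refits models or recomputes FDRs. Genes significant at
FDR < 0.1 (strict) in both transitions are `common`; genes significant in
exactly one are unique to it, and unique genes at FDR < 0.01 in their own
table form the high-confidence subsets. "Unique to A" means *significant
in A and not significant in B at the same cut*: a gene that was
CPM-filtered out of B's table before fitting counts as not significant
there, and the membership table flags table absence (`in_table_a`,
`in_table_b`) so both readings of the pre-filter question stay
recoverable. The CPM filter keeps a gene reaching 1 CPM in strictly more
than the stated number of samples, on raw library sizes.

## What the synthetic data emulate

The generators exist so that every stage is testable without the
sequencing archives. They emulate, per the study design: 5 + 5 blastocysts
in two treatment groups with balanced sex and two balanced two-level batch
factors; a panel of imprinted genes and non-imprinted neighbours grouped
into loci on a few chromosomes (defaults 10 + 73 over 6 loci on 4
chromosomes); single-exon transcripts of 1–10 kb; parental heterozygosity
of ~1 het site per kb of transcript (bracketed by the ~1-per-300-bp
genome-wide human figure and the 0.3–2 SNP/kb transcripts such screens
observe); mono-allelic (maternal fraction 1 or 0) versus balanced (0.5)
expression; uniform edge-truncated read starts at a configurable mean
coverage; per-base errors at rate *e* flipping to a uniform other base;
and Phred qualities drawn Normal(35, 3) truncated to [2, 41], so the
quality filter can be exercised in both directions.

Two grains of generator share one configuration:

* `simulate_allelic_reads()` materialises SAM records against an emitted
  per-chromosome FASTA reference, with BED annotation and a truth table
  on the side. Truth is output only — the scoring functions never read it.
* `simulate_allelic_sites()` draws the pileup tallies those reads would
  induce at planted sites: depth is Binomial over read placements and the
  alternate count is Binomial(depth, f) with
  `f = (1 − r)(1 − e) + r e/3` for maternal fraction `r`. A
  goodness-of-fit test in the suite checks the read-level path induces
  exactly this law, and a paired run of both generators checks they agree
  on detected SNP rates. Pure-error sites (no planted SNP) are not
  materialised: at depth 200 and e = 0.5% the chance that a specific
  wrong base accumulates the 10 supporting reads the caller requires is
  below 10⁻¹², so such sites cannot produce calls.

Each blastocyst is treated as an independent mating: het sites are planted
per gene × sample on a shared reference backbone (the maternal allele
always matches the reference, so variant frequency estimates the paternal
read fraction). This mirrors a study population drawn from many dams and
sires and makes gene × sample observations independent in the replication
studies. What the simulations do *not* model: splicing (the statistic uses
mature transcript length only, so single-exon transcripts lose nothing
that is scored), PCR duplicates, indels, strand-specific protocols,
quality miscalibration, and reference/mapping bias — recovery rates on
synthetic data are therefore upper bounds on real-data behaviour, and the
pipeline's robustness to mapping artefacts is untested by design.

## Validation studies and their sizes

The replicated studies in the test suite run at sizes chosen to make their
statistical targets sharp while the whole suite stays quick to run:

* *Imprinting recovery*: 100 replicates of 5 + 5 samples, 20 + 20 genes of
  2–4 kb, 200× coverage, 1 SNP/kb, 0.5% error, imprinted genes
  mono-allelic in the supplemented group only. The within-`MT+`
  imprinted-vs-neighbour Tukey contrast must be significant and the
  within-`MT-` one not, in at least 90% of replicates.
* *Type-I calibration*: 1000 all-null replicates (12 genes, 5 + 5
  samples, everything bi-allelic); the supplementation term's rejection
  rate at α = 0.05 must stay within [2%, 9%].
* *Density recovery*: 60 bi-allelic 1 kb genes at 200×, 5 SNP/kb planted;
  the mean recovered SNP/kb must land within 20% of the planted density.
  The shortfall that remains is structural, not a bug: transcripts drawing
  fewer than three detectable sites are zeroed by the retention rule, and
  sites within a read length of a transcript edge run at reduced depth.
* *Caller equivalence*: on randomly generated SAM files with soft clips,
  insertions and deletions, pileup tallies and calls must match an
  independently coded per-read enumerator exactly.

All generators are deterministic under their seed — identical
configurations give byte-identical FASTA/SAM/TSV output — so every study
above is reproducible line by line.

## A worked sliver

```{r example}
cfg <- sim_config(n_imprinted_genes = 4, n_neighbour_genes = 4, n_loci = 2,
                  n_samples_per_group = 3,
                  transcript_len_range = c(2000L, 3000L),
                  mean_coverage = 150, parental_snp_density = 2,
                  imprinted_monoallelic_in = "MT+", seed = 7)
sim <- simulate_allelic_sites(cfg)
calls <- call_variants(sim$pileup)
summaries <- score_allelic_expression(calls, sim$models,
                                      sim$gene_read_counts)
summaries |>
  inner_join(sim$meta, by = "sample_id") |>
  group_by(group, imprinted) |>
  summarise(mean_snp_per_kb = mean(ifelse(retained, snp_per_kb, 0)),
            .groups = "drop")
```

With only eight genes and three samples per group this is far below the
sizes the ANOVA needs, but the separation of the `MT+` imprinted class is
already visible in the cell means.

## Known limitations

The screen cannot assign parental origin — a transcript scored
mono-allelic might be expressed from either allele, and distinguishing
imprinting from, e.g., random mono-allelic expression needs orthogonal
data. Low parental heterozygosity mimics mono-allelic expression; the
locus design mitigates but cannot remove this, which is why neighbour
genes at the same locus are the comparison class. The 5000-read gate is
applied to both classes by default (symmetric treatment;
`gate_imprinted_only = TRUE` restores the literal asymmetric reading).
Finally, CPM values here are unnormalised by design — TMM or similar
belongs upstream with the DEG fitting, which this package deliberately
consumes rather than reimplements.
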