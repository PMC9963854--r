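mk_call <- function(depth, vf, gene_id = "g1", sample_id = "s1", pos = 100L) {
  tibble::tibble(
    sample_id = sample_id, gene_id = gene_id, chromosome = "chr1",
    pos = pos, ref_base = "A", alt_base = "C",
    depth = as.integer(depth),
    alt_reads = as.integer(round(vf / 100 * depth)),
    variant_frequency = vf, mean_alt_quality = 35)
}

test_that("site filter applies the strict depth and inclusive frequency bounds", {
  filt <- allelic_filter()
  expect_equal(nrow(filter_biallelic_snps(mk_call(25, 50), filt)), 0L)  # >25 strict
  expect_equal(nrow(filter_biallelic_snps(mk_call(26, 50), filt)), 1L)
  expect_equal(nrow(filter_biallelic_snps(mk_call(26, 20), filt)), 1L)  # inclusive
  expect_equal(nrow(filter_biallelic_snps(mk_call(26, 80), filt)), 1L)  # inclusive
  expect_equal(nrow(filter_biallelic_snps(mk_call(100, 81), filt)), 0L)
  expect_equal(nrow(filter_biallelic_snps(mk_call(100, 19.9), filt)), 0L)
})

test_that("the gene read gate is inclusive at its threshold", {
  filt <- allelic_filter()
  counts <- tibble::tibble(
    gene_id = c("a", "a", "b", "b", "c"),
    sample_id = c("s1", "s2", "s1", "s2", "s1"),
    reads = c(2500, 2500, 2499, 2500, 10000))
  eligible <- gate_gene_depth(counts, filt)
  expect_setequal(eligible$gene_id, c("a", "c"))  # 5000 kept, 4999 dropped
  empty <- gate_gene_depth(counts[0, ], filt)
  expect_equal(nrow(empty), 0L)
})

test_that("snp_frequency reproduces the worked examples exactly", {
  expect_equal(round(snp_frequency(3, 7560), 2), 0.40)
  expect_equal(round(snp_frequency(27, 29281), 2), 0.92)
  expect_equal(snp_frequency(0, 1000), 0)
  expect_error(snp_frequency(1, 0), class = "biallele_input_error")
})

test_that("snp_frequency is linear in the SNP count", {
  for (n in c(1, 4, 9)) {
    expect_equal(snp_frequency(2 * n, 3456), 2 * snp_frequency(n, 3456))
  }
})

test_that("transcript summaries count, normalise and apply the retention rule", {
  models <- tibble::tibble(gene_id = "igf2r_like", chromosome = "chr1",
                           start = 0L, end = 7560L, strand = "+",
                           transcript_length_bp = 7560L,
                           imprinted = TRUE, locus_id = "L1")
  calls3 <- dplyr::bind_rows(lapply(c(100L, 200L, 300L), function(p)
    mk_call(50, 52, gene_id = "igf2r_like", pos = p)))
  s3 <- summarize_transcripts(calls3, models, "s1")
  expect_true(s3$retained)
  expect_equal(s3$n_confident_snps, 3L)
  expect_equal(round(s3$snp_per_kb, 2), 0.40)
  expect_equal(s3$mean_variant_frequency, 52)
  # two SNPs are discarded as potential artefacts
  s2 <- summarize_transcripts(calls3[1:2, ], models, "s1")
  expect_false(s2$retained)
  expect_equal(s2$n_confident_snps, 2L)
  # zero SNPs still reported, snp_per_kb 0
  s0 <- summarize_transcripts(calls3[0, ], models, "s1")
  expect_false(s0$retained)
  expect_equal(s0$snp_per_kb, 0)
  expect_true(is.na(s0$mean_variant_frequency))
})

test_that("calls without a gene label are assigned by genomic position", {
  models <- tibble::tibble(
    gene_id = c("g1", "g2"), chromosome = "chr1",
    start = c(0L, 1000L), end = c(500L, 1800L), strand = "+",
    transcript_length_bp = c(500L, 800L), imprinted = c(TRUE, FALSE),
    locus_id = "L1")
  calls <- mk_call(50, 50, pos = 1500L)[, setdiff(names(mk_call(50, 50)), "gene_id")]
  s <- summarize_transcripts(calls, models, "s1")
  expect_equal(s$n_confident_snps[s$gene_id == "g2"], 1L)
  expect_equal(s$n_confident_snps[s$gene_id == "g1"], 0L)
  # position 500 is outside g1 (half-open) -- no assignment
  calls_edge <- mk_call(50, 50, pos = 500L)[, setdiff(names(mk_call(50, 50)), "gene_id")]
  s_edge <- summarize_transcripts(calls_edge, models, "s1")
  expect_equal(sum(s_edge$n_confident_snps), 1L)
  expect_equal(s_edge$n_confident_snps[s_edge$gene_id == "g1"], 1L)
})

test_that("locus aggregation sums retained members and matches the neighbour example", {
  # ten neighbour genes carrying 27 SNPs over 29,281 bp in one sample
  lens <- c(2928L, 2928L, 2928L, 2928L, 2928L, 2928L, 2928L, 2928L, 2928L, 2929L)
  snps <- c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 0L)
  models <- tibble::tibble(
    gene_id = sprintf("n%02d", 1:10), chromosome = "chr1",
    start = cumsum(c(0L, lens[-10])), end = cumsum(lens), strand = "+",
    transcript_length_bp = lens, imprinted = FALSE, locus_id = "L1")
  summaries <- tibble::tibble(
    gene_id = models$gene_id, sample_id = "mtplus_05",
    n_confident_snps = snps, transcript_length_bp = lens,
    snp_per_kb = snp_frequency(snps, lens),
    mean_variant_frequency = 50, retained = snps >= 3,
    imprinted = FALSE, locus_id = "L1")
  agg <- aggregate_locus(summaries, models)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$total_snps, 27L)
  # every analysed member contributes its length: 29,281 bp in total
  expect_equal(agg$total_length_bp, 29281L)
  expect_equal(round(agg$snp_per_kb, 2), 0.92)
  # restricting to retained members drops the zero-SNP transcript
  agg_ret <- aggregate_locus(summaries, models, members = "retained")
  expect_equal(agg_ret$total_length_bp, 29281L - 2929L)
  # a single retained gene aggregates to its own summary
  one <- aggregate_locus(summaries[1, ], models[1, ])
  expect_equal(one$snp_per_kb, summaries$snp_per_kb[1])
  # no retained members -> omitted under the retained-only accounting
  none <- aggregate_locus(dplyr::mutate(summaries, retained = FALSE), models,
                          members = "retained")
  expect_equal(nrow(none), 0L)
})

test_that("the filter chain is idempotent", {
  filt <- allelic_filter()
  calls <- dplyr::bind_rows(mk_call(30, 50), mk_call(20, 50, pos = 2L),
                            mk_call(100, 90, pos = 3L), mk_call(60, 20, pos = 4L))
  once <- filter_biallelic_snps(calls, filt)
  twice <- filter_biallelic_snps(once, filt)
  expect_identical(once, twice)
  counts <- tibble::tibble(gene_id = c("a", "b"), sample_id = "s1",
                           reads = c(6000, 100))
  g1 <- gate_gene_depth(counts, filt)
  g2 <- gate_gene_depth(dplyr::mutate(g1, sample_id = "s1", reads = total_reads),
                        filt)
  expect_equal(g1$gene_id, g2$gene_id)
})

test_that("the pipeline recovers the planted SNP density on bi-allelic genes", {
  # 60 bi-allelic genes, depth 200, error 0.5%, 5 SNP/kb planted: the mean
  # SNP/kb across genes should land within 20% of the planted density
  cfg <- sim_config(n_imprinted_genes = 0, n_neighbour_genes = 60, n_loci = 5,
                    n_samples_per_group = 1, transcript_len_range = c(1000L, 1000L),
                    mean_coverage = 200, parental_snp_density = 5,
                    base_error_rate = 0.005, seed = 91)
  sim <- simulate_allelic_reads(cfg)
  s1 <- sim$meta$sample_id[1]
  reads1 <- dplyr::filter(sim$reads, sample_id == s1)
  calls <- list()
  for (g in seq_len(nrow(sim$models))) {
    p <- pileup(reads1, sim$models[g, ], sim$reference)
    if (nrow(p) == 0) next
    p$sample_id <- s1
    calls[[length(calls) + 1L]] <- call_variants(p)
  }
  summ <- score_allelic_expression(
    dplyr::bind_rows(calls), sim$models, sim$gene_read_counts,
    sample_ids = s1, filter = allelic_filter(min_gene_reads_total = 0))
  observed <- mean(ifelse(summ$retained, summ$snp_per_kb, 0))
  expect_lt(abs(observed - 5) / 5, 0.20)
  # retained bi-allelic transcripts concentrate near 50% variant frequency
  vf <- summ$mean_variant_frequency[summ$retained]
  expect_true(all(vf >= 40 & vf <= 60))
})

test_that("mono-allelic genes score near-zero SNP/kb", {
  cfg <- sim_config(n_imprinted_genes = 20, n_neighbour_genes = 0, n_loci = 2,
                    n_samples_per_group = 1, transcript_len_range = c(800L, 800L),
                    mean_coverage = 200, parental_snp_density = 5,
                    base_error_rate = 0.005, allelic_ratio_imprinted = 1,
                    seed = 92)
  sim <- simulate_allelic_sites(cfg)
  calls <- call_variants(sim$pileup)
  summ <- score_allelic_expression(calls, sim$models, sim$gene_read_counts,
                                   filter = allelic_filter(min_gene_reads_total = 0))
  observed <- mean(ifelse(summ$retained, summ$snp_per_kb, 0))
  expect_lt(observed, 0.05 * 5)
})
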