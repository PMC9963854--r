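# a minimal single-gene configuration where every read spans the whole
# transcript, so planted sites sit at full depth
spanning_cfg <- function(coverage, error = 0, seed = 1) {
  sim_config(n_imprinted_genes = 0, n_neighbour_genes = 1, n_loci = 1,
             n_samples_per_group = 1, transcript_len_range = c(100L, 100L),
             read_len = 100L, mean_coverage = coverage,
             base_error_rate = error, seed = seed)
}

one_gene_model <- function(cfg) make_gene_models(cfg)[1, ]

# haplotype pair with one planted site at transcript position 50
planted_pair <- function(seed) {
  withr::with_seed(seed, {
    ref <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                 collapse = "")
  })
  b <- substring(ref, 50, 50)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  pat <- ref
  substr(pat, 50, 50) <- alt
  list(maternal = ref, paternal = pat, alt = alt, ref = ref)
}

vf_at_site <- function(reads, model, reference, site_pos) {
  p <- pileup(reads, model, reference)
  at <- p[p$pos == site_pos & p$base != p$ref_base, ]
  if (nrow(at) == 0) return(0)
  100 * max(at$count) / at$depth[1]
}

test_that("balanced allelic ratio gives ~50% variant frequency at depth 200", {
  cfg <- spanning_cfg(coverage = 200)
  model <- one_gene_model(cfg)
  hp <- planted_pair(11)
  # reference holds the gene sequence at its genomic coordinates
  full_ref <- paste(c(rep("A", model$start), strsplit(hp$ref, "")[[1]],
                      rep("A", 1000)), collapse = "")
  reference <- setNames(full_ref, model$chromosome)
  site_pos <- model$start + 50L
  ok <- vapply(1:100, function(s) {
    reads <- simulate_reads(hp, 0.5, model, cfg, seed = s)
    vf <- vf_at_site(reads, model, reference, site_pos)
    vf >= 40 && vf <= 60
  }, logical(1))
  expect_gte(sum(ok), 95L)
})

test_that("mono-allelic expression leaves no site in the bi-allelic window", {
  cfg <- spanning_cfg(coverage = 200)
  model <- one_gene_model(cfg)
  hp <- planted_pair(13)
  full_ref <- paste(c(rep("A", model$start), strsplit(hp$ref, "")[[1]],
                      rep("A", 1000)), collapse = "")
  reference <- setNames(full_ref, model$chromosome)
  reads <- simulate_reads(hp, 1.0, model, cfg, seed = 21)
  p <- pileup(reads, model, reference)
  calls <- call_variants(p, caller_thresholds(min_reads2 = 1, min_avg_qual = 0,
                                              min_var_freq = 0))
  inside <- calls[calls$variant_frequency >= 20 & calls$variant_frequency <= 80, ]
  expect_equal(nrow(inside), 0L)
})

test_that("total sequenced nucleotides track coverage times length", {
  cfg <- sim_config(n_imprinted_genes = 0, n_neighbour_genes = 1, n_loci = 1,
                    n_samples_per_group = 1, transcript_len_range = c(1537L, 1537L),
                    mean_coverage = 60, seed = 2)
  model <- make_gene_models(cfg)[1, ]
  hp <- plant_parental_snps(model, density = 1, seed = 3)
  reads <- simulate_reads(hp, 0.5, model, cfg, seed = 4)
  total_nt <- sum(nchar(reads$seq))
  expect_lt(abs(total_nt - 60 * 1537) / (60 * 1537), 0.10)
})

test_that("a read length longer than the transcript is a configuration error", {
  cfg <- spanning_cfg(coverage = 10)
  model <- one_gene_model(cfg)
  hp <- list(maternal = paste(rep("A", 50), collapse = ""),
             paternal = paste(rep("A", 50), collapse = ""))
  expect_error(simulate_reads(hp, 0.5, model, cfg),
               class = "biallele_config_error")
})

test_that("identical configurations give byte-identical simulated files", {
  cfg <- sim_config(n_imprinted_genes = 1, n_neighbour_genes = 2, n_loci = 1,
                    n_samples_per_group = 2, transcript_len_range = c(300L, 500L),
                    mean_coverage = 20, seed = 77)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  for (d in c(dir1, dir2)) {
    sim <- simulate_allelic_reads(cfg)
    write_sam(sim$reads, file.path(d, "reads.sam"), sim$reference)
    write_reference_fasta(sim$reference, file.path(d, "ref.fa"))
    write_bed(sim$models, file.path(d, "genes.bed"))
    readr::write_tsv(sim$truth_sites, file.path(d, "truth.tsv"))
  }
  for (f in c("reads.sam", "ref.fa", "genes.bed", "truth.tsv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("allelic counts at a planted site are Binomial(depth, f)", {
  # every read spans the site; with maternal fraction r and error e the
  # alternate-base probability is f = (1-r)(1-e) + r e/3
  cfg <- spanning_cfg(coverage = 100, error = 0.01)
  model <- one_gene_model(cfg)
  hp <- planted_pair(17)
  full_ref <- paste(c(rep("A", model$start), strsplit(hp$ref, "")[[1]],
                      rep("A", 1000)), collapse = "")
  reference <- setNames(full_ref, model$chromosome)
  site_pos <- model$start + 50L
  f <- 0.5 * (1 - 0.01) + 0.5 * 0.01 / 3
  alt_counts <- vapply(1:200, function(s) {
    reads <- simulate_reads(hp, 0.5, model, cfg, seed = 1000 + s)
    p <- pileup(reads, model, reference)
    at <- p[p$pos == site_pos & p$base == hp$alt, ]
    if (nrow(at) == 0) 0L else at$count
  }, integer(1))
  # chi-square goodness of fit against Binomial(100, f), binned by quintile
  qs <- qbinom(c(0.2, 0.4, 0.6, 0.8), 100, f)
  breaks <- c(-Inf, qs, Inf)
  obs <- table(cut(alt_counts, breaks))
  pr <- diff(c(0, pbinom(qs, 100, f), 1))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("site-level and read-level simulators agree on detected SNP rates", {
  # same configuration through both paths; compare the mean confident SNP
  # count per transcript
  cfg <- sim_config(n_imprinted_genes = 0, n_neighbour_genes = 12, n_loci = 2,
                    n_samples_per_group = 2, transcript_len_range = c(800L, 1200L),
                    mean_coverage = 120, parental_snp_density = 4,
                    base_error_rate = 0.005, seed = 31)
  site_sim <- simulate_allelic_sites(cfg)
  site_calls <- call_variants(site_sim$pileup)
  site_summ <- score_allelic_expression(site_calls, site_sim$models,
                                        site_sim$gene_read_counts,
                                        filter = allelic_filter(min_gene_reads_total = 0))
  read_sim <- simulate_allelic_reads(cfg)
  read_calls <- list()
  for (g in seq_len(nrow(read_sim$models))) {
    model <- read_sim$models[g, ]
    for (s in read_sim$meta$sample_id) {
      p <- pileup(dplyr::filter(read_sim$reads, sample_id == s), model,
                  read_sim$reference)
      if (nrow(p) == 0) next
      p$sample_id <- s
      read_calls[[length(read_calls) + 1L]] <- call_variants(p)
    }
  }
  read_summ <- score_allelic_expression(dplyr::bind_rows(read_calls),
                                        read_sim$models,
                                        read_sim$gene_read_counts,
                                        filter = allelic_filter(min_gene_reads_total = 0))
  m_site <- mean(site_summ$n_confident_snps)
  m_read <- mean(read_summ$n_confident_snps)
  expect_gt(m_site, 0)
  expect_gt(m_read, 0)
  expect_lt(abs(m_site - m_read) / m_read, 0.25)
})
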