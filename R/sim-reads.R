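# RNG discipline: every public generator takes a seed and scopes it with
# withr::with_seed; `seed = NULL` means "use the current RNG stream", which
# lets the dataset orchestrators draw everything from one seeded stream.
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# plant heterozygous sites on an existing reference transcript
plant_on_reference <- function(reference, density) {
  len <- nchar(reference)
  k <- min(rpois(1L, density * len / 1000), len)
  if (k == 0L) {
    return(list(paternal = reference,
                sites = tibble(position = integer(), ref = character(),
                               alt = character())))
  }
  pos <- sort(sample.int(len, k))
  ref_alleles <- substring(reference, pos, pos)
  alt_alleles <- vapply(ref_alleles,
                        function(b) sample(setdiff(.BASES, b), 1L),
                        character(1), USE.NAMES = FALSE)
  pat <- reference
  for (i in seq_along(pos)) {
    substr(pat, pos[i], pos[i]) <- alt_alleles[i]
  }
  list(paternal = pat,
       sites = tibble(position = pos, ref = ref_alleles, alt = alt_alleles))
}

phred_to_string <- function(q) intToUtf8(q + 33L)

draw_phred <- function(n, mean_q) {
  pmin(pmax(as.integer(round(rnorm(n, mean_q, 3))), 2L), 41L)
}

#' Simulate aligned reads from a parental haplotype pair
#'
#' Draws `round(mean_coverage * L / read_len)` reads with uniform
#' (edge-truncated) start positions over one transcript. Each read comes
#' from the maternal haplotype with probability `allelic_ratio`, has each
#' base flipped to a random other base with probability `base_error_rate`,
#' and carries Phred qualities drawn Normal(`base_quality_mean`, 3)
#' truncated to `[2, 41]`. Reads are reported as mapped SAM records against
#' the reference chromosome of `model` (single-exon transcripts, so the
#' CIGAR is always a full-length match).
#'
#' @param haplotypes List with `maternal` and `paternal` transcript
#'   sequences of equal length (see [plant_parental_snps()]).
#' @param allelic_ratio Probability a read is drawn from the maternal
#'   haplotype.
#' @param model One-row gene-model tibble giving `chromosome` and 0-based
#'   `start` used to place reads genomically.
#' @param config A [sim_config()] (supplies coverage, read length, error
#'   rate, quality model).
#' @param sample_id Sample label stamped into read names.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A tibble of SAM fields: `qname`, `flag`, `rname`, `pos` (1-based
#'   leftmost), `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`.
#' @examples
#' cfg <- sim_config(n_imprinted_genes = 0, n_neighbour_genes = 1,
#'                   transcript_len_range = c(500, 500), mean_coverage = 20)
#' m <- make_gene_models(cfg)[1, ]
#' hp <- plant_parental_snps(m, density = 1, seed = 3)
#' simulate_reads(hp, 0.5, m, cfg, seed = 4)
#' @export
simulate_reads <- function(haplotypes, allelic_ratio, model, config,
                           sample_id = "sample", seed = NULL) {
  len <- nchar(haplotypes$maternal)
  rl <- config$read_len
  if (rl > len) {
    abort("`read_len` exceeds the transcript length.", class = "biallele_config_error")
  }
  n_reads <- max(1L, as.integer(round(config$mean_coverage * len / rl)))
  maybe_with_seed(seed, {
    starts <- sample.int(len - rl + 1L, n_reads, replace = TRUE)
    maternal <- runif(n_reads) < allelic_ratio
    seqs <- character(n_reads)
    if (any(maternal)) {
      seqs[maternal] <- substring(haplotypes$maternal, starts[maternal],
                                  starts[maternal] + rl - 1L)
    }
    if (any(!maternal)) {
      seqs[!maternal] <- substring(haplotypes$paternal, starts[!maternal],
                                   starts[!maternal] + rl - 1L)
    }
    if (config$base_error_rate > 0) {
      n_err <- rbinom(n_reads, rl, config$base_error_rate)
      for (i in which(n_err > 0L)) {
        at <- sample.int(rl, n_err[i])
        for (p in at) {
          b <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(.BASES, b), 1L)
        }
      }
    }
    quals <- draw_phred(n_reads * rl, config$base_quality_mean)
  })
  qmat <- matrix(quals, nrow = rl)
  qual_strings <- vapply(seq_len(n_reads),
                         function(i) phred_to_string(qmat[, i]),
                         character(1))
  tibble(
    qname = sprintf("%s_%s_r%06d", sample_id, model$gene_id, seq_len(n_reads)),
    flag = 0L,
    rname = model$chromosome,
    pos = as.integer(model$start) + starts,  # model$start is 0-based half-open
    mapq = 60L,
    cigar = sprintf("%dM", rl),
    rnext = "*",
    pnext = 0L,
    tlen = 0L,
    seq = seqs,
    qual = qual_strings
  ) |>
    arrange(.data$pos)
}

# maternal-read fraction for one gene in one group under a config
gene_allelic_ratio <- function(imprinted, group, config) {
  if (imprinted && group %in% config$imprinted_monoallelic_in) {
    config$allelic_ratio_imprinted
  } else {
    config$allelic_ratio_biallelic
  }
}

#' Simulate a full allele-aware read-level dataset
#'
#' End-to-end generator for the allelic-expression pipeline: builds the gene
#' panel, a reference sequence per chromosome, and — per gene and per sample
#' — a parental haplotype pair and aligned reads. Every blastocyst is
#' treated as an independent mating: heterozygous sites are planted per
#' gene x sample on the shared reference backbone (the maternal allele
#' always matches the reference), so variant frequency at a planted site
#' estimates the paternal read fraction. The emitted truth table is for
#' validation only and is never consumed by the scoring modules.
#'
#' @param config A [sim_config()].
#' @return A list: `models` (gene panel tibble), `reference` (named
#'   character vector, one sequence per chromosome), `reads` (SAM-field
#'   tibble with a `sample_id` column), `truth_sites` (planted sites with
#'   transcript and genomic coordinates and the true maternal fraction),
#'   `meta` (sample sheet), `gene_read_counts` (`gene_id`, `sample_id`,
#'   `reads`).
#' @examples
#' cfg <- sim_config(n_imprinted_genes = 1, n_neighbour_genes = 2, n_loci = 1,
#'                   n_samples_per_group = 1, transcript_len_range = c(400, 600),
#'                   mean_coverage = 30)
#' sim <- simulate_allelic_reads(cfg)
#' dplyr::count(sim$reads, sample_id)
#' @export
simulate_allelic_reads <- function(config) {
  config <- validate_sim_config(config)
  models <- make_gene_models(config)
  meta <- sim_sample_meta(config$n_samples_per_group)
  withr::with_seed(config$seed + 1L, {
    gene_refs <- setNames(
      vapply(models$transcript_length_bp, random_sequence, character(1)),
      models$gene_id
    )
    reference <- build_chromosomes(models, gene_refs)
    reads_list <- list()
    truth_list <- list()
    for (g in seq_len(nrow(models))) {
      model <- models[g, ]
      for (s in seq_len(nrow(meta))) {
        ratio <- gene_allelic_ratio(model$imprinted, meta$group[s], config)
        planted <- plant_on_reference(gene_refs[[model$gene_id]],
                                      config$parental_snp_density)
        hp <- list(maternal = gene_refs[[model$gene_id]],
                   paternal = planted$paternal)
        reads_list[[length(reads_list) + 1L]] <-
          simulate_reads(hp, ratio, model, config,
                         sample_id = meta$sample_id[s], seed = NULL) |>
          mutate(sample_id = meta$sample_id[s], .before = 1)
        if (nrow(planted$sites) > 0L) {
          truth_list[[length(truth_list) + 1L]] <- planted$sites |>
            mutate(gene_id = model$gene_id,
                   sample_id = meta$sample_id[s],
                   chromosome = model$chromosome,
                   genomic_pos = as.integer(model$start) + .data$position,
                   true_allelic_ratio = ratio)
        }
      }
    }
  })
  reads <- bind_rows(reads_list)
  truth_sites <- if (length(truth_list)) bind_rows(truth_list) else
    tibble(position = integer(), ref = character(), alt = character(),
           gene_id = character(), sample_id = character(),
           chromosome = character(), genomic_pos = integer(),
           true_allelic_ratio = double())
  gene_read_counts <- reads |>
    left_join(select(models, "gene_id", "chromosome", "start", "end"),
              by = c(rname = "chromosome"),
              relationship = "many-to-many") |>
    filter(.data$pos > .data$start, .data$pos <= .data$end) |>
    dplyr::count(.data$gene_id, .data$sample_id, name = "reads")
  list(models = models, reference = reference, reads = reads,
       truth_sites = truth_sites, meta = meta,
       gene_read_counts = gene_read_counts)
}

# assemble one random sequence per chromosome with gene references spliced in
build_chromosomes <- function(models, gene_refs) {
  out <- list()
  for (chr in unique(models$chromosome)) {
    sub <- models[models$chromosome == chr, ]
    chr_len <- max(sub$end) + 1000L
    seq <- random_sequence(chr_len)
    for (i in seq_len(nrow(sub))) {
      substr(seq, sub$start[i] + 1L, sub$end[i]) <- gene_refs[[sub$gene_id[i]]]
    }
    out[[chr]] <- seq
  }
  unlist(out)
}

#' Simulate site-level allelic tallies without materialising reads
#'
#' Draws, for each gene x sample, the pileup tallies the read-level
#' simulator would induce at planted heterozygous sites: site depth is
#' Binomial over read placements (edge-truncated uniform starts), and the
#' alternate-allele count is Binomial(depth, f) with
#' `f = (1 - allelic_ratio) * (1 - e) + allelic_ratio * e / 3` for base
#' error rate `e` — the same distribution the read-level path induces.
#' Sites without a planted SNP are not materialised: with the default
#' caller thresholds a pure-error site cannot reach `min_reads2` supporting
#' reads at realistic depth. This is the fast path used for replicated
#' power and calibration studies; its agreement with the read-level path is
#' checked by a goodness-of-fit test.
#'
#' @param config A [sim_config()].
#' @return A list: `pileup` (long tallies with `gene_id`, `sample_id`,
#'   `chromosome`, `pos`, `ref_base`, `depth`, `base`, `count`,
#'   `mean_qual`), `truth_sites`, `meta`, `models`, `gene_read_counts`.
#' @examples
#' sim <- simulate_allelic_sites(sim_config(n_imprinted_genes = 2,
#'   n_neighbour_genes = 2, n_loci = 1, transcript_len_range = c(1000, 2000)))
#' head(sim$pileup)
#' @export
simulate_allelic_sites <- function(config) {
  config <- validate_sim_config(config)
  models <- make_gene_models(config)
  meta <- sim_sample_meta(config$n_samples_per_group)
  rl <- config$read_len
  e <- config$base_error_rate
  rows <- vector("list", nrow(models) * nrow(meta))
  k_row <- 0L
  withr::with_seed(config$seed + 2L, {
    for (g in seq_len(nrow(models))) {
      model <- models[g, ]
      len <- model$transcript_length_bp
      n_reads <- max(1L, as.integer(round(config$mean_coverage * len / rl)))
      for (s in seq_len(nrow(meta))) {
        ratio <- gene_allelic_ratio(model$imprinted, meta$group[s], config)
        k <- min(rpois(1L, config$parental_snp_density * len / 1000), len)
        if (k == 0L) next
        pos <- sort(sample.int(len, k))
        ref_b <- sample(.BASES, k, replace = TRUE)
        alt_b <- vapply(ref_b, function(b) sample(setdiff(.BASES, b), 1L),
                        character(1), USE.NAMES = FALSE)
        # depth: number of uniform read starts covering the site
        n_starts <- len - rl + 1L
        covering <- pmin(pos, n_starts) - pmax(1L, pos - rl + 1L) + 1L
        depth <- rbinom(k, n_reads, covering / n_starts)
        p_alt <- (1 - ratio) * (1 - e) + ratio * e / 3
        alt <- rbinom(k, depth, p_alt)
        mean_q <- vapply(alt, function(a) {
          if (a == 0L) return(NA_real_)
          mean(draw_phred(a, config$base_quality_mean))
        }, double(1))
        k_row <- k_row + 1L
        gpos <- rep(as.integer(model$start) + pos, 2L)
        tpos2 <- rep(pos, 2L)
        depth2 <- rep(depth, 2L)
        counts2 <- c(depth - alt, alt)
        quals2 <- c(rep(config$base_quality_mean, k), mean_q)
        rows[[k_row]] <- tibble(
          gene_id = model$gene_id,
          sample_id = meta$sample_id[s],
          chromosome = model$chromosome,
          pos = gpos,
          ref_base = rep(ref_b, 2L),
          depth = depth2,
          base = c(ref_b, alt_b),
          count = counts2,
          mean_qual = quals2,
          .transcript_pos = tpos2,
          .true_ratio = ratio
        )
      }
    }
  })
  pile <- bind_rows(rows[seq_len(k_row)])
  truth_sites <- pile |>
    filter(.data$base != .data$ref_base) |>
    select(gene_id = "gene_id", sample_id = "sample_id",
           chromosome = "chromosome", genomic_pos = "pos",
           position = ".transcript_pos", ref = "ref_base", alt = "base",
           true_allelic_ratio = ".true_ratio")
  pileup <- pile |>
    filter(.data$count > 0L) |>
    select(-".transcript_pos", -".true_ratio") |>
    arrange(.data$sample_id, .data$chromosome, .data$pos, .data$base)
  gene_read_counts <- tidyr::expand_grid(
    gene_id = models$gene_id, sample_id = meta$sample_id
  ) |>
    left_join(select(models, "gene_id", "transcript_length_bp"), by = "gene_id") |>
    mutate(reads = pmax(1L, as.integer(round(
      config$mean_coverage * .data$transcript_length_bp / rl)))) |>
    select(-"transcript_length_bp")
  list(pileup = pileup, truth_sites = truth_sites, meta = meta,
       models = models, gene_read_counts = gene_read_counts)
}
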