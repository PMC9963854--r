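#' Generate a synthetic gene panel grouped into imprinting loci
#'
#' Lays out `n_imprinted_genes + n_neighbour_genes` single-exon genes on
#' `n_loci` loci spread round-robin across `n_chromosomes` chromosomes,
#' emulating the topology of an imprinting-locus panel (each locus holds
#' imprinted genes surrounded by non-imprinted neighbours). Coordinates are
#' 0-based half-open (BED convention); because transcripts are single-exon,
#' `transcript_length_bp == end - start`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per gene: `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`, `transcript_length_bp`, `imprinted`, `locus_id`.
#' @examples
#' models <- make_gene_models(sim_config(n_imprinted_genes = 2, n_neighbour_genes = 4, n_loci = 2))
#' models
#' @export
make_gene_models <- function(config) {
  config <- validate_sim_config(config)
  n_genes <- config$n_imprinted_genes + config$n_neighbour_genes
  len_pool <- seq(config$transcript_len_range[1], config$transcript_len_range[2])
  withr::with_seed(config$seed, {
    # index into the pool: sample(x, ...) on a length-1 vector would
    # silently sample from 1:x
    lens <- len_pool[sample.int(length(len_pool), n_genes, replace = TRUE)]
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  })
  imprinted <- c(rep(TRUE, config$n_imprinted_genes),
                 rep(FALSE, config$n_neighbour_genes))
  # round-robin over loci so every locus gets imprinted genes first, then
  # neighbours interleaved around them
  locus_idx <- rep_len(seq_len(config$n_loci), n_genes)
  genes <- tibble(
    gene_id = sprintf("gene_%03d", seq_len(n_genes)),
    imprinted = imprinted,
    locus_id = sprintf("locus_%d", locus_idx),
    transcript_length_bp = as.integer(lens),
    strand = strands
  ) |>
    arrange(.data$locus_id, dplyr::desc(.data$imprinted), .data$gene_id)

  chrom_of_locus <- setNames(
    sprintf("chr%d", rep_len(seq_len(config$n_chromosomes), config$n_loci)),
    sprintf("locus_%d", seq_len(config$n_loci))
  )
  genes$chromosome <- unname(chrom_of_locus[genes$locus_id])

  # sequential layout per chromosome: 10 kb between loci, 500 bp between genes
  genes <- genes |>
    group_by(.data$chromosome) |>
    mutate(
      .locus_break = c(0L, as.integer(utils::head(.data$locus_id, -1) != .data$locus_id[-1])),
      .gap = 500L + 9500L * .data$.locus_break,
      start = cumsum(dplyr::lag(.data$transcript_length_bp, default = 0L) +
                       .data$.gap) - .data$.gap[1] + 1000L,
      end = .data$start + .data$transcript_length_bp
    ) |>
    ungroup() |>
    select("gene_id", "chromosome", "start", "end", "strand",
           "transcript_length_bp", "imprinted", "locus_id") |>
    arrange(.data$chromosome, .data$start)
  genes
}

.BASES <- c("A", "C", "G", "T")

random_sequence <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

#' Plant parental heterozygous sites into a transcript
#'
#' Draws a random reference transcript sequence and a parental haplotype
#' pair: the maternal haplotype equals the reference, the paternal
#' haplotype differs at `Poisson(density * length / 1000)` positions drawn
#' uniformly without replacement. Variant frequency observed downstream at
#' a planted site therefore estimates the paternal read fraction.
#'
#' @param model One-row gene-model tibble (or any list with
#'   `transcript_length_bp` and `gene_id`).
#' @param density Expected heterozygous sites per kb of transcript (>= 0).
#' @param seed Integer seed.
#' @return A list with `gene_id`, `reference`, `maternal`, `paternal`
#'   (character sequences) and `sites`, a tibble of planted positions
#'   (`position`, 1-based within the transcript; `ref`; `alt`).
#' @examples
#' m <- make_gene_models(sim_config(n_imprinted_genes = 0, n_neighbour_genes = 1))[1, ]
#' hp <- plant_parental_snps(m, density = 2, seed = 7)
#' hp$sites
#' @export
plant_parental_snps <- function(model, density, seed = 1L) {
  if (density < 0) abort("`density` must be >= 0.", class = "biallele_config_error")
  len <- as.integer(model$transcript_length_bp)
  stopifnot(len > 0L)
  withr::with_seed(as.integer(seed), {
    ref <- random_sequence(len)
    k <- min(rpois(1L, density * len / 1000), len)
    pos <- if (k > 0L) sort(sample.int(len, k)) else integer(0)
    ref_alleles <- if (k > 0L) substring(ref, pos, pos) else character(0)
    alt_alleles <- vapply(ref_alleles,
                          function(b) sample(setdiff(.BASES, b), 1L),
                          character(1), USE.NAMES = FALSE)
  })
  pat <- ref
  for (i in seq_along(pos)) {
    substr(pat, pos[i], pos[i]) <- alt_alleles[i]
  }
  list(
    gene_id = model$gene_id,
    reference = ref,
    maternal = ref,
    paternal = pat,
    sites = tibble(position = pos, ref = ref_alleles, alt = alt_alleles)
  )
}
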