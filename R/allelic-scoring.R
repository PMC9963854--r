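#' Bi-allelic evidence filter settings
#'
#' The filter chain applied to caller output before the SNP-per-kb
#' statistic: a site must have **more than** `min_site_depth` reads
#' (strict, i.e. depth >= 26 at the default) and a variant frequency
#' inside `[vf_low, vf_high]` percent (inclusive); a transcript must carry
#' at least `min_snps_per_transcript` such sites to be retained as showing
#' confident bi-allelic expression; and a gene enters the analysis only if
#' its read count summed over all samples reaches `min_gene_reads_total`
#' (inclusive, "5000 reads or more").
#'
#' @param min_site_depth Site depth threshold, exclusive (keep depth >
#'   this; default 25).
#' @param vf_low,vf_high Variant-frequency window in percent, inclusive
#'   (defaults 20 and 80).
#' @param min_snps_per_transcript Minimum confident SNPs for a transcript
#'   to be retained (default 3; a transcript with exactly 3 is kept).
#' @param min_gene_reads_total Minimum reads per gene summed over all
#'   samples, inclusive (default 5000).
#' @return A list of class `"allelic_filter"`.
#' @export
allelic_filter <- function(min_site_depth = 25, vf_low = 20, vf_high = 80,
                           min_snps_per_transcript = 3,
                           min_gene_reads_total = 5000) {
  if (vf_low < 0 || vf_high > 100 || vf_low >= vf_high) {
    abort("need 0 <= vf_low < vf_high <= 100.", class = "biallele_config_error")
  }
  if (min_site_depth < 0 || min_snps_per_transcript < 0 ||
      min_gene_reads_total < 0) {
    abort("filter counts must be >= 0.", class = "biallele_config_error")
  }
  structure(list(min_site_depth = min_site_depth, vf_low = vf_low,
                 vf_high = vf_high,
                 min_snps_per_transcript = as.integer(min_snps_per_transcript),
                 min_gene_reads_total = min_gene_reads_total),
            class = "allelic_filter")
}

#' Gate genes on total read depth across samples
#'
#' A gene is eligible for allelic scoring iff its reads summed over all
#' samples reach `min_gene_reads_total` ("5000 reads or more" at the
#' default) — genes below the gate cannot support reliable SNP
#' identification.
#'
#' @param gene_read_counts Tibble with `gene_id`, `sample_id`, `reads`.
#' @param filter An [allelic_filter()].
#' @return Tibble of eligible genes: `gene_id`, `total_reads`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "a", "b"),
#'                          sample_id = c("s1", "s2", "s1"),
#'                          reads = c(3000, 2000, 4999))
#' gate_gene_depth(counts, allelic_filter())
#' @export
gate_gene_depth <- function(gene_read_counts, filter = allelic_filter()) {
  stopifnot(inherits(filter, "allelic_filter"))
  if (nrow(gene_read_counts) == 0L) {
    return(tibble(gene_id = character(), total_reads = double()))
  }
  gene_read_counts |>
    group_by(.data$gene_id) |>
    summarise(total_reads = sum(.data$reads), .groups = "drop") |>
    filter(.data$total_reads >= filter$min_gene_reads_total)
}

#' Keep variant calls with bi-allelic evidence
#'
#' Site-level filter: depth strictly above `min_site_depth` and variant
#' frequency within the inclusive `[vf_low, vf_high]` percent window
#' (around 50% indicates both alleles of a heterozygous site are
#' transcribed; values near 0 or 100 indicate mono-allelic expression or
#' sequencing error).
#'
#' @param calls Variant-call tibble from [call_variants()].
#' @param filter An [allelic_filter()].
#' @return The filtered call tibble.
#' @export
filter_biallelic_snps <- function(calls, filter = allelic_filter()) {
  stopifnot(inherits(filter, "allelic_filter"))
  calls |>
    filter(.data$depth > filter$min_site_depth,
           .data$variant_frequency >= filter$vf_low,
           .data$variant_frequency <= filter$vf_high)
}

#' SNP frequency per kb of transcript
#'
#' The mono- vs bi-allelic expression indicator: confident SNP count
#' normalised by mature transcript length, `1000 * n / L`. Computed at
#' full precision; round only for display.
#'
#' @param n_snps Confident SNP count(s).
#' @param transcript_length_bp Transcript length(s), bp (> 0).
#' @return SNPs per kb (numeric, vectorised).
#' @examples
#' snp_frequency(3, 7560)    # 0.3968... -> displays as 0.40
#' snp_frequency(27, 29281)  # 0.9221... -> displays as 0.92
#' @export
snp_frequency <- function(n_snps, transcript_length_bp) {
  if (any(transcript_length_bp <= 0)) {
    abort("`transcript_length_bp` must be > 0.", class = "biallele_input_error")
  }
  1000 * n_snps / transcript_length_bp
}

# attach gene ids to calls by genomic position when absent
assign_calls_to_genes <- function(calls, models) {
  if ("gene_id" %in% names(calls)) return(calls)
  calls |>
    inner_join(select(models, "gene_id", "chromosome", "start", "end"),
               by = join_by(chromosome, between(pos, start, end,
                                                bounds = "(]"))) |>
    select(-"start", -"end")
}

#' Summarise confident SNPs per transcript and sample
#'
#' Counts confident (site-filtered) SNPs per gene x sample, computes the
#' SNP-per-kb statistic and the unweighted mean variant frequency over the
#' transcript's confident SNPs, and flags retention: a transcript is
#' retained iff it carries at least `min_snps_per_transcript` confident
#' SNPs (fewer may reflect PCR or sequencing artefacts rather than
#' bi-allelic expression). Every gene x sample combination in
#' `models` x `sample_ids` is reported, including zero-SNP ones.
#'
#' @param confident_snps Filtered call tibble (see
#'   [filter_biallelic_snps()]); a `gene_id` column is used if present,
#'   otherwise calls are assigned to genes by genomic position.
#' @param models Gene-model tibble (`gene_id`, `transcript_length_bp`,
#'   optionally `imprinted`, `locus_id`, coordinates).
#' @param sample_ids Character vector of samples to report.
#' @param filter An [allelic_filter()].
#' @return A tibble: `gene_id`, `sample_id`, `n_confident_snps`,
#'   `transcript_length_bp`, `snp_per_kb`, `mean_variant_frequency`,
#'   `retained`, plus `imprinted` and `locus_id` when available.
#' @export
summarize_transcripts <- function(confident_snps, models, sample_ids,
                                  filter = allelic_filter()) {
  stopifnot(inherits(filter, "allelic_filter"))
  if (any(models$transcript_length_bp <= 0)) {
    abort("transcript lengths must be > 0.", class = "biallele_input_error")
  }
  snps <- assign_calls_to_genes(confident_snps, models)
  per <- snps |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(n_confident_snps = dplyr::n(),
              mean_variant_frequency = mean(.data$variant_frequency),
              .groups = "drop")
  extra <- intersect(c("imprinted", "locus_id"), names(models))
  grid <- tidyr::expand_grid(gene_id = models$gene_id, sample_id = sample_ids)
  grid |>
    left_join(per, by = c("gene_id", "sample_id")) |>
    mutate(n_confident_snps = if_else(is.na(.data$n_confident_snps), 0L,
                                      as.integer(.data$n_confident_snps))) |>
    left_join(select(models, "gene_id", "transcript_length_bp",
                     dplyr::all_of(extra)), by = "gene_id") |>
    mutate(
      snp_per_kb = snp_frequency(.data$n_confident_snps,
                                 .data$transcript_length_bp),
      retained = .data$n_confident_snps >= filter$min_snps_per_transcript
    ) |>
    select("gene_id", "sample_id", "n_confident_snps",
           "transcript_length_bp", "snp_per_kb", "mean_variant_frequency",
           "retained", dplyr::all_of(extra))
}

#' Aggregate SNP frequency over locus members
#'
#' Per locus x sample x class (imprinted vs non-imprinted), sums confident
#' SNP counts and transcript lengths over member transcripts and
#' recomputes SNP/kb from the totals. By default every analysed member
#' contributes its transcript length, while transcripts that failed the
#' retention rule contribute zero SNPs (their candidate SNPs were
#' discarded as possible artefacts) — this is the accounting that yields
#' the published locus totals, where a locus' summed transcript length
#' spans all its analysed neighbours. With `members = "retained"` both
#' sums run over retained transcripts only and cells without a retained
#' member are omitted.
#'
#' @param summaries Output of [summarize_transcripts()].
#' @param models Gene-model tibble with `gene_id`, `locus_id`, `imprinted`.
#' @param members `"analysed"` (default) or `"retained"`; see above.
#' @return A tibble: `locus_id`, `sample_id`, `class`, `total_snps`,
#'   `total_length_bp`, `snp_per_kb`.
#' @export
aggregate_locus <- function(summaries, models,
                            members = c("analysed", "retained")) {
  members <- match.arg(members)
  s <- summaries
  if (!all(c("imprinted", "locus_id") %in% names(s))) {
    s <- s |>
      left_join(select(models, "gene_id", "imprinted", "locus_id"),
                by = "gene_id")
  }
  if (members == "retained") {
    s <- filter(s, .data$retained)
  } else {
    s <- mutate(s, n_confident_snps = if_else(.data$retained,
                                              .data$n_confident_snps, 0L))
  }
  s |>
    mutate(class = if_else(.data$imprinted, "imprinted", "non-imprinted")) |>
    group_by(.data$locus_id, .data$sample_id, .data$class) |>
    summarise(total_snps = sum(.data$n_confident_snps),
              total_length_bp = sum(.data$transcript_length_bp),
              .groups = "drop") |>
    mutate(snp_per_kb = snp_frequency(.data$total_snps,
                                      .data$total_length_bp))
}

#' Run the full allelic-scoring filter chain
#'
#' Convenience pipeline: depth-gate genes, site-filter calls, summarise
#' transcripts. The depth gate applies to imprinted and neighbour genes
#' alike by default (symmetric treatment avoids a class-specific depth
#' bias); set `gate_imprinted_only = TRUE` to gate only imprinted genes.
#'
#' @param calls Variant-call tibble from [call_variants()].
#' @param models Gene-model tibble.
#' @param gene_read_counts Tibble `gene_id`, `sample_id`, `reads`.
#' @param sample_ids Samples to report; defaults to those present in
#'   `gene_read_counts`.
#' @param filter An [allelic_filter()].
#' @param gate_imprinted_only Apply the read gate only to imprinted genes.
#' @return Per-transcript summary tibble (see [summarize_transcripts()]).
#' @export
score_allelic_expression <- function(calls, models, gene_read_counts,
                                     sample_ids = NULL,
                                     filter = allelic_filter(),
                                     gate_imprinted_only = FALSE) {
  if (is.null(sample_ids)) {
    sample_ids <- sort(unique(gene_read_counts$sample_id))
  }
  eligible <- gate_gene_depth(gene_read_counts, filter)$gene_id
  if (gate_imprinted_only) {
    eligible <- union(eligible, models$gene_id[!models$imprinted])
  }
  kept_models <- filter(models, .data$gene_id %in% eligible)
  confident <- filter_biallelic_snps(calls, filter)
  summarize_transcripts(confident, kept_models, sample_ids, filter)
}
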