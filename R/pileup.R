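#' Variant-caller thresholds
#'
#' Defaults reproduce the VarScan settings used for genotype-free
#' allele-specific expression screening: minimum mean Phred quality of the
#' alternate-supporting bases 20, minimum variant frequency 1% (a
#' fraction), and at least 10 alternate-supporting reads. All comparisons
#' are inclusive (`>=`), matching VarScan semantics.
#'
#' @param min_avg_qual Minimum mean Phred quality of alt-supporting bases.
#' @param min_var_freq Minimum alt fraction of site depth, in `[0, 1]`.
#' @param min_reads2 Minimum alternate-supporting read count.
#' @param min_base_qual_for_tally Phred floor a base must meet to be
#'   tallied in the pileup at all (0 = count every base; quality then only
#'   enters through `min_avg_qual`).
#' @return A list of class `"caller_thresholds"`.
#' @export
caller_thresholds <- function(min_avg_qual = 20, min_var_freq = 0.01,
                              min_reads2 = 10, min_base_qual_for_tally = 0) {
  if (min_avg_qual < 0 || min_reads2 < 0 || min_base_qual_for_tally < 0) {
    abort("caller thresholds must be >= 0.", class = "biallele_config_error")
  }
  if (min_var_freq < 0 || min_var_freq > 1) {
    abort("`min_var_freq` must lie in [0, 1].", class = "biallele_config_error")
  }
  structure(list(min_avg_qual = min_avg_qual, min_var_freq = min_var_freq,
                 min_reads2 = as.integer(min_reads2),
                 min_base_qual_for_tally = min_base_qual_for_tally),
            class = "caller_thresholds")
}

SKIP_FLAGS <- bitwOr(bitwOr(0x4L, 0x100L), 0x800L)  # unmapped/secondary/suppl.

cigar_is_valid <- function(cigar) {
  grepl("^([0-9]+[MIDNSHP=X])+$", cigar) | cigar == "*"
}

# expand one read's CIGAR into (reference position, query index) pairs for
# aligned bases; insertions/soft clips consume query only, deletions and
# skips reference only
expand_cigar <- function(pos, cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  rpos <- pos
  qpos <- 1L
  ref_out <- integer(0)
  q_out <- integer(0)
  for (i in seq_along(ops)) {
    l <- lens[i]
    op <- ops[i]
    if (op %in% c("M", "=", "X")) {
      ref_out <- c(ref_out, rpos:(rpos + l - 1L))
      q_out <- c(q_out, qpos:(qpos + l - 1L))
      rpos <- rpos + l
      qpos <- qpos + l
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + l
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + l
    }
    # H and P consume neither
  }
  list(ref = ref_out, query = q_out)
}

#' Pile up aligned reads over a gene region
#'
#' Tallies, per 1-based reference position inside the region, how many
#' reads support each base and at what quality. Bases are assigned to
#' reference positions through the read CIGAR (insertions and soft clips
#' consume query only; deletions and reference skips consume reference
#' only — reads with indels contribute their aligned matches).
#' Unmapped, secondary and supplementary records are skipped; records with
#' a malformed CIGAR raise a warning and are dropped.
#'
#' @param reads Tibble of SAM fields (see [read_alignments()]), or a path
#'   to a SAM/BAM file.
#' @param region One-row gene-model tibble: `chromosome` plus 0-based
#'   half-open `start`/`end` (BED convention; converted internally via
#'   [bed_to_pileup()]).
#' @param reference Named character vector (or `Biostrings::DNAStringSet`)
#'   of reference chromosome sequences.
#' @param min_base_quality Phred floor for a base to be tallied (default 0,
#'   i.e. every base counts).
#' @return A tibble with one row per (position, base) observed: columns
#'   `chromosome`, `pos` (1-based), `ref_base`, `depth` (total bases
#'   tallied at the position), `base`, `count`, `mean_qual`; sorted by
#'   position. Empty regions give a zero-row tibble.
#' @examples
#' cfg <- sim_config(n_imprinted_genes = 0, n_neighbour_genes = 1,
#'                   transcript_len_range = c(300, 300), mean_coverage = 20)
#' sim <- simulate_allelic_reads(cfg)
#' p <- pileup(sim$reads, sim$models[1, ], sim$reference)
#' head(p)
#' @export
pileup <- function(reads, region, reference, min_base_quality = 0) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_alignments(reads)
  }
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  chrom <- region$chromosome[1]
  if (!chrom %in% names(reference)) {
    abort(sprintf("chromosome '%s' absent from the reference header.", chrom),
          class = "biallele_input_error")
  }
  span <- bed_to_pileup(region$start[1], region$end[1])
  empty <- tibble(chromosome = character(), pos = integer(),
                  ref_base = character(), depth = integer(),
                  base = character(), count = integer(),
                  mean_qual = double())
  reads <- reads |>
    filter(.data$rname == chrom,
           bitwAnd(.data$flag, SKIP_FLAGS) == 0L)
  if (nrow(reads) == 0L) return(empty)
  bad <- !cigar_is_valid(reads$cigar)
  if (any(bad)) {
    warn(sprintf("skipping %d record(s) with malformed CIGAR.", sum(bad)))
    reads <- reads[!bad, ]
  }
  reads <- reads[reads$cigar != "*", ]
  # drop reads that cannot overlap the region (cheap bound: aligned span
  # never exceeds cigar length sum)
  if (nrow(reads) == 0L) return(empty)

  simple <- grepl("^[0-9]+M$", reads$cigar)
  pos_vec <- integer(0); base_vec <- character(0); qual_vec <- integer(0)

  if (any(simple)) {
    rs <- reads[simple, ]
    lens <- nchar(rs$seq)
    offs <- sequence(lens) - 1L
    pos_vec <- rep(rs$pos, lens) + offs
    base_vec <- unlist(strsplit(rs$seq, "", fixed = TRUE), use.names = FALSE)
    qual_vec <- unlist(lapply(rs$qual, utf8ToInt), use.names = FALSE) - 33L
  }
  if (any(!simple)) {
    for (i in which(!simple)) {
      al <- expand_cigar(reads$pos[i], reads$cigar[i])
      if (length(al$ref) == 0L) next
      sbases <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
      squals <- utf8ToInt(reads$qual[i]) - 33L
      pos_vec <- c(pos_vec, al$ref)
      base_vec <- c(base_vec, sbases[al$query])
      qual_vec <- c(qual_vec, squals[al$query])
    }
  }
  keep <- pos_vec >= span$first & pos_vec <= span$last &
    qual_vec >= min_base_quality
  if (!any(keep)) return(empty)
  df <- tibble(pos = pos_vec[keep], base = toupper(base_vec[keep]),
               qual = qual_vec[keep]) |>
    group_by(.data$pos, .data$base) |>
    summarise(count = dplyr::n(), mean_qual = mean(.data$qual),
              .groups = "drop") |>
    group_by(.data$pos) |>
    mutate(depth = as.integer(sum(.data$count))) |>
    ungroup()
  chrom_seq <- reference[[chrom]]
  df |>
    mutate(chromosome = chrom,
           ref_base = toupper(substring(chrom_seq, .data$pos, .data$pos)),
           count = as.integer(.data$count)) |>
    select("chromosome", "pos", "ref_base", "depth", "base", "count",
           "mean_qual") |>
    arrange(.data$pos, .data$base)
}

#' Call candidate variants from pileup tallies
#'
#' At each site the single most frequent non-reference base is evaluated
#' (ties broken by fixed base order A < C < G < T; sites are treated as
#' bi-allelic SNPs, indels are never called). A call is emitted iff the
#' alternate read count is at least `min_reads2`, the alternate fraction of
#' depth is at least `min_var_freq`, and the mean Phred quality of the
#' alternate-supporting bases is at least `min_avg_qual` — all inclusive.
#' Zero-depth sites are skipped silently. Variant frequency is reported in
#' percent at full precision.
#'
#' Grouping columns `sample_id` and/or `gene_id`, if present in `sites`,
#' are preserved and calls are made within each group.
#'
#' @param sites Pileup tibble from [pileup()] (or the site-level
#'   simulator).
#' @param thresholds A [caller_thresholds()].
#' @return A tibble of calls: any grouping columns, then `chromosome`,
#'   `pos`, `ref_base`, `alt_base`, `depth`, `alt_reads`,
#'   `variant_frequency` (percent), `mean_alt_quality`.
#' @export
call_variants <- function(sites, thresholds = caller_thresholds()) {
  stopifnot(inherits(thresholds, "caller_thresholds"))
  gcols <- intersect(c("sample_id", "gene_id"), names(sites))
  keys <- c(gcols, "chromosome", "pos")
  base_rank <- match(sites$base, .BASES)
  cand <- sites |>
    mutate(.base_rank = base_rank) |>
    filter(.data$depth > 0L,
           .data$base != .data$ref_base,
           !is.na(.data$.base_rank),
           .data$count > 0L) |>
    arrange(dplyr::desc(.data$count), .data$.base_rank) |>
    distinct(across(dplyr::all_of(keys)), .keep_all = TRUE)
  cand |>
    filter(.data$count >= thresholds$min_reads2,
           .data$count / .data$depth >= thresholds$min_var_freq,
           .data$mean_qual >= thresholds$min_avg_qual) |>
    mutate(variant_frequency = 100 * .data$count / .data$depth) |>
    select(dplyr::all_of(gcols), "chromosome", "pos", "ref_base",
           alt_base = "base", "depth", alt_reads = "count",
           "variant_frequency", mean_alt_quality = "mean_qual") |>
    arrange(across(dplyr::all_of(keys)))
}
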