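#' Configuration for the allelic-expression read simulator
#'
#' Bundles every tunable of the synthetic diploid-transcriptome generator:
#' study design (two treatment groups of blastocysts), gene panel (imprinted
#' genes plus non-imprinted neighbours grouped into loci), parental
#' heterozygosity, allelic expression ratios, sequencing depth and per-base
#' error model.
#'
#' Defaults mirror the study design the package targets: 5 blastocysts per
#' group (`MT-` = no mitochondrial supplementation, `MT+` = supplemented),
#' 10 imprinted genes and 73 non-imprinted neighbours over 6 imprinting
#' loci on 4 chromosomes, and a parental SNP density of 1 het site per kb
#' of transcript (the human genome averages roughly one SNP per 300 bp;
#' transcripts observed in this kind of screen run 0.3-2 SNP/kb).
#'
#' @param n_samples_per_group Blastocysts per treatment group (> 0).
#' @param n_imprinted_genes Number of imprinted genes in the panel (>= 0).
#' @param n_neighbour_genes Number of non-imprinted neighbour genes (>= 0;
#'   the panel must contain at least one gene).
#' @param n_loci Number of imprinting loci the panel is grouped into.
#' @param n_chromosomes Chromosomes the loci are spread across.
#' @param transcript_len_range Length-2 integer vector, bp; mature transcript
#'   lengths are drawn uniformly from this closed range. Synthetic
#'   transcripts are single-exon, so genomic span equals transcript length.
#' @param parental_snp_density Expected heterozygous sites between the two
#'   parental haplotypes, per kb of transcript (>= 0).
#' @param allelic_ratio_imprinted Fraction of a mono-allelic (imprinted)
#'   gene's reads drawn from the maternal haplotype; 1 or 0 means fully
#'   mono-allelic.
#' @param allelic_ratio_biallelic Maternal read fraction for bi-allelically
#'   expressed genes (0.5 = balanced).
#' @param imprinted_monoallelic_in Character subset of `c("MT-", "MT+")`:
#'   the groups in which imprinted genes are expressed mono-allelically.
#'   Groups not listed express all genes bi-allelically.
#' @param mean_coverage Mean per-base read depth per transcript.
#' @param read_len Read length, bp.
#' @param base_error_rate Per-base sequencing error probability, in
#'   `[0, 0.1]`.
#' @param base_quality_mean Mean Phred base quality; qualities are drawn
#'   Normal(mean, 3) and truncated to `[2, 41]`.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_imprinted_genes = 2, n_neighbour_genes = 6, n_loci = 2)
#' cfg$parental_snp_density
#' @export
sim_config <- function(n_samples_per_group = 5,
                       n_imprinted_genes = 10,
                       n_neighbour_genes = 73,
                       n_loci = 6,
                       n_chromosomes = 4,
                       transcript_len_range = c(1000L, 10000L),
                       parental_snp_density = 1,
                       allelic_ratio_imprinted = 1,
                       allelic_ratio_biallelic = 0.5,
                       imprinted_monoallelic_in = c("MT-", "MT+"),
                       mean_coverage = 200,
                       read_len = 100L,
                       base_error_rate = 0.005,
                       base_quality_mean = 35,
                       seed = 1L) {
  cfg <- list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_imprinted_genes = as.integer(n_imprinted_genes),
    n_neighbour_genes = as.integer(n_neighbour_genes),
    n_loci = as.integer(n_loci),
    n_chromosomes = as.integer(n_chromosomes),
    transcript_len_range = as.integer(round(transcript_len_range)),
    parental_snp_density = parental_snp_density,
    allelic_ratio_imprinted = allelic_ratio_imprinted,
    allelic_ratio_biallelic = allelic_ratio_biallelic,
    imprinted_monoallelic_in = imprinted_monoallelic_in,
    mean_coverage = mean_coverage,
    read_len = as.integer(read_len),
    base_error_rate = base_error_rate,
    base_quality_mean = base_quality_mean,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples_per_group < 1L) {
    abort("`n_samples_per_group` must be a positive count.", class = "biallele_config_error")
  }
  if (cfg$n_imprinted_genes < 0L || cfg$n_neighbour_genes < 0L ||
      cfg$n_imprinted_genes + cfg$n_neighbour_genes < 1L) {
    abort("gene counts must be non-negative and the panel non-empty.", class = "biallele_config_error")
  }
  if (cfg$n_loci < 1L || cfg$n_chromosomes < 1L) {
    abort("`n_loci` and `n_chromosomes` must be positive counts.", class = "biallele_config_error")
  }
  if (length(cfg$transcript_len_range) != 2L ||
      any(cfg$transcript_len_range < 1L) ||
      cfg$transcript_len_range[1] > cfg$transcript_len_range[2]) {
    abort("`transcript_len_range` must be an increasing pair of positive lengths.", class = "biallele_config_error")
  }
  if (cfg$parental_snp_density < 0) {
    abort("`parental_snp_density` must be >= 0.", class = "biallele_config_error")
  }
  for (r in c(cfg$allelic_ratio_imprinted, cfg$allelic_ratio_biallelic)) {
    if (r < 0 || r > 1) {
      abort("allelic ratios must lie in [0, 1].", class = "biallele_config_error")
    }
  }
  if (!all(cfg$imprinted_monoallelic_in %in% c("MT-", "MT+"))) {
    abort("`imprinted_monoallelic_in` must be a subset of c(\"MT-\", \"MT+\").", class = "biallele_config_error")
  }
  if (cfg$mean_coverage <= 0) {
    abort("`mean_coverage` must be > 0.", class = "biallele_config_error")
  }
  if (cfg$read_len < 1L) {
    abort("`read_len` must be a positive count.", class = "biallele_config_error")
  }
  if (cfg$base_error_rate < 0 || cfg$base_error_rate > 0.1) {
    abort("`base_error_rate` must lie in [0, 0.1].", class = "biallele_config_error")
  }
  if (cfg$read_len > cfg$transcript_len_range[1]) {
    abort("`read_len` exceeds the shortest transcript length.", class = "biallele_config_error")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  samples: %d per group (MT-/MT+)\n", x$n_samples_per_group))
  cat(sprintf("  genes: %d imprinted + %d neighbours over %d loci / %d chromosomes\n",
              x$n_imprinted_genes, x$n_neighbour_genes, x$n_loci, x$n_chromosomes))
  cat(sprintf("  transcripts: %d-%d bp, %.2f parental SNP/kb\n",
              x$transcript_len_range[1], x$transcript_len_range[2],
              x$parental_snp_density))
  cat(sprintf("  reads: %dx coverage, %d bp, error %.4f, Q%.0f, seed %d\n",
              round(x$mean_coverage), x$read_len, x$base_error_rate,
              x$base_quality_mean, x$seed))
  invisible(x)
}

#' Sample metadata for a simulated two-group blastocyst study
#'
#' Builds the sample sheet the simulators and the group-comparison module
#' share: `n` blastocysts per treatment group with balanced sex and two
#' balanced two-level batch factors (date of sampling, date of library
#' construction). The assignment pattern is deterministic so that the
#' factorial design is never aliased.
#'
#' @param n_samples_per_group Blastocysts per group.
#' @return A tibble with columns `sample_id`, `group`, `sex`,
#'   `sampling_date`, `library_date`.
#' @examples
#' sim_sample_meta(5)
#' @export
sim_sample_meta <- function(n_samples_per_group = 5) {
  n <- as.integer(n_samples_per_group)
  per_group <- function(group, offset) {
    i <- seq_len(n)
    tibble(
      sample_id = sprintf("%s_%02d", sub("MT\\+", "MTplus", sub("MT-", "MTminus", group)), i),
      group = group,
      sex = ifelse((i + offset) %% 2L == 0L, "F", "M"),
      sampling_date = ifelse(((i + offset) %/% 2L) %% 2L == 0L, "sd1", "sd2"),
      library_date = ifelse(((i + offset + 1L) %/% 2L) %% 2L == 0L, "ld1", "ld2")
    )
  }
  bind_rows(per_group("MT-", 0L), per_group("MT+", 1L))
}
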