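#' CPM-based expression filter
#'
#' Keeps a gene iff it reaches `min_cpm` counts per million in **more
#' than** `min_samples` samples (strict, e.g. "more than eight samples"
#' keeps a gene seen in 9+). CPM uses raw library sizes; normalisation is
#' upstream territory.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param min_cpm CPM a sample must reach to count (inclusive; default 1).
#' @param min_samples Gene kept iff strictly more than this many samples
#'   reach `min_cpm`.
#' @return Character vector of retained gene ids, in input order.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), s1 = c(100, 0),
#'                          s2 = c(80, 0), s3 = c(120, 5))
#' cpm_filter(counts, min_cpm = 1, min_samples = 2)
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples) {
  cpms <- cpm(counts)  # validates non-empty matrix and library sizes
  num <- setdiff(names(cpms), "gene_id")
  mat <- as.matrix(cpms[num])
  n_ok <- rowSums(mat >= min_cpm)
  counts$gene_id[n_ok > min_samples]
}

#' Threshold a DEG table on FDR
#'
#' @param table DEG tibble with `gene_id` and `fdr` columns (`FDR` is
#'   accepted); gene ids must be unique, FDR in `[0, 1]`.
#' @param fdr_cut Strict cut: genes with `fdr < fdr_cut` are significant.
#' @return Character vector of significant gene ids.
#' @export
threshold_degs <- function(table, fdr_cut = 0.1) {
  table <- normalise_deg_table(table)
  table$gene_id[table$fdr < fdr_cut]
}

normalise_deg_table <- function(table) {
  nm <- names(table)
  names(table)[match(c("FDR", "logFC", "logCPM"), nm, nomatch = 0)] <-
    c("fdr", "log_fc", "log_cpm")[c("FDR", "logFC", "logCPM") %in% nm]
  if (!all(c("gene_id", "fdr") %in% names(table))) {
    abort("a DEG table needs `gene_id` and `fdr`/`FDR` columns.",
          class = "biallele_input_error")
  }
  if (anyDuplicated(table$gene_id)) {
    abort("gene ids must be unique within a DEG table.",
          class = "biallele_input_error")
  }
  if (any(table$fdr < 0 | table$fdr > 1, na.rm = TRUE)) {
    abort("FDR values must lie in [0, 1].", class = "biallele_input_error")
  }
  table
}

#' Compare two transition DEG sets
#'
#' The longitudinal set algebra: given DEG tables for two developmental
#' transitions (A and B, e.g. oocyte to non-supplemented blastocyst and
#' oocyte to supplemented blastocyst), genes significant at `fdr_cut` in
#' both are `common`; genes significant in exactly one are unique to that
#' transition. "Unique to A" means significant in A and **not significant
#' in B at the same cut** — a gene filtered out of B's table before
#' fitting counts as not significant there and is flagged
#' (`in_table_a`/`in_table_b`). Unique genes with `fdr < high_conf_cut` in
#' their own table form the high-confidence subsets.
#'
#' @param degs_a,degs_b DEG tibbles (`gene_id`, `log_fc`/`logFC`,
#'   `log_cpm`/`logCPM`, `fdr`/`FDR`).
#' @param fdr_cut Significance cut (strict; default 0.1).
#' @param high_conf_cut High-confidence cut within unique sets (strict;
#'   default 0.01).
#' @return An object of class `"transition_comparison"`: list with
#'   `common`, `unique_a`, `unique_b`, `high_conf_unique_a`,
#'   `high_conf_unique_b` (character vectors), `membership` (tibble with
#'   one row per gene in the union: `gene_id`, `membership`, `fdr_a`,
#'   `fdr_b`, `high_confidence`, `in_table_a`, `in_table_b`) and the cuts.
#' @export
compare_transitions <- function(degs_a, degs_b, fdr_cut = 0.1,
                                high_conf_cut = 0.01) {
  degs_a <- normalise_deg_table(degs_a)
  degs_b <- normalise_deg_table(degs_b)
  sig_a <- degs_a$gene_id[degs_a$fdr < fdr_cut]
  sig_b <- degs_b$gene_id[degs_b$fdr < fdr_cut]
  common <- intersect(sig_a, sig_b)
  unique_a <- setdiff(sig_a, sig_b)
  unique_b <- setdiff(sig_b, sig_a)
  fdr_a <- setNames(degs_a$fdr, degs_a$gene_id)
  fdr_b <- setNames(degs_b$fdr, degs_b$gene_id)
  high_a <- unique_a[fdr_a[unique_a] < high_conf_cut]
  high_b <- unique_b[fdr_b[unique_b] < high_conf_cut]
  all_genes <- union(sig_a, sig_b)
  membership <- tibble(
    gene_id = all_genes,
    membership = dplyr::case_when(
      all_genes %in% common ~ "common",
      all_genes %in% unique_a ~ "unique_a",
      TRUE ~ "unique_b"
    ),
    fdr_a = unname(fdr_a[all_genes]),
    fdr_b = unname(fdr_b[all_genes]),
    high_confidence = all_genes %in% c(high_a, high_b),
    in_table_a = all_genes %in% degs_a$gene_id,
    in_table_b = all_genes %in% degs_b$gene_id
  )
  structure(list(common = common, unique_a = unique_a, unique_b = unique_b,
                 high_conf_unique_a = high_a, high_conf_unique_b = high_b,
                 membership = membership, fdr_cut = fdr_cut,
                 high_conf_cut = high_conf_cut),
            class = "transition_comparison")
}

#' Set sizes of a transition comparison
#'
#' @param cmp A [compare_transitions()] result.
#' @return A tibble with one row: `common`, `unique_a`, `unique_b`,
#'   `high_conf_unique_a`, `high_conf_unique_b` — the numbers a two-set
#'   Venn diagram displays.
#' @export
venn_counts <- function(cmp) {
  stopifnot(inherits(cmp, "transition_comparison"))
  tibble(common = length(cmp$common),
         unique_a = length(cmp$unique_a),
         unique_b = length(cmp$unique_b),
         high_conf_unique_a = length(cmp$high_conf_unique_a),
         high_conf_unique_b = length(cmp$high_conf_unique_b))
}

#' @export
print.transition_comparison <- function(x, ...) {
  v <- venn_counts(x)
  cat(sprintf(
    "Transition DEG comparison (FDR < %s, high-confidence FDR < %s)\n",
    format(x$fdr_cut), format(x$high_conf_cut)))
  cat(sprintf("  common: %d\n  unique to A: %d (high-confidence %d)\n  unique to B: %d (high-confidence %d)\n",
              v$common, v$unique_a, v$high_conf_unique_a,
              v$unique_b, v$high_conf_unique_b))
  invisible(x)
}

#' @rdname compare_transitions
#' @param x A `transition_comparison` object.
#' @param ... Unused.
#' @export
tidy.transition_comparison <- function(x, ...) x$membership

#' @rdname compare_transitions
#' @export
glance.transition_comparison <- function(x, ...) {
  dplyr::bind_cols(venn_counts(x),
                   tibble(fdr_cut = x$fdr_cut,
                          high_conf_cut = x$high_conf_cut))
}

#' @rdname compare_transitions
#' @param object A `transition_comparison` object.
#' @export
autoplot.transition_comparison <- function(object, ...) {
  v <- venn_counts(object)
  dat <- tibble(
    set = factor(c("unique to A", "common", "unique to B"),
                 levels = c("unique to A", "common", "unique to B")),
    n = c(v$unique_a, v$common, v$unique_b),
    high_conf = c(v$high_conf_unique_a, NA, v$high_conf_unique_b)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$set, y = .data$n)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$high_conf), .data$n,
                     sprintf("%d (%d high-conf.)", .data$n, .data$high_conf))),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "DEGs") +
    ggplot2::theme_bw()
}
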