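#' Simulate a count matrix with truth-labelled transition DEG tables
#'
#' Generates a negative-binomial count matrix for a longitudinal design —
#' oocytes plus two blastocyst groups (`MT-`, `MT+`) — with genes planted
#' as `"common"` (differentially expressed in both oocyte-to-blastocyst
#' transitions), `"unique_a"` (transition to `MT-` only), `"unique_b"`
#' (transition to `MT+` only) or `"null"`. Two DEG tables (one per
#' transition) are derived from the counts by per-gene equal-variance
#' t-tests on `log2(CPM + 0.5)` with Benjamini-Hochberg adjustment, and
#' X/Y-linked sex-marker genes are appended so sex can be called from the
#' counts (male blastocysts express the Y markers, females do not; marker
#' genes are kept out of the DEG tables).
#'
#' @param n_genes Genes in the matrix (markers excluded).
#' @param n_oocytes,n_per_blastocyst_group Samples per stage/group.
#' @param prop_common,prop_unique_a,prop_unique_b Fractions of genes
#'   planted in each effect class (the rest are null).
#' @param log_fc Absolute planted log2 fold change for affected
#'   transitions (sign drawn per gene).
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param baseline_mean Mean of the per-gene log-normal baseline
#'   expression.
#' @param n_x_markers,n_y_markers Number of X-/Y-linked marker genes.
#' @param marker_cpm Expected marker expression, CPM, where present.
#' @param seed Integer seed.
#' @return A list: `counts` (wide tibble, markers included), `deg_a`,
#'   `deg_b` (tibbles `gene_id`, `log_fc`, `log_cpm`, `fdr`), `truth`
#'   (`gene_id`, `class`, `lfc_a`, `lfc_b`), `meta` (`sample_id`, `stage`,
#'   `group`, `sex`), `x_genes`, `y_genes`.
#' @examples
#' sim <- simulate_counts_and_degs(n_genes = 200, seed = 42)
#' head(sim$deg_a)
#' @export
simulate_counts_and_degs <- function(n_genes = 2000,
                                     n_oocytes = 5,
                                     n_per_blastocyst_group = 5,
                                     prop_common = 0.10,
                                     prop_unique_a = 0.05,
                                     prop_unique_b = 0.05,
                                     log_fc = 2,
                                     dispersion = 0.05,
                                     baseline_mean = 100,
                                     n_x_markers = 4,
                                     n_y_markers = 4,
                                     marker_cpm = 50,
                                     seed = 1L) {
  stopifnot(n_genes > 0, prop_common + prop_unique_a + prop_unique_b <= 1)
  n_o <- as.integer(n_oocytes)
  n_b <- as.integer(n_per_blastocyst_group)
  meta <- tibble(
    sample_id = c(sprintf("oocyte_%02d", seq_len(n_o)),
                  sprintf("MTminus_%02d", seq_len(n_b)),
                  sprintf("MTplus_%02d", seq_len(n_b))),
    stage = c(rep("oocyte", n_o), rep("blastocyst", 2L * n_b)),
    group = c(rep(NA_character_, n_o), rep("MT-", n_b), rep("MT+", n_b)),
    sex = c(rep("F", n_o),
            rep_len(c("M", "F"), n_b), rep_len(c("F", "M"), n_b))
  )
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  n_common <- round(prop_common * n_genes)
  n_ua <- round(prop_unique_a * n_genes)
  n_ub <- round(prop_unique_b * n_genes)
  withr::with_seed(as.integer(seed), {
    class_vec <- sample(c(rep("common", n_common), rep("unique_a", n_ua),
                          rep("unique_b", n_ub),
                          rep("null", n_genes - n_common - n_ua - n_ub)))
    signs <- sample(c(-1, 1), n_genes, replace = TRUE)
    mu0 <- stats::rlnorm(n_genes, meanlog = log(baseline_mean), sdlog = 1)
    lfc_a <- ifelse(class_vec %in% c("common", "unique_a"),
                    signs * log_fc, 0)
    lfc_b <- ifelse(class_vec %in% c("common", "unique_b"),
                    signs * log_fc, 0)
    mu_mat <- cbind(
      matrix(mu0, n_genes, n_o),
      matrix(mu0 * 2^lfc_a, n_genes, n_b),
      matrix(mu0 * 2^lfc_b, n_genes, n_b)
    )
    counts_mat <- matrix(
      rnbinom(length(mu_mat), mu = as.vector(mu_mat), size = 1 / dispersion),
      n_genes, ncol(mu_mat))
    # marker genes: expected library size sets the CPM scale
    exp_lib <- n_genes * baseline_mean * exp(0.5)  # lognormal mean
    mu_marker <- marker_cpm * exp_lib / 1e6
    x_genes <- sprintf("Xmarker_%02d", seq_len(n_x_markers))
    y_genes <- sprintf("Ymarker_%02d", seq_len(n_y_markers))
    x_mat <- matrix(rpois(n_x_markers * nrow(meta), mu_marker),
                    n_x_markers, nrow(meta))
    y_mat <- matrix(0L, n_y_markers, nrow(meta))
    male <- which(meta$sex == "M" & meta$stage == "blastocyst")
    if (length(male) > 0L && n_y_markers > 0L) {
      y_mat[, male] <- rpois(n_y_markers * length(male), mu_marker)
    }
  })
  colnames(counts_mat) <- meta$sample_id
  counts <- bind_rows(
    bind_cols(tibble(gene_id = gene_ids), as_tibble(counts_mat)),
    bind_cols(tibble(gene_id = x_genes),
              as_tibble(matrix(x_mat, n_x_markers,
                               dimnames = list(NULL, meta$sample_id)))),
    bind_cols(tibble(gene_id = y_genes),
              as_tibble(matrix(y_mat, n_y_markers,
                               dimnames = list(NULL, meta$sample_id))))
  )
  main_counts <- counts[counts$gene_id %in% gene_ids, ]
  deg_a <- deg_t_test(main_counts, meta$sample_id[meta$stage == "oocyte"],
                      meta$sample_id[!is.na(meta$group) & meta$group == "MT-"])
  deg_b <- deg_t_test(main_counts, meta$sample_id[meta$stage == "oocyte"],
                      meta$sample_id[!is.na(meta$group) & meta$group == "MT+"])
  list(counts = counts, deg_a = deg_a, deg_b = deg_b,
       truth = tibble(gene_id = gene_ids, class = class_vec,
                      lfc_a = lfc_a, lfc_b = lfc_b),
       meta = meta, x_genes = x_genes, y_genes = y_genes)
}

# vectorised per-gene equal-variance t-test on log2(CPM + 0.5)
deg_t_test <- function(counts, samples_ref, samples_alt) {
  cpms <- cpm(counts[c("gene_id", samples_ref, samples_alt)])
  logmat <- log2(as.matrix(cpms[c(samples_ref, samples_alt)]) + 0.5)
  n1 <- length(samples_ref)
  n2 <- length(samples_alt)
  x1 <- logmat[, seq_len(n1), drop = FALSE]
  x2 <- logmat[, n1 + seq_len(n2), drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m2 - m1) / se, 0)
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  tibble(
    gene_id = counts$gene_id,
    log_fc = m2 - m1,
    log_cpm = rowMeans(logmat),
    fdr = p.adjust(p, method = "BH")
  )
}
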