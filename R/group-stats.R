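#' Counts-per-million for a wide count table
#'
#' @param counts Tibble with a `gene_id` column and one numeric column per
#'   sample (raw counts). Library size is the column sum (unnormalised).
#' @return A tibble of the same shape holding CPM values.
#' @export
cpm <- function(counts) {
  num <- setdiff(names(counts), "gene_id")
  if (length(num) == 0L || nrow(counts) == 0L) {
    abort("the count matrix is empty.", class = "biallele_input_error")
  }
  lib <- vapply(counts[num], sum, double(1))
  if (any(lib <= 0)) {
    abort("library sizes must be > 0.", class = "biallele_input_error")
  }
  out <- counts
  for (s in num) out[[s]] <- counts[[s]] * 1e6 / lib[[s]]
  out
}

#' Determine sample sex from Y-linked marker expression
#'
#' A sample is called male iff its mean CPM over the Y-linked marker genes
#' reaches `threshold` (default 1 CPM), otherwise female — females carry
#' no Y chromosome, so Y-linked transcripts should be absent apart from
#' mapping noise. X-linked markers are reported alongside as a sanity
#' check but do not enter the call.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param x_genes,y_genes Character vectors of marker gene ids; both must
#'   be non-empty and present in `counts`.
#' @param threshold Mean Y-marker CPM at or above which a sample is called
#'   male.
#' @return A tibble: `sample_id`, `y_cpm`, `x_cpm`, `sex` (`"M"`/`"F"`).
#' @export
determine_sex <- function(counts, x_genes, y_genes, threshold = 1) {
  if (length(y_genes) == 0L || length(x_genes) == 0L) {
    abort("marker gene lists must be non-empty.", class = "biallele_config_error")
  }
  missing <- setdiff(c(x_genes, y_genes), counts$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf("marker gene(s) absent from the count matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "biallele_config_error")
  }
  cpms <- cpm(counts)
  samples <- setdiff(names(counts), "gene_id")
  marker_mean <- function(genes, s) {
    mean(cpms[[s]][cpms$gene_id %in% genes])
  }
  tibble(
    sample_id = samples,
    y_cpm = vapply(samples, function(s) marker_mean(y_genes, s), double(1)),
    x_cpm = vapply(samples, function(s) marker_mean(x_genes, s), double(1))
  ) |>
    mutate(sex = if_else(.data$y_cpm >= threshold, "M", "F"))
}

#' Factorial ANOVA of SNP frequency with Tukey post-hoc comparison
#'
#' Fits `snp_per_kb ~ group * status + covariates` on the per-transcript
#' summaries (status = imprinted vs non-imprinted), reports a Type II
#' analysis-of-variance table (robust to the unbalance that dropped
#' transcripts introduce; switchable to Type III), and runs Tukey HSD on
#' the four group x status cell means. Covariates enter as additive
#' categorical main effects only; covariates with fewer than two observed
#' levels are dropped with a message.
#'
#' Transcripts that failed the confident-SNP retention rule carry no
#' bi-allelic evidence; by default they enter the response as
#' `snp_per_kb = 0` (their candidate SNPs were discarded), which is what
#' lets mono-allelic transcripts pull their cell mean down. Set
#' `nonretained = "drop"` to exclude them instead.
#'
#' @param summaries Per-transcript summary tibble from
#'   [summarize_transcripts()] (needs `gene_id`, `sample_id`,
#'   `snp_per_kb`, `retained`, `imprinted`).
#' @param meta Sample sheet with `sample_id`, `group`, and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names in `meta`.
#' @param terms Model terms on the right-hand side; `NULL` (default) fits
#'   the full factorial `group * status` plus the covariates. Supply e.g.
#'   `"group"` for a single-factor analysis. The Tukey cell comparison is
#'   computed only when both `group` and `status` are in the model.
#' @param nonretained `"zero"` (default) or `"drop"`.
#' @param ss_type Sum-of-squares type for `car::Anova` (2 or 3).
#' @param tukey Compute the Tukey cell-mean comparison (default `TRUE`;
#'   disable to speed up large replication studies that only read the
#'   ANOVA table).
#' @return An object of class `"allelic_anova"`: a list with `anova`
#'   (term, sumsq, df, statistic, p_value), `tukey` (cell-pair contrasts
#'   with Tukey-adjusted p), `model` (the `lm` fit), `data` (the analysis
#'   table) and `constant_response` (flag; when `TRUE` the test statistics
#'   are undefined and reported as `NA`).
#' @export
anova_snp_frequency <- function(summaries, meta,
                                covariates = c("sex", "sampling_date",
                                               "library_date"),
                                terms = NULL,
                                nonretained = c("zero", "drop"),
                                ss_type = 2, tukey = TRUE) {
  nonretained <- match.arg(nonretained)
  dat <- summaries |>
    inner_join(meta, by = "sample_id") |>
    mutate(status = factor(if_else(.data$imprinted, "imprinted",
                                   "non-imprinted"),
                           levels = c("imprinted", "non-imprinted")),
           group = factor(.data$group))
  if (nonretained == "zero") {
    dat <- mutate(dat, snp_per_kb = if_else(.data$retained,
                                            .data$snp_per_kb, 0))
  } else {
    dat <- filter(dat, .data$retained)
  }
  if (is.null(terms)) terms <- c("group", "status", "group:status")
  tested <- intersect(c("group", "status"), unlist(strsplit(terms, ":")))
  for (f in tested) {
    if (length(unique(dat[[f]])) < 2L) {
      abort(sprintf("factor '%s' has fewer than 2 levels in the data.", f),
            class = "biallele_input_error")
    }
  }
  covariates <- covariates[covariates %in% names(dat)]
  keep_cov <- vapply(covariates,
                     function(cv) length(unique(dat[[cv]])) >= 2L, logical(1))
  if (any(!keep_cov)) {
    message("dropping single-level covariate(s): ",
            paste(covariates[!keep_cov], collapse = ", "))
  }
  covariates <- covariates[keep_cov]
  for (cv in covariates) dat[[cv]] <- factor(dat[[cv]])

  term_names <- c(terms, covariates)
  if (var(dat$snp_per_kb) == 0) {
    # degenerate: a constant response carries no evidence either way
    anova_tbl <- tibble(term = term_names, sumsq = 0,
                        df = NA_integer_, statistic = NA_real_,
                        p_value = NA_real_)
    out <- list(anova = anova_tbl, tukey = empty_tukey(), model = NULL,
                data = dat, constant_response = TRUE)
    return(structure(out, class = "allelic_anova"))
  }
  fml <- stats::as.formula(paste(
    "snp_per_kb ~", paste(c(terms, covariates), collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(sprintf("rank-deficient design; aliased term(s): %s",
                  paste(aliased, collapse = ", ")),
          class = "biallele_input_error")
  }
  a <- car::Anova(fit, type = ss_type)
  anova_tbl <- tibble(
    term = rownames(a),
    sumsq = a[["Sum Sq"]],
    df = a[["Df"]],
    statistic = a[["F value"]],
    p_value = a[["Pr(>F)"]]
  )
  tukey_tbl <- empty_tukey()
  if (tukey && all(c("group", "status") %in% tested)) {
    emm <- emmeans::emmeans(fit, ~ group * status)
    grid <- as.data.frame(emm)
    pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "tukey"))
    idx <- utils::combn(nrow(grid), 2)
    tukey_tbl <- tibble(
      group_1 = as.character(grid$group[idx[1, ]]),
      status_1 = as.character(grid$status[idx[1, ]]),
      group_2 = as.character(grid$group[idx[2, ]]),
      status_2 = as.character(grid$status[idx[2, ]]),
      estimate = pr$estimate,
      se = pr$SE,
      adj_p_value = pr$p.value
    )
  }
  structure(list(anova = anova_tbl, tukey = tukey_tbl, model = fit, data = dat,
                 constant_response = FALSE),
            class = "allelic_anova")
}

empty_tukey <- function() {
  tibble(group_1 = character(), status_1 = character(),
         group_2 = character(), status_2 = character(),
         estimate = double(), se = double(), adj_p_value = double())
}

#' @export
print.allelic_anova <- function(x, ...) {
  cat("Factorial ANOVA of SNP frequency (SNP/kb)\n")
  if (x$constant_response) {
    cat("  constant response: test statistics undefined\n")
  } else {
    print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
    cat("\nTukey HSD on group x status cell means:\n")
    print(as.data.frame(x$tukey), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @rdname anova_snp_frequency
#' @param x An `allelic_anova` object.
#' @param type `"anova"` (default) or `"tukey"`: which table to tidy.
#' @param ... Unused.
#' @export
tidy.allelic_anova <- function(x, type = c("anova", "tukey"), ...) {
  type <- match.arg(type)
  if (type == "anova") x$anova else x$tukey
}

#' @rdname anova_snp_frequency
#' @export
glance.allelic_anova <- function(x, ...) {
  if (x$constant_response || is.null(x$model)) {
    return(tibble(r.squared = NA_real_, adj.r.squared = NA_real_,
                  sigma = NA_real_, df.residual = NA_integer_,
                  nobs = nrow(x$data)))
  }
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, df.residual = x$model$df.residual,
         nobs = stats::nobs(x$model))
}

#' Jittered boxplot of SNP frequency by imprinting status and group
#'
#' The per-class view of the allelic-expression screen: one panel per
#' treatment group, SNP/kb by imprinting status, transcripts as jittered
#' points over boxes. Non-retained transcripts are shown at 0.
#'
#' @param summaries Per-transcript summary tibble (with `imprinted`).
#' @param meta Sample sheet with `sample_id` and `group`.
#' @return A ggplot object.
#' @export
plot_snp_frequency <- function(summaries, meta) {
  dat <- summaries |>
    inner_join(meta, by = "sample_id") |>
    mutate(status = if_else(.data$imprinted, "imprinted", "non-imprinted"),
           snp_per_kb = if_else(.data$retained, .data$snp_per_kb, 0))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$status, y = .data$snp_per_kb)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "SNP frequency (SNP/kb transcript)") +
    ggplot2::theme_bw()
}

#' @rdname anova_snp_frequency
#' @param object An `allelic_anova` object.
#' @export
autoplot.allelic_anova <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$status, y = .data$snp_per_kb)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "SNP frequency (SNP/kb transcript)") +
    ggplot2::theme_bw()
}
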