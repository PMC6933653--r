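#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min_{j >= i} p_(j) * m / j over the sorted p-values, clipped at 1
#' and mapped back to the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
benjamini_hochberg <- function(pvals) {
  p <- as.numeric(pvals)
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

de_label <- function(logfc, q, alpha) {
  dplyr::case_when(
    q <= alpha & logfc > 0 ~ "up",
    q <= alpha & logfc < 0 ~ "down",
    TRUE ~ "unchanged"
  )
}

new_de_result <- function(tb, alpha, method) {
  class(tb) <- c("de_result", class(tb))
  attr(tb, "alpha") <- alpha
  attr(tb, "method") <- method
  tb
}

#' Import an externally computed differential-expression table
#'
#' Carrier for DE calls produced by a dedicated tool (e.g. a
#' negative-binomial GLM package). Expects a TSV with columns `gene_id`,
#' `logFC` and `p`; a `q` column is preserved verbatim when present and
#' completed by Benjamini-Hochberg adjustment when absent. Labels are
#' assigned at `alpha` on q and the sign of logFC.
#'
#' @param path Path to the TSV.
#' @param alpha Significance threshold on the adjusted q-value.
#' @return A tibble of class `de_result`: `gene_id`, `logFC`, `p`, `q`,
#'   `label`.
#' @export
import_de_results <- function(path, alpha = 0.05) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  miss <- setdiff(c("gene_id", "logFC", "p"), names(tb))
  if (length(miss)) abort(paste0("DE table lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(tb$gene_id)) {
    abort(paste0("duplicate gene id in DE table: ", tb$gene_id[duplicated(tb$gene_id)][1]))
  }
  if (!"q" %in% names(tb)) {
    tb$q <- benjamini_hochberg(tb$p)
  } else if (any(tb$q < tb$p, na.rm = TRUE)) {
    warn("imported q-values smaller than raw p-values for some genes")
  }
  tb <- tb %>% mutate(label = de_label(.data$logFC, .data$q, alpha))
  new_de_result(select(tb, "gene_id", "logFC", "p", "q", "label"),
                alpha, "imported")
}

#' Rank-based two-group differential expression stand-in
#'
#' Per-gene two-sided Wilcoxon rank-sum test of log2(TPM+1) between the two
#' conditions, Benjamini-Hochberg adjusted, with the log fold change computed
#' as log2((mean TPM alt + 1) / (mean TPM ref + 1)). The test uses the
#' tie-corrected normal approximation with continuity correction, vectorised
#' across genes; genes with all values tied get p = 1. This is a robust
#' stand-in so the full pipeline runs end to end on any matrix — it is not a
#' reimplementation of negative-binomial GLM differential expression, and
#' externally computed DE tables can be supplied via [import_de_results()]
#' instead.
#'
#' @param em An `expression_matrix`.
#' @param alpha Significance threshold on q.
#' @param ref,alt Condition labels (reference and altered).
#' @return A tibble of class `de_result`: `gene_id`, `logFC`, `p`, `q`,
#'   `label`.
#' @export
simple_de_test <- function(em, alpha = 0.05, ref = "WT", alt = "KD") {
  stopifnot(inherits(em, "expression_matrix"))
  in_ref <- em$cells$condition == ref
  in_alt <- em$cells$condition == alt
  if (sum(in_ref) < 2 || sum(in_alt) < 2) abort("each condition needs at least 2 cells")
  x <- em$log_expr[, in_ref | in_alt, drop = FALSE]
  grp_alt <- em$cells$condition[in_ref | in_alt] == alt
  p <- ranksum_rows(x, grp_alt)
  mean_ref <- rowMeans(em$tpm[, in_ref, drop = FALSE])
  mean_alt <- rowMeans(em$tpm[, in_alt, drop = FALSE])
  tb <- tibble(
    gene_id = rownames(em$tpm),
    logFC = log2((mean_alt + 1) / (mean_ref + 1)),
    p = p,
    q = benjamini_hochberg(p)
  ) %>% mutate(label = de_label(.data$logFC, .data$q, alpha))
  new_de_result(tb, alpha, "wilcoxon rank-sum (normal approximation)")
}

# Row-wise two-sided rank-sum p, tie-corrected normal approximation with
# continuity correction; matches wilcox.test(exact = FALSE, correct = TRUE).
ranksum_rows <- function(x, grp_alt) {
  n1 <- sum(grp_alt)
  n2 <- sum(!grp_alt)
  n <- n1 + n2
  r <- t(apply(x, 1, rank))
  w <- rowSums(r[, grp_alt, drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_term <- apply(r, 1, function(ri) {
    t <- table(ri)
    sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z_num <- w - mu
  cc <- sign(z_num) * 0.5
  p <- ifelse(sigma2 <= 0, 1, 2 * pnorm(-abs((z_num - cc) / sqrt(sigma2))))
  pmin(unname(p), 1)
}

#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$label == "up"),
    n_down = sum(x$label == "down"),
    n_unchanged = sum(x$label == "unchanged"),
    alpha = attr(x, "alpha"),
    method = attr(x, "method")
  )
}

#' @exportS3Method generics::tidy
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_result")
  out
}

#' Volcano-style plot of a differential-expression result
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot of -log10 q against logFC, coloured by label.
#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$logFC, y = -log10(pmax(.data$q, 1e-300)), colour = .data$label
  )) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(
      up = "#c0392b", down = "#2980b9", unchanged = "grey60"
    )) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q", colour = NULL) +
    ggplot2::theme_minimal()
}
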