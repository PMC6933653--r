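#' Principal component analysis of cells in log-expression space
#'
#' Cells are embedded by PCA of their log2(TPM+1) vectors, gene-centred and
#' by default not unit-scaled (centering-only preserves expression-magnitude
#' structure and is the common single-cell default). PC signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is positive, so repeated runs and platforms agree.
#'
#' @param em An `expression_matrix`.
#' @param n_pcs Number of components to retain.
#' @param scale_genes Unit-scale genes before PCA.
#' @return An object of class `pca_result`: list with `scores` (cells x PCs
#'   matrix), `loadings` (genes x PCs matrix), `explained` (variance
#'   fractions per retained PC), `cells` (the cell metadata tibble),
#'   `center`, `scaled`.
#' @export
pca_embed <- function(em, n_pcs = 10, scale_genes = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  x <- t(em$log_expr)  # cells x genes
  if (nrow(x) < n_pcs + 1) abort("need at least n_pcs + 1 cells")
  v <- apply(x, 2, var)
  if (all(v == 0)) abort("expression matrix is constant; PCA undefined")
  if (scale_genes) {
    keep <- v > 0
    x <- x[, keep, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = scale_genes)
  n_pcs <- min(n_pcs, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  sco <- pc$x[, seq_len(n_pcs), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per PC
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = sco, loadings = rot,
      explained = ev[seq_len(n_pcs)],
      cells = em$cells, center = pc$center, scaled = scale_genes
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d cells x %d PCs; PC1 explains %.1f%% of variance\n",
    nrow(x$scores), ncol(x$scores), 100 * x$explained[1]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pca_result <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = dplyr::bind_cols(x$cells, as_tibble(x$scores)),
    loadings = as_tibble(x$loadings, rownames = "gene_id"),
    eigenvalues = tibble(
      pc = seq_along(x$explained),
      explained_fraction = x$explained,
      cumulative = cumsum(x$explained)
    )
  )
}

#' @exportS3Method generics::glance
glance.pca_result <- function(x, ...) {
  tibble(
    n_cells = nrow(x$scores), n_pcs = ncol(x$scores),
    pc1_explained = x$explained[1],
    pc2_explained = if (length(x$explained) > 1) x$explained[2] else NA_real_
  )
}

#' Plot a PCA embedding coloured by condition
#'
#' @param object A `pca_result`.
#' @param pcs Which two components to plot.
#' @param ... Unused.
#' @return A ggplot, coloured by condition and shaped by batch.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_result <- function(object, pcs = c(1, 2), ...) {
  sc <- tidy(object, "scores")
  xvar <- paste0("PC", pcs[1]); yvar <- paste0("PC", pcs[2])
  ggplot2::ggplot(sc, ggplot2::aes(
    x = .data[[xvar]], y = .data[[yvar]],
    colour = .data$condition, shape = .data$batch
  )) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xvar, 100 * object$explained[pcs[1]]),
      y = sprintf("%s (%.1f%%)", yvar, 100 * object$explained[pcs[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Test group separation along one principal component
#'
#' Two-sided two-sample Student's t-test (equal-variance by default; Welch by
#' flag) on the coordinates of the chosen PC between two groups of cells.
#' Used both for condition separation and for checking the absence of a
#' batch effect.
#'
#' @param pca A `pca_result`.
#' @param labels Either the name of a metadata column (`"condition"`,
#'   `"batch"`) or a vector of two-level labels aligned with the cells.
#' @param pc Which component to test.
#' @param var_equal Classical equal-variance t-test (default); `FALSE` for
#'   Welch.
#' @return A one-row tibble: `pc`, `statistic`, `df`, `p_value`,
#'   `mean_group_1`, `mean_group_2`, `method`.
#' @export
separation_test <- function(pca, labels = "condition", pc = 1, var_equal = TRUE) {
  stopifnot(inherits(pca, "pca_result"))
  if (is.character(labels) && length(labels) == 1) {
    if (!labels %in% names(pca$cells)) abort(paste0("no metadata column '", labels, "'"))
    labels <- pca$cells[[labels]]
  }
  labels <- as.character(labels)
  levs <- sort(unique(labels))
  if (length(levs) != 2) abort("separation_test requires exactly 2 groups")
  if (min(table(labels)) < 2) abort("each group needs at least 2 cells")
  v <- pca$scores[, pc]
  ht <- t.test(v[labels == levs[1]], v[labels == levs[2]], var.equal = var_equal)
  tibble(
    pc = pc, statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_group_1 = unname(ht$estimate[1]), mean_group_2 = unname(ht$estimate[2]),
    method = if (var_equal) "Student t (equal variance)" else "Welch t"
  )
}

#' Correlate one gene's expression with PC coordinates
#'
#' Squared Pearson correlation of the gene's log2(TPM+1) vector with each
#' retained PC's scores, with the two-sided t-distribution p-value for the
#' correlation. Used to relate a driver gene's expression level to the
#' embedding (e.g. a knocked-down factor versus PC coordinates).
#'
#' @param em The `expression_matrix` the PCA was computed from.
#' @param gene_id Gene to correlate.
#' @param pca A `pca_result` on the same cells.
#' @param pcs Components to test; default all retained.
#' @return A tibble: `pc`, `r`, `r_squared`, `p_value`.
#' @export
gene_pc_correlation <- function(em, gene_id, pca, pcs = NULL) {
  stopifnot(inherits(em, "expression_matrix"), inherits(pca, "pca_result"))
  if (!gene_id %in% rownames(em$log_expr)) abort(paste0("gene not found: ", gene_id))
  g <- em$log_expr[gene_id, ]
  if (sd(g) == 0) abort(paste0("gene '", gene_id, "' is constant; correlation undefined"))
  if (is.null(pcs)) pcs <- seq_len(ncol(pca$scores))
  purrr::map_dfr(pcs, function(j) {
    ht <- suppressWarnings(cor.test(g, pca$scores[, j]))
    tibble(pc = j, r = unname(ht$estimate),
           r_squared = unname(ht$estimate)^2, p_value = ht$p.value)
  })
}
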