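#' Filter cells by number of detected genes
#'
#' A gene counts as detected in a cell when its raw count is greater than
#' zero. Cells detecting fewer than `min_genes` genes are removed; the
#' default of 3000 is the standard quality threshold for full-length
#' single-cell libraries. The threshold is inclusive: a cell with exactly
#' `min_genes` detected genes is retained.
#'
#' @param cm A [count_matrix()].
#' @param min_genes Minimum number of detected genes per cell.
#' @return The filtered `count_matrix`, with the removal recorded in its
#'   filter log (including per-removed-cell detected counts).
#' @export
filter_cells_by_detected_genes <- function(cm, min_genes = 3000) {
  stopifnot(inherits(cm, "count_matrix"))
  detected <- colSums(cm$counts > 0)
  keep <- detected >= min_genes
  if (!any(keep)) {
    abort(sprintf(
      "all %d cells removed at min_genes = %d (max detected: %d); review the threshold",
      ncol(cm$counts), min_genes, max(detected)
    ))
  }
  dim_before <- dim(cm$counts)
  cm$counts <- cm$counts[, keep, drop = FALSE]
  cm$cells <- cm$cells[keep, , drop = FALSE]
  cm$filter_log <- append_log(
    cm$filter_log, "filter_cells_by_detected_genes",
    list(min_genes = min_genes), dim_before, dim(cm$counts),
    details = list(removed = setNames(detected[!keep], names(detected)[!keep]))
  )
  cm
}

#' Normalise a count matrix to TPM
#'
#' Transcripts per million: per cell, each gene's count is divided by its
#' effective length, and the resulting rates are rescaled to sum to 10^6.
#' When no length table is supplied every length is taken as 1, which reduces
#' TPM to counts per million; this is recorded in the filter log. Length
#' cancels within a gene, so per-gene statistics downstream (CV, noise, PCA
#' on gene-centred values) are unaffected by the fallback.
#'
#' @param cm A [count_matrix()].
#' @param lengths Optional tibble with columns `gene_id`, `length`. Must cover
#'   every gene in `cm` when supplied.
#' @return An `expression_matrix` holding TPM and log2(TPM+1), inheriting the
#'   count matrix's filter log.
#' @export
tpm_normalize <- function(cm, lengths = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  genes <- rownames(cm$counts)
  if (is.null(lengths)) {
    len <- rep(1, length(genes))
    fallback <- TRUE
  } else {
    len <- lengths$length[match(genes, lengths$gene_id)]
    if (anyNA(len)) {
      abort(paste0("no length for gene(s): ", genes[which(is.na(len))[1]],
                   " ... ; supply a complete table or omit `lengths` for counts-per-million"))
    }
    if (any(len <= 0)) abort("gene lengths must be positive")
    fallback <- FALSE
  }
  rate <- cm$counts / len
  totals <- colSums(rate)
  zero_cells <- totals == 0
  if (any(zero_cells)) {
    warn(sprintf("%d all-zero cell(s) produce all-zero TPM", sum(zero_cells)))
    totals[zero_cells] <- 1
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  log <- append_log(
    cm$filter_log, "tpm_normalize",
    list(lengths = if (fallback) "none (counts-per-million fallback, all lengths = 1)" else "supplied"),
    dim(cm$counts), dim(cm$counts)
  )
  new_expression_matrix(tpm, cm$cells, log)
}

#' Filter genes by expression prevalence
#'
#' Retains genes whose expression exceeds `level` on the log2(TPM+1) scale
#' (strict inequality) in at least `min_cells` cells. The defaults remove
#' genes with log2(TPM+1) > 1 in fewer than two cells.
#'
#' @param em An `expression_matrix` (cells should already have passed QC).
#' @param level Expression level on the log2(TPM+1) scale; strict `>` applies.
#' @param min_cells Minimum number of cells exceeding `level`.
#' @return The filtered `expression_matrix`.
#' @export
filter_genes_by_prevalence <- function(em, level = 1.0, min_cells = 2L) {
  stopifnot(inherits(em, "expression_matrix"))
  n_above <- rowSums(em$log_expr > level)
  keep <- n_above >= min_cells
  if (!any(keep)) warn("prevalence filter removed every gene")
  dim_before <- dim(em$tpm)
  em$tpm <- em$tpm[keep, , drop = FALSE]
  em$log_expr <- em$log_expr[keep, , drop = FALSE]
  em$filter_log <- append_log(
    em$filter_log, "filter_genes_by_prevalence",
    list(level = level, min_cells = min_cells), dim_before, dim(em$tpm)
  )
  em
}

#' Pool cells into pseudobulk profiles and correlate groups
#'
#' Sums counts within each group (condition or batch), TPM-normalises the
#' summed profiles, and reports the squared Pearson correlation of
#' log2(TPM+1) for every group pair. Used to check reproducibility between
#' batches or agreement of pooled single cells with bulk-style profiles.
#'
#' @param cm A [count_matrix()].
#' @param by Grouping variable: `"condition"` or `"batch"`.
#' @param lengths Optional gene-length table, as in [tpm_normalize()].
#' @return A list with `profiles` (tibble: gene_id, one log2(TPM+1) column per
#'   group) and `correlations` (tibble: group_1, group_2, r_squared).
#' @export
pooled_pseudobulk <- function(cm, by = c("condition", "batch"), lengths = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  by <- match.arg(by)
  groups <- cm$cells[[by]]
  levs <- unique(groups)
  if (length(levs) < 2) abort("pooled_pseudobulk requires at least 2 groups")
  summed <- vapply(levs, function(g) {
    rowSums(cm$counts[, groups == g, drop = FALSE])
  }, numeric(nrow(cm$counts)))
  colnames(summed) <- levs
  pooled_cm <- count_matrix(
    summed,
    tibble(cell_id = levs, condition = levs, batch = levs)
  )
  em <- tpm_normalize(pooled_cm, lengths)
  pairs <- utils::combn(levs, 2)
  cors <- tibble(
    group_1 = pairs[1, ], group_2 = pairs[2, ],
    r_squared = apply(pairs, 2, function(p) {
      cor(em$log_expr[, p[1]], em$log_expr[, p[2]])^2
    })
  )
  list(
    profiles = as_tibble(em$log_expr, rownames = "gene_id"),
    correlations = cors
  )
}
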