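#' Construct a count matrix with cell metadata
#'
#' Bundles a genes-by-cells matrix of non-negative integer counts with a
#' per-cell metadata table. This is the entry object of the pipeline; all
#' quality filters operate on it before TPM normalisation.
#'
#' @param counts Numeric matrix, genes in rows, cells in columns. Entries must
#'   be finite, non-negative whole numbers. Row and column names are used as
#'   gene and cell identifiers and must be unique.
#' @param cell_meta Data frame with one row per cell and columns `cell_id`,
#'   `condition` and `batch`. Order need not match the matrix columns; rows
#'   are matched by `cell_id`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix), `cells` (a tibble aligned with the matrix columns) and
#'   `filter_log` (a list recording applied filters).
#' @export
count_matrix <- function(counts, cell_meta) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    abort("`counts` must have gene row names and cell column names.")
  }
  if (anyDuplicated(gene_ids)) {
    abort(paste0("duplicate gene ids: ", gene_ids[duplicated(gene_ids)][1]))
  }
  if (anyDuplicated(cell_ids)) {
    abort(paste0("duplicate cell ids: ", cell_ids[duplicated(cell_ids)][1]))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    abort(sprintf(
      "counts must be finite non-negative integers; first offending entry at gene '%s', cell '%s' (value %s)",
      gene_ids[i[1]], cell_ids[i[2]], format(counts[bad[1]])
    ))
  }
  meta <- as_tibble(cell_meta)
  need <- c("cell_id", "condition", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("cell metadata lacks column(s): ", paste(miss, collapse = ", ")))
  meta$cell_id <- as.character(meta$cell_id)
  unmatched <- setdiff(meta$cell_id, cell_ids)
  if (length(unmatched)) {
    abort(paste0("metadata lists cell(s) absent from the matrix: ", unmatched[1]))
  }
  unmatched2 <- setdiff(cell_ids, meta$cell_id)
  if (length(unmatched2)) {
    abort(paste0("matrix contains cell(s) absent from metadata: ", unmatched2[1]))
  }
  if (anyDuplicated(meta$cell_id)) {
    abort("cell metadata has duplicated cell_id rows")
  }
  meta <- meta[match(cell_ids, meta$cell_id), , drop = FALSE]
  storage.mode(counts) <- "double"  # uniform storage across io dialects
  structure(
    list(counts = counts, cells = meta, filter_log = list()),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)
  ))
  cat("  conditions:", paste(sprintf(
    "%s (%d)", names(table(x$cells$condition)), table(x$cells$condition)
  ), collapse = ", "), "\n")
  cat("  batches:   ", paste(sprintf(
    "%s (%d)", names(table(x$cells$batch)), table(x$cells$batch)
  ), collapse = ", "), "\n")
  if (length(x$filter_log)) {
    cat("  filters applied:", paste(vapply(x$filter_log, `[[`, "", "step"), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

new_expression_matrix <- function(tpm, cells, filter_log = list()) {
  structure(
    list(
      tpm = tpm,
      log_expr = log2(tpm + 1),
      cells = cells,
      filter_log = filter_log
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d cells (TPM + log2(TPM+1))\n",
    nrow(x$tpm), ncol(x$tpm)
  ))
  if (length(x$filter_log)) {
    cat("  history:", paste(vapply(x$filter_log, `[[`, "", "step"), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$tpm)

append_log <- function(log, step, params, dim_before, dim_after, details = NULL) {
  c(log, list(list(
    step = step, params = params,
    dim_before = dim_before, dim_after = dim_after,
    details = details
  )))
}

#' Retrieve the filter history of a pipeline object
#'
#' @param x A `count_matrix` or `expression_matrix`.
#' @return A tibble with one row per applied filter: step name, before/after
#'   dimensions and a parameter summary.
#' @export
filter_log <- function(x) {
  stopifnot(inherits(x, c("count_matrix", "expression_matrix")))
  if (!length(x$filter_log)) {
    return(tibble(
      step = character(), genes_before = integer(), cells_before = integer(),
      genes_after = integer(), cells_after = integer(), params = character()
    ))
  }
  purrr::map_dfr(x$filter_log, function(e) tibble(
    step = e$step,
    genes_before = e$dim_before[1], cells_before = e$dim_before[2],
    genes_after = e$dim_after[1], cells_after = e$dim_after[2],
    params = paste(names(e$params), unlist(lapply(e$params, format)),
                   sep = "=", collapse = "; ")
  ))
}
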