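#' Read a genes-by-cells count matrix with cell metadata
#'
#' Supports two on-disk dialects: MatrixMarket triplet (`.mtx` with `.genes`
#' and `.cells` sidecar files listing row and column ids, one per line) and a
#' TSV matrix (first column `gene_id`, remaining columns named by cell id).
#' Cell metadata is a TSV with columns `cell_id`, `condition`, `batch`.
#'
#' @param path Path to the matrix file (`.mtx` or `.tsv`).
#' @param metadata_path Path to the cell metadata TSV.
#' @param format `"auto"` (by extension), `"mtx"` or `"tsv"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, metadata_path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  if (!file.exists(metadata_path)) abort(paste0("metadata file not found: ", metadata_path))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(sub("\\.mtx$", ".genes", path))
    cells <- readLines(sub("\\.mtx$", ".cells", path))
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      abort("sidecar gene/cell id files do not match matrix dimensions")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    tb <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(), .default = readr::col_double()
    ))
    m <- as.matrix(tb[, -1, drop = FALSE])
    rownames(m) <- tb$gene_id
  }
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(.default = readr::col_character()))
  count_matrix(m, meta)
}

#' Write a count matrix and its metadata to disk
#'
#' Inverse of [read_count_matrix()]; the round trip preserves counts, ids and
#' labels exactly.
#'
#' @param cm A `count_matrix`.
#' @param path Output matrix path (`.mtx` or `.tsv`).
#' @param metadata_path Output metadata TSV path.
#' @param format `"auto"`, `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, metadata_path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(rownames(cm$counts), sub("\\.mtx$", ".genes", path))
    writeLines(colnames(cm$counts), sub("\\.mtx$", ".cells", path))
  } else {
    tb <- as_tibble(cm$counts, rownames = "gene_id")
    readr::write_tsv(tb, path)
  }
  readr::write_tsv(cm$cells, metadata_path)
  invisible(path)
}

#' Read a gene-length table
#'
#' TSV with columns `gene_id` and `length` (effective length in bases, used
#' for TPM normalisation).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `length`.
#' @export
read_gene_lengths <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), length = readr::col_double()
  ))
  if (any(!is.finite(tb$length) | tb$length <= 0)) {
    abort("gene lengths must be positive and finite")
  }
  tb
}

#' Read a BED file of regulatory-site intervals
#'
#' Parses BED 0-based half-open intervals. `track`, `browser` and `#` comment
#' lines are skipped. Columns beyond the third (name, score) are kept when
#' present.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) {
    abort(sprintf("BED line %d has fewer than 3 tab-separated fields", idx[which.min(lengths(fields))]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.numeric(vapply(fields, `[[`, "", 2))
  end <- as.numeric(vapply(fields, `[[`, "", 3))
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end)
  if (length(bad)) {
    abort(sprintf("BED line %d: start must be < end (got %s, %s)",
                  idx[bad[1]], fields[[bad[1]]][2], fields[[bad[1]]][3]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  ncol_max <- max(lengths(fields))
  if (ncol_max >= 4) {
    out$name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  }
  if (ncol_max >= 5) {
    out$score <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_, "")
    ))
  }
  out
}

#' Read a TSS table
#'
#' TSV with columns `gene_id`, `chrom`, `tss` (0-based position), `strand`.
#'
#' @param path Path to the TSV.
#' @return A tibble with one TSS per gene.
#' @export
read_tss_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_double(), strand = readr::col_character()
  ))
  if (anyDuplicated(tb$gene_id)) abort("TSS table must have one row per gene")
  if (any(tb$tss < 0)) abort("TSS positions must be >= 0")
  tb
}

#' Derive one TSS per gene from a GTF annotation
#'
#' Uses transcript features. The TSS is the transcript start for `+` strand
#' genes and the transcript end for `-` strand genes, converted from GTF
#' 1-based inclusive coordinates to 0-based positions. When a gene has several
#' transcripts, `policy` selects one TSS: `most_upstream` takes the 5'-most
#' position in the direction of transcription; `longest_transcript` takes the
#' TSS of the longest transcript.
#'
#' @param path Path to a GTF file.
#' @param policy TSS selection policy for multi-transcript genes.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
tss_from_gtf <- function(path, policy = c("most_upstream", "longest_transcript")) {
  policy <- match.arg(policy)
  gr <- rtracklayer::import(path, format = "gtf")
  tx <- gr[gr$type == "transcript"]
  if (!length(tx)) abort("GTF contains no transcript features")
  tb <- tibble(
    gene_id = as.character(tx$gene_id),
    chrom = as.character(GenomicRanges::seqnames(tx)),
    start1 = GenomicRanges::start(tx),
    end1 = GenomicRanges::end(tx),
    strand = as.character(GenomicRanges::strand(tx))
  )
  tb <- tb[tb$strand %in% c("+", "-"), , drop = FALSE]
  # 0-based TSS: start-1 on + strand, end-1 on - strand
  tb$tss <- ifelse(tb$strand == "+", tb$start1 - 1, tb$end1 - 1)
  tb$width <- tb$end1 - tb$start1 + 1
  picked <- tb %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      tss = if (policy == "longest_transcript") {
        .data$tss[which.max(.data$width)]
      } else if (.data$strand[1] == "+") min(.data$tss) else max(.data$tss),
      .groups = "drop"
    ) %>%
    select("gene_id", "chrom", "tss", "strand")
  picked
}

#' Read gene sets in GMT format
#'
#' Each line: term, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (term -> gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}
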