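# Small in-code fixtures shared across test files.

# A tiny deterministic count matrix: `ng` genes x `nc` cells, two conditions
# split evenly, one batch.
tiny_cm <- function(ng = 3, nc = 4, counts = NULL, conditions = NULL) {
  if (is.null(counts)) {
    counts <- matrix(seq_len(ng * nc) %% 7, ng, nc)
  }
  rownames(counts) <- paste0("g", seq_len(ng))
  colnames(counts) <- paste0("c", seq_len(nc))
  if (is.null(conditions)) {
    conditions <- rep(c("WT", "KD"), length.out = nc)
  }
  count_matrix(counts, tibble::tibble(
    cell_id = colnames(counts), condition = conditions, batch = "B1"
  ))
}

# Build an expression_matrix directly from a TPM matrix (bypassing counts),
# for unit tests of the noise statistics.
em_from_tpm <- function(tpm, conditions, batch = "B1") {
  if (is.null(rownames(tpm))) rownames(tpm) <- paste0("g", seq_len(nrow(tpm)))
  if (is.null(colnames(tpm))) colnames(tpm) <- paste0("c", seq_len(ncol(tpm)))
  cells <- tibble::tibble(
    cell_id = colnames(tpm), condition = conditions,
    batch = rep(batch, length.out = ncol(tpm))
  )
  structure(
    list(tpm = tpm, log_expr = log2(tpm + 1), cells = cells, filter_log = list()),
    class = "expression_matrix"
  )
}

# Independent brute-force recomputation of the mean +/- SD classifier: plain
# loops, no shared code with classify_variation_change().
brute_force_classify <- function(cv_ref, cv_alt) {
  d <- cv_alt - cv_ref
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  lab <- character(n)
  for (i in seq_len(n)) {
    lab[i] <- if (d[i] > m + s) "increased" else if (d[i] < m - s) "decreased" else "unchanged"
  }
  lab
}

# O(n*m) brute-force peak counting: any overlap between the BED half-open
# peak [start, end) and the closed window [tss - w, tss + w].
brute_force_peak_counts <- function(peaks, tss, w) {
  vapply(seq_len(nrow(tss)), function(i) {
    hit <- 0L
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != tss$chrom[i]) next
      if (peaks$start[j] <= tss$tss[i] + w && peaks$end[j] - 1 >= tss$tss[i] - w) {
        hit <- hit + 1L
      }
    }
    hit
  }, integer(1))
}
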