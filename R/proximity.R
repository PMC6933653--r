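#' Count regulatory-site peaks near each gene's TSS
#'
#' For each gene, counts peaks falling within `window` bases of its
#' transcription start site. The default rule counts a peak when its
#' interval overlaps any part of the closed window
#' \[tss - window, tss + window\] (so a peak starting exactly at
#' tss + window is counted); the alternative `"midpoint"` rule requires the
#' peak midpoint to lie inside the window. Peak intervals are BED 0-based
#' half-open; TSS positions are 0-based. Chromosome names are reconciled
#' across the two inputs by stripping a leading "chr" prefix when only one
#' side carries it. Counting is done with an interval index.
#'
#' @param peaks Peak tibble from [read_bed()] (`chrom`, `start`, `end`).
#' @param tss TSS tibble (`gene_id`, `chrom`, `tss`, `strand` optional).
#' @param window Half-width of the TSS window in bases.
#' @param rule Overlap rule: `"any_overlap"` (default) or `"midpoint"`.
#' @return A tibble: `gene_id`, `count`. Attribute `window` records the
#'   half-width; genes on chromosomes with no peaks get 0.
#' @export
count_peaks_near_tss <- function(peaks, tss, window = 20000,
                                 rule = c("any_overlap", "midpoint")) {
  rule <- match.arg(rule)
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss") %in% names(tss)))
  harmonised <- normalize_chroms(peaks$chrom, tss$chrom)
  pk_chrom <- harmonised$a
  ts_chrom <- harmonised$b
  if (rule == "midpoint") {
    mid <- floor((peaks$start + peaks$end) / 2)
    pk <- GenomicRanges::GRanges(pk_chrom, IRanges::IRanges(mid + 1, mid + 1))
  } else {
    pk <- GenomicRanges::GRanges(pk_chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  }
  win_start1 <- pmax(tss$tss - window, 0) + 1
  win_end1 <- tss$tss + window + 1
  win <- GenomicRanges::GRanges(ts_chrom, IRanges::IRanges(win_start1, win_end1))
  suppressWarnings(
    counts <- GenomicRanges::countOverlaps(win, pk)
  )
  out <- tibble(gene_id = tss$gene_id, count = as.integer(counts))
  attr(out, "window") <- window
  attr(out, "rule") <- rule
  out
}

# Reconcile "chr1" vs "1" dialects: if exactly one side uses the prefix,
# strip it from both.
normalize_chroms <- function(a, b) {
  has_a <- any(grepl("^chr", a))
  has_b <- any(grepl("^chr", b))
  if (has_a != has_b) {
    a <- sub("^chr", "", a)
    b <- sub("^chr", "", b)
  }
  list(a = a, b = b)
}

#' Compare peak counts across variation classes
#'
#' Pairwise Wilcoxon rank-sum tests of per-gene peak counts between the
#' variation classes (increased vs decreased, increased vs unchanged,
#' decreased vs unchanged), with per-class descriptive statistics. Genes
#' present in only one of the two inputs are ignored; an empty class skips
#' its comparisons.
#'
#' @param gpc Per-gene peak counts from [count_peaks_near_tss()].
#' @param vcs A `variation_calls` object (or tibble with `gene_id`, `label`).
#' @return A list with `tests` (tibble: group_1, group_2, statistic,
#'   p_value) and `class_stats` (tibble: label, n, mean_count, median_count).
#' @export
compare_class_counts <- function(gpc, vcs) {
  joined <- dplyr::inner_join(
    select(as_tibble(gpc), "gene_id", "count"),
    select(as_tibble(vcs), "gene_id", "label"),
    by = "gene_id"
  )
  class_stats <- joined %>%
    group_by(.data$label) %>%
    summarise(
      n = dplyr::n(),
      mean_count = mean(.data$count),
      median_count = median(.data$count),
      .groups = "drop"
    )
  pairs <- list(
    c("increased", "decreased"),
    c("increased", "unchanged"),
    c("decreased", "unchanged")
  )
  tests <- purrr::map_dfr(pairs, function(p) {
    x <- joined$count[joined$label == p[1]]
    y <- joined$count[joined$label == p[2]]
    if (!length(x) || !length(y)) {
      inform(paste0("class '", p[which(!c(length(x), length(y)))[1]],
                    "' is empty; comparison skipped"))
      return(tibble(group_1 = p[1], group_2 = p[2],
                    statistic = NA_real_, p_value = NA_real_))
    }
    wt <- wilcoxon_ranksum(x, y)
    tibble(group_1 = p[1], group_2 = p[2],
           statistic = wt$statistic, p_value = wt$p_value)
  })
  list(tests = tests, class_stats = class_stats)
}
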