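#' Build a 2x2 overlap contingency table
#'
#' Cross-tabulates membership of two gene sets within a declared universe:
#' `a` genes in both sets, `b` in A only, `c` in B only, `d` in neither.
#' Genes outside the universe are dropped from the sets and counted.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector of all genes under consideration.
#' @return A one-row tibble of class `overlap_table` with columns `a`, `b`,
#'   `c`, `d`, `n_universe`; attribute `n_dropped` records per-set counts of
#'   genes outside the universe.
#' @export
build_overlap_table <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("universe must be non-empty")
  a_in <- unique(set_a)
  b_in <- unique(set_b)
  dropped <- c(A = sum(!a_in %in% universe), B = sum(!b_in %in% universe))
  A <- intersect(a_in, universe)
  B <- intersect(b_in, universe)
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  cc <- length(setdiff(B, A))
  d <- length(universe) - a - b - cc
  out <- tibble(a = a, b = b, c = cc, d = d, n_universe = length(universe))
  class(out) <- c("overlap_table", class(out))
  attr(out, "n_dropped") <- dropped
  out
}

as_table_counts <- function(t) {
  if (inherits(t, "overlap_table") || (is.data.frame(t) && all(c("a", "b", "c", "d") %in% names(t)))) {
    c(a = t$a[1], b = t$b[1], c = t$c[1], d = t$d[1])
  } else if (is.numeric(t) && length(t) == 4) {
    setNames(as.numeric(t), c("a", "b", "c", "d"))
  } else {
    abort("expected an overlap_table or a numeric vector (a, b, c, d)")
  }
}

#' Pearson chi-square test of a 2x2 overlap table
#'
#' Computes the Pearson chi-square statistic with 1 degree of freedom for the
#' table and its p-value from the chi-square survival function, together with
#' the fold enrichment a*N / ((a+b)(a+c)) — the observed overlap relative to
#' the overlap expected under independence. No continuity correction by
#' default, the convention for large tables.
#'
#' @param t An `overlap_table` (or numeric vector a, b, c, d).
#' @param correction Apply the Yates continuity correction.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `fold_enrichment`,
#'   `method`.
#' @export
chi2_test <- function(t, correction = FALSE) {
  k <- as_table_counts(t)
  a <- k["a"]; b <- k["b"]; cc <- k["c"]; d <- k["d"]
  n <- sum(k)
  row1 <- a + b; row2 <- cc + d; col1 <- a + cc; col2 <- b + d
  if (any(c(row1, row2, col1, col2) == 0)) {
    abort("a table margin is zero; use fisher_exact() instead")
  }
  expected <- outer(c(row1, row2), c(col1, col2)) / n
  if (any(expected <= 0)) abort("all expected counts must be > 0")
  obs <- matrix(c(a, cc, b, d), 2)
  dev <- abs(obs - expected)
  if (correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  tibble(
    statistic = stat, df = 1,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    fold_enrichment = unname(a * n / (row1 * col1)),
    method = if (correction) "Pearson chi-square (Yates)" else "Pearson chi-square"
  )
}

#' Fisher exact test of a 2x2 overlap table
#'
#' Two-sided exact test summing, over tables with the observed margins, the
#' probabilities of all tables no more likely than the observed one. Serves
#' as the exact cross-check of [chi2_test()] on small or unbalanced tables.
#'
#' @param t An `overlap_table` (or numeric vector a, b, c, d).
#' @return A one-row tibble: `odds_ratio` (conditional MLE), `p_value`,
#'   `method`.
#' @export
fisher_exact <- function(t) {
  k <- as_table_counts(t)
  ht <- fisher.test(matrix(c(k["a"], k["c"], k["b"], k["d"]), 2))
  tibble(
    odds_ratio = unname(ht$estimate), p_value = ht$p.value,
    method = "Fisher exact (two-sided)"
  )
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term tests whether the query set overlaps the term's
#' gene set more than expected by chance: p = P(X >= k) for X hypergeometric
#' with the universe as population. Benjamini-Hochberg adjustment across
#' terms; results sorted by q. A generic stand-in for web-based functional
#' enrichment services.
#'
#' @param query Character vector of gene ids.
#' @param annotation Named list of character vectors (term -> gene set), e.g.
#'   from [read_gmt()].
#' @param universe Character vector of background gene ids.
#' @param alpha Significance threshold carried into the `significant` column.
#' @return A tibble: `term`, `n_term`, `n_query`, `overlap`, `expected`, `p`,
#'   `q`, `significant`. Terms whose gene set does not intersect the universe
#'   are skipped; their names are kept in attribute `skipped_terms`.
#' @export
hypergeometric_ora <- function(query, annotation, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) abort("universe must be non-empty")
  q_set <- intersect(unique(query), universe)
  sets <- lapply(annotation, function(g) intersect(unique(g), universe))
  skipped <- names(sets)[lengths(sets) == 0]
  sets <- sets[lengths(sets) > 0]
  N <- length(universe)
  n <- length(q_set)
  rows <- purrr::imap_dfr(sets, function(g, term) {
    K <- length(g)
    k <- length(intersect(q_set, g))
    tibble(
      term = term, n_term = K, n_query = n, overlap = k,
      expected = n * K / N,
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  rows$q <- benjamini_hochberg(rows$p)
  rows$significant <- rows$q <= alpha
  rows <- arrange(rows, .data$q, .data$p)
  attr(rows, "skipped_terms") <- skipped
  rows
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midrank ties. The p-value is exact (by
#' enumeration over rank assignments) when the combined sample size is at
#' most 12 and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for x vs y).
#' @return A one-row tibble: `statistic` (the Mann-Whitney U of `x`),
#'   `p_value`, `method`.
#' @export
wilcoxon_ranksum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n <= 12 && !ties
  ht <- suppressWarnings(wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE
  ))
  tibble(
    statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
    method = if (exact) "Wilcoxon rank-sum (exact)" else "Wilcoxon rank-sum (normal approximation)"
  )
}
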