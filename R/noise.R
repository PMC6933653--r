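#' Per-gene, per-condition expression noise and coefficient of variation
#'
#' For every gene and condition computes the mean, variance (n-1
#' denominator), expression noise eta^2 = sigma^2/mu^2 and coefficient of
#' variation CV = sigma/mu, on linear TPM by default. eta^2 equals CV^2 by
#' construction and is undefined (NA) for genes with zero mean in a
#' condition. The pooled mean of log2(TPM+1) across all retained cells is
#' attached per gene for the downstream low-expression cutoff.
#'
#' @param em An `expression_matrix` with condition labels in `em$cells`.
#' @param cv_on Scale on which mean/variance/CV are computed: linear `"tpm"`
#'   (default, the conventional CV) or `"log"` for log2(TPM+1).
#' @return A tibble of class `gene_noise_tbl`, one row per gene x condition:
#'   `gene_id`, `condition`, `mu`, `sigma2`, `eta2`, `cv`, `mean_log_expr`.
#' @export
gene_noise_stats <- function(em, cv_on = c("tpm", "log")) {
  stopifnot(inherits(em, "expression_matrix"))
  cv_on <- match.arg(cv_on)
  conds <- unique(em$cells$condition)
  n_per <- table(em$cells$condition)
  if (any(n_per < 2)) {
    abort(sprintf("condition '%s' has fewer than 2 cells", names(n_per)[n_per < 2][1]))
  }
  x <- if (cv_on == "tpm") em$tpm else em$log_expr
  mean_log <- rowMeans(em$log_expr)
  out <- purrr::map_dfr(conds, function(cn) {
    xc <- x[, em$cells$condition == cn, drop = FALSE]
    mu <- rowMeans(xc)
    sigma2 <- rowSums((xc - mu)^2) / (ncol(xc) - 1)
    eta2 <- ifelse(mu == 0, NA_real_, sigma2 / mu^2)
    tibble(
      gene_id = rownames(x), condition = cn,
      mu = unname(mu), sigma2 = unname(sigma2), eta2 = unname(eta2),
      cv = sqrt(unname(eta2)), mean_log_expr = unname(mean_log)
    )
  })
  class(out) <- c("gene_noise_tbl", class(out))
  attr(out, "cv_on") <- cv_on
  out
}

#' Binned noise-versus-expression profile
#'
#' Summarises the relationship between expression level and expression noise:
#' genes are split into `n_bins` equal-count bins of pooled mean log2(TPM+1),
#' and the mean noise per bin is reported per condition. Spearman
#' correlations between expression and noise are reported separately for
#' genes at or below and above the low-expression cutoff — for count data the
#' low-expression regime shows the 1/mu technical-noise scaling while noise
#' plateaus at the biological overdispersion above it.
#'
#' @param gnt A `gene_noise_tbl` from [gene_noise_stats()].
#' @param n_bins Number of equal-count expression bins.
#' @param cutoff Low-expression cutoff on the pooled mean log2(TPM+1) scale.
#' @return A list with `curve` (tibble: condition, bin, mean_log_expr,
#'   mean_eta2, n_genes) and `correlations` (tibble: condition, regime,
#'   spearman_rho, n_genes).
#' @export
noise_vs_expression_profile <- function(gnt, n_bins = 20, cutoff = 1.0) {
  stopifnot(inherits(gnt, "gene_noise_tbl"))
  if (dplyr::n_distinct(gnt$gene_id) < n_bins) abort("fewer genes than bins")
  dat <- gnt %>% filter(!is.na(.data$eta2))
  curve <- dat %>%
    group_by(.data$condition) %>%
    mutate(bin = dplyr::ntile(.data$mean_log_expr, n_bins)) %>%
    group_by(.data$condition, .data$bin) %>%
    summarise(
      mean_log_expr = mean(.data$mean_log_expr),
      mean_eta2 = mean(.data$eta2),
      n_genes = dplyr::n(), .groups = "drop"
    )
  correlations <- dat %>%
    mutate(regime = ifelse(.data$mean_log_expr > cutoff, "above_cutoff", "at_or_below_cutoff")) %>%
    group_by(.data$condition, .data$regime) %>%
    summarise(
      spearman_rho = if (dplyr::n() >= 3 && sd(.data$mean_log_expr) > 0 && sd(.data$eta2) > 0) {
        cor(.data$mean_log_expr, .data$eta2, method = "spearman")
      } else 0,
      n_genes = dplyr::n(), .groups = "drop"
    )
  list(curve = curve, correlations = correlations)
}

#' Low-expression gene filter for the noise analysis
#'
#' Retains genes whose pooled mean log2(TPM+1) across all retained cells
#' exceeds `cutoff` (strict `>`; genes at or below the cutoff are removed).
#' Low-expressed genes are dominated by the 1/mu sampling-noise regime, so
#' they are excluded before variability classification.
#'
#' @param gnt A `gene_noise_tbl`.
#' @param cutoff Cutoff on the pooled mean log2(TPM+1); default 1.
#' @return Character vector of retained gene ids.
#' @export
low_expression_filter <- function(gnt, cutoff = 1.0) {
  stopifnot(inherits(gnt, "gene_noise_tbl"))
  per_gene <- gnt %>% distinct(.data$gene_id, .data$mean_log_expr)
  keep <- per_gene$gene_id[per_gene$mean_log_expr > cutoff]
  if (!length(keep)) abort("low-expression filter removed every gene")
  keep
}

#' Classify variation-increased and variation-decreased genes
#'
#' The classifier statistic is the per-gene change in coefficient of
#' variation, delta CV = CV(alt) - CV(ref). A gene is labelled `increased`
#' when its delta CV exceeds mean(delta CV) + sd(delta CV), `decreased` when
#' it falls below mean(delta CV) - sd(delta CV) (strict inequalities, sample
#' sd with n-1 denominator), and `unchanged` otherwise. The mean and sd are
#' computed over exactly the supplied gene subset; by default that subset is
#' [low_expression_filter()] applied to `gnt`. Genes whose CV is undefined in
#' either condition (zero mean) are excluded before the thresholds are
#' computed and their count recorded.
#'
#' @param gnt A `gene_noise_tbl` covering both conditions.
#' @param genes Character vector of gene ids to classify; `NULL` applies
#'   [low_expression_filter()] at `cutoff`.
#' @param cutoff Low-expression cutoff used when `genes` is `NULL`.
#' @param ref,alt Condition labels: the reference (e.g. wild type) and the
#'   altered condition (e.g. knockdown).
#' @return A tibble of class `variation_calls`: `gene_id`, `cv_ref`,
#'   `cv_alt`, `delta_cv`, `label`. Attributes `mean_delta`, `sd_delta`,
#'   `ref`, `alt` and `n_dropped_undefined_cv` carry the thresholds and
#'   bookkeeping; see [glance.variation_calls()].
#' @export
classify_variation_change <- function(gnt, genes = NULL, cutoff = 1.0,
                                      ref = "WT", alt = "KD") {
  stopifnot(inherits(gnt, "gene_noise_tbl"))
  if (is.null(genes)) genes <- low_expression_filter(gnt, cutoff)
  missing_cond <- setdiff(c(ref, alt), unique(gnt$condition))
  if (length(missing_cond)) {
    abort(paste0("condition(s) not present in noise table: ", paste(missing_cond, collapse = ", ")))
  }
  wide <- gnt %>%
    filter(.data$condition %in% c(ref, alt), .data$gene_id %in% genes) %>%
    select("gene_id", "condition", "cv") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "cv") %>%
    rename(cv_ref = all_of(ref), cv_alt = all_of(alt))
  defined <- complete.cases(wide)
  n_dropped <- sum(!defined)
  wide <- wide[defined, , drop = FALSE]
  if (nrow(wide) < 3) abort("fewer than 3 genes with defined CV in both conditions")
  wide <- wide %>% mutate(delta_cv = .data$cv_alt - .data$cv_ref)
  m <- mean(wide$delta_cv)
  s <- sd(wide$delta_cv)
  wide <- wide %>% mutate(label = dplyr::case_when(
    .data$delta_cv > m + s ~ "increased",
    .data$delta_cv < m - s ~ "decreased",
    TRUE ~ "unchanged"
  ))
  class(wide) <- c("variation_calls", class(wide))
  attr(wide, "mean_delta") <- m
  attr(wide, "sd_delta") <- s
  attr(wide, "ref") <- ref
  attr(wide, "alt") <- alt
  attr(wide, "n_dropped_undefined_cv") <- n_dropped
  wide
}

#' @exportS3Method generics::glance
glance.variation_calls <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_increased = sum(x$label == "increased"),
    n_decreased = sum(x$label == "decreased"),
    n_unchanged = sum(x$label == "unchanged"),
    mean_delta = attr(x, "mean_delta"),
    sd_delta = attr(x, "sd_delta"),
    n_dropped_undefined_cv = attr(x, "n_dropped_undefined_cv")
  )
}

#' @exportS3Method generics::tidy
tidy.variation_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "variation_calls")
  out
}

#' Plot the CV change classification
#'
#' Scatter of CV in the altered condition against CV in the reference
#' condition, coloured by variation label, with the identity line.
#'
#' @param object A `variation_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.variation_calls <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$cv_ref, y = .data$cv_alt, colour = .data$label
  )) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      increased = "#c0392b", decreased = "#2980b9", unchanged = "grey60"
    )) +
    ggplot2::labs(
      x = paste0("CV (", attr(object, "ref"), ")"),
      y = paste0("CV (", attr(object, "alt"), ")"),
      colour = "variation"
    ) +
    ggplot2::theme_minimal()
}

#' Descriptive normality check of the delta-CV distribution
#'
#' Reports the sample skewness, excess kurtosis and a goodness-of-fit test of
#' delta CV against a fitted normal distribution: Shapiro-Wilk for up to 5000
#' values, otherwise a Kolmogorov-Smirnov test against the fitted normal.
#' Used descriptively — the classifier does not require normality, but the
#' mean +/- SD rule captures ~15.9% per tail only when delta CV is roughly
#' normal.
#'
#' @param x A `variation_calls` object or a numeric vector of delta-CV values.
#' @return A one-row tibble: `n`, `skewness`, `excess_kurtosis`, `statistic`,
#'   `p_value`, `method`, `degenerate`.
#' @export
normality_check <- function(x) {
  v <- if (inherits(x, "variation_calls")) x$delta_cv else as.numeric(x)
  if (length(v) < 20) abort("normality_check requires at least 20 values")
  s <- sd(v)
  if (s == 0) {
    return(tibble(
      n = length(v), skewness = NA_real_, excess_kurtosis = NA_real_,
      statistic = NA_real_, p_value = NA_real_,
      method = "none (constant input)", degenerate = TRUE
    ))
  }
  z <- v - mean(v)
  m2 <- mean(z^2)
  skew <- mean(z^3) / m2^1.5
  exkurt <- mean(z^4) / m2^2 - 3
  if (length(v) <= 5000) {
    ht <- shapiro.test(v)
    method <- "Shapiro-Wilk"
  } else {
    ht <- suppressWarnings(ks.test(v, "pnorm", mean = mean(v), sd = s))
    method <- "Kolmogorov-Smirnov vs fitted normal"
  }
  tibble(
    n = length(v), skewness = skew, excess_kurtosis = exkurt,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = method, degenerate = FALSE
  )
}
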