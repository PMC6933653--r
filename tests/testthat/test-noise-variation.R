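test_that("noise statistics match hand-computed moments and the eta2 = cv^2 identity", {
  tpm <- rbind(constant = c(2, 2, 2, 2), two_vals = c(1, 3, 1, 3))
  em <- em_from_tpm(tpm, c("WT", "WT", "KD", "KD"))
  gnt <- gene_noise_stats(em)
  const_wt <- dplyr::filter(gnt, gene_id == "constant", condition == "WT")
  expect_equal(const_wt$mu, 2)
  expect_equal(const_wt$sigma2, 0)
  expect_equal(const_wt$eta2, 0)
  expect_equal(const_wt$cv, 0)
  # {1,3}: mu = 2, sigma2 = 2 (n-1), eta2 = 0.5, cv = sqrt(0.5)
  tv <- dplyr::filter(gnt, gene_id == "two_vals", condition == "WT")
  expect_equal(tv$mu, 2)
  expect_equal(tv$sigma2, 2)
  expect_equal(tv$eta2, 0.5)
  expect_equal(tv$cv, sqrt(0.5))
  expect_equal(gnt$eta2, gnt$cv^2)
})

test_that("cv and eta2 are invariant to positive scaling; zero-mean genes are NA", {
  set.seed(31)
  tpm <- matrix(rpois(40, 10), 4, 10)
  em1 <- em_from_tpm(tpm, rep(c("WT", "KD"), 5))
  em2 <- em_from_tpm(tpm * 7.3, rep(c("WT", "KD"), 5))
  g1 <- gene_noise_stats(em1)
  g2 <- gene_noise_stats(em2)
  expect_equal(g1$cv, g2$cv, tolerance = 1e-12)
  expect_equal(g1$eta2, g2$eta2, tolerance = 1e-12)

  tpm0 <- rbind(zero_in_wt = c(0, 0, 5, 7), ok = c(1, 2, 3, 4))
  g0 <- gene_noise_stats(em_from_tpm(tpm0, c("WT", "WT", "KD", "KD")))
  expect_true(is.na(dplyr::filter(g0, gene_id == "zero_in_wt", condition == "WT")$eta2))
  expect_false(anyNA(dplyr::filter(g0, gene_id == "ok")$eta2))
  # a condition with fewer than 2 cells is an error
  expect_error(gene_noise_stats(em_from_tpm(tpm0, c("WT", "KD", "KD", "KD"))),
               "fewer than 2 cells")
})

test_that("noise-versus-expression has Poisson 1/mu scaling and an NB plateau", {
  # Poisson counts: eta2 = 1/mu, so log eta2 vs log mu has slope -1
  cfg <- sim_config(n_genes = 400, n_cells = 400, n_batches = 1, phi0 = 0,
                    fraction_de = 0, fraction_disp = 0, fraction_disp_down = 0,
                    mean_meanlog = log(5), mean_sdlog = 1.2, seed = 5)
  sim <- simulate_counts(cfg)
  gnt <- gene_noise_stats(tpm_normalize(sim$cm))
  wt <- dplyr::filter(gnt, condition == "WT", mu > 0, eta2 > 0)
  slope <- coef(lm(log(eta2) ~ log(mu), data = wt))[2]
  expect_equal(unname(slope), -1, tolerance = 0.1)

  # NB with phi = 0.5: eta2 = 1/mu + phi -> plateau near phi at high mean
  cfg2 <- sim_config(n_genes = 300, n_cells = 800, n_batches = 1, phi0 = 0.5,
                     fraction_de = 0, fraction_disp = 0, fraction_disp_down = 0,
                     mean_meanlog = log(100), mean_sdlog = 0.5, seed = 6)
  sim2 <- simulate_counts(cfg2)
  gnt2 <- gene_noise_stats(tpm_normalize(sim2$cm))
  high <- dplyr::filter(gnt2, condition == "WT", mu > quantile(mu, 0.5))
  expect_equal(mean(high$eta2), 0.5, tolerance = 0.07)

  prof <- noise_vs_expression_profile(gnt, n_bins = 10)
  expect_true(all(c("curve", "correlations") %in% names(prof)))
  # Poisson noise is 1/mu at every level: strong negative association
  pois_cor <- dplyr::filter(prof$correlations, condition == "WT",
                            regime == "above_cutoff")
  expect_lt(pois_cor$spearman_rho, -0.5)
  # NB at high mean: the plateau abolishes the association above the cutoff
  prof2 <- noise_vs_expression_profile(gnt2, n_bins = 10)
  nb_cor <- dplyr::filter(prof2$correlations, condition == "WT",
                          regime == "above_cutoff")
  expect_gt(nb_cor$spearman_rho, -0.5)
})

test_that("constant-expression genes give a flat noise profile with zero correlation", {
  tpm <- matrix(3, 25, 6, dimnames = list(paste0("g", 1:25), NULL))
  em <- em_from_tpm(tpm, rep(c("WT", "KD"), 3))
  prof <- noise_vs_expression_profile(gene_noise_stats(em), n_bins = 5)
  expect_true(all(prof$curve$mean_eta2 == 0))
  expect_true(all(prof$correlations$spearman_rho == 0))
})

test_that("low-expression filter removes genes at the cutoff and keeps those above", {
  # pooled mean log2(TPM+1) = 1 exactly <=> constant TPM of 1 -> removed
  tpm <- rbind(at_cutoff = rep(1, 4), just_above = rep(1.01, 4), high = rep(50, 4))
  gnt <- gene_noise_stats(em_from_tpm(tpm, c("WT", "WT", "KD", "KD")))
  kept <- low_expression_filter(gnt, cutoff = 1)
  expect_setequal(kept, c("just_above", "high"))
  expect_setequal(low_expression_filter(gnt, cutoff = -Inf), rownames(tpm))
})

test_that("classification reproduces hand-computed thresholds and symmetries", {
  make_gnt <- function(cv_wt, cv_kd) {
    n <- length(cv_wt)
    tibble_rows <- dplyr::bind_rows(
      tibble::tibble(gene_id = paste0("g", 1:n), condition = "WT",
                     mu = 10, sigma2 = (cv_wt * 10)^2, eta2 = cv_wt^2,
                     cv = cv_wt, mean_log_expr = 5),
      tibble::tibble(gene_id = paste0("g", 1:n), condition = "KD",
                     mu = 10, sigma2 = (cv_kd * 10)^2, eta2 = cv_kd^2,
                     cv = cv_kd, mean_log_expr = 5)
    )
    class(tibble_rows) <- c("gene_noise_tbl", class(tibble_rows))
    tibble_rows
  }
  # delta CV = {-3,-1,0,1,3}: mean 0, sd sqrt(5) ~ 2.236 -> only +-3 are called
  gnt <- make_gnt(rep(1, 5), 1 + c(-3, -1, 0, 1, 3))
  vcs <- classify_variation_change(gnt, genes = paste0("g", 1:5))
  expect_equal(attr(vcs, "mean_delta"), 0)
  expect_equal(attr(vcs, "sd_delta"), sqrt(5))
  expect_identical(vcs$label[match(paste0("g", 1:5), vcs$gene_id)],
                   c("decreased", "unchanged", "unchanged", "unchanged", "increased"))
  # identical delta for all genes: sd = 0, strict inequalities call nothing
  gnt_const <- make_gnt(rep(1, 5), rep(1.4, 5))
  vcs_const <- classify_variation_change(gnt_const, genes = paste0("g", 1:5))
  expect_true(all(vcs_const$label == "unchanged"))
  # negating every delta swaps increased and decreased exactly
  gnt_neg <- make_gnt(1 + c(-3, -1, 0, 1, 3), rep(1, 5))
  vcs_neg <- classify_variation_change(gnt_neg, genes = paste0("g", 1:5))
  expect_identical(
    vcs_neg$label[vcs$label == "increased"],
    rep("decreased", sum(vcs$label == "increased"))
  )
  expect_identical(
    vcs_neg$label[vcs$label == "decreased"],
    rep("increased", sum(vcs$label == "decreased"))
  )
  expect_error(classify_variation_change(gnt, genes = paste0("g", 1:2)),
               "fewer than 3")
})

test_that("classification equals an independent brute-force pass on random instances", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    cv_wt <- runif(n, 0.1, 2)
    cv_kd <- runif(n, 0.1, 2)
    gnt <- dplyr::bind_rows(
      tibble::tibble(gene_id = paste0("g", 1:n), condition = "WT",
                     mu = 10, sigma2 = 1, eta2 = cv_wt^2, cv = cv_wt,
                     mean_log_expr = 5),
      tibble::tibble(gene_id = paste0("g", 1:n), condition = "KD",
                     mu = 10, sigma2 = 1, eta2 = cv_kd^2, cv = cv_kd,
                     mean_log_expr = 5)
    )
    class(gnt) <- c("gene_noise_tbl", class(gnt))
    vcs <- classify_variation_change(gnt, genes = paste0("g", 1:n))
    expect_identical(vcs$label[match(paste0("g", 1:n), vcs$gene_id)],
                     brute_force_classify(cv_wt, cv_kd))
  }
})

test_that("dispersion-amplified genes rank above background in delta CV", {
  # genes with 4x dispersion in KD at decent expression should be enriched at
  # the top of the delta-CV ranking (rank-based enrichment p < 0.01)
  cfg <- sim_config(n_genes = 2000, n_cells = 25, n_batches = 2,
                    fraction_de = 0, fraction_disp = 0.05,
                    fraction_disp_down = 0, disp_fold = 4, coupling = 0,
                    mean_meanlog = log(40), mean_sdlog = 1, seed = 13)
  sim <- simulate_counts(cfg)
  em <- filter_genes_by_prevalence(tpm_normalize(sim$cm))
  gnt <- gene_noise_stats(em)
  vcs <- classify_variation_change(gnt)
  joined <- dplyr::inner_join(tidy(vcs), sim$truth, by = "gene_id")
  wt <- wilcoxon_ranksum(
    joined$delta_cv[joined$var_label == "var_up"],
    joined$delta_cv[joined$var_label == "none"],
    alternative = "greater"
  )
  expect_lt(wt$p_value, 0.01)
})

test_that("normality check recovers moments and flags degenerate input", {
  set.seed(41)
  nrm <- normality_check(rnorm(5000))
  expect_equal(nrm$skewness, 0, tolerance = 0.15)
  expect_equal(nrm$excess_kurtosis, 0, tolerance = 0.3)
  expo <- normality_check(rexp(2000))
  expect_gt(expo$skewness, 1)
  expect_lt(expo$p_value, 0.01)
  cst <- normality_check(rep(0.5, 50))
  expect_true(cst$degenerate)
  expect_error(normality_check(rnorm(5)), "at least 20")
})
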