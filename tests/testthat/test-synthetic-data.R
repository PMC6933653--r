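test_that("the simulator is deterministic under its seed and validates its config", {
  cfg <- sim_config(n_genes = 150, n_cells = 6, seed = 33)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$cm$counts, s2$cm$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(sim_config(n_genes = 150, n_cells = 6, seed = 34))
  expect_false(identical(s1$cm$counts, s3$cm$counts))
  expect_error(sim_config(fraction_de = 1.3), "fractions")
  expect_error(sim_config(n_cells = 1), "2 cells")
  expect_error(sim_config(mean_fold = -1), "folds")
  err <- tryCatch(sim_config(fraction_de = 2, disp_fold = 0), error = conditionMessage)
  expect_match(err, "fractions")
  expect_match(err, "folds")
})

test_that("NB moments follow var = mu + phi mu^2, with the Poisson limit at phi = 0", {
  # single high-mean gene, many cells: CV^2 ~ 1/mu + phi
  cfg <- sim_config(n_genes = 50, n_cells = 2000, n_batches = 1, phi0 = 0.5,
                    fraction_de = 0, fraction_disp = 0, fraction_disp_down = 0,
                    mean_meanlog = log(100), mean_sdlog = 0, seed = 44)
  sim <- simulate_counts(cfg)
  cv2 <- apply(sim$cm$counts, 1, function(v) var(v) / mean(v)^2)
  expect_equal(mean(cv2), 1 / 100 + 0.5, tolerance = 0.02)

  cfg_p <- sim_config(n_genes = 60, n_cells = 800, n_batches = 1, phi0 = 0,
                      fraction_de = 0, fraction_disp = 0, fraction_disp_down = 0,
                      mean_meanlog = log(50), mean_sdlog = 0.3, seed = 45)
  sim_p <- simulate_counts(cfg_p)
  vmr <- apply(sim_p$cm$counts, 1, function(v) var(v) / mean(v))
  expect_equal(mean(vmr), 1, tolerance = 0.03)
})

test_that("regressing sample CV^2 on 1/mean recovers slope 1 and intercept phi", {
  cfg <- sim_config(n_genes = 1000, n_cells = 2500, n_batches = 1, phi0 = 0.4,
                    fraction_de = 0, fraction_disp = 0, fraction_disp_down = 0,
                    mean_meanlog = log(20), mean_sdlog = 1, seed = 46)
  sim <- simulate_counts(cfg)
  mu <- rowMeans(sim$cm$counts)
  cv2 <- apply(sim$cm$counts, 1, var) / mu^2
  fit <- coef(lm(cv2 ~ I(1 / mu)))
  expect_equal(unname(fit[1]), 0.4, tolerance = 0.05)
  expect_equal(unname(fit[2]), 1, tolerance = 0.1)
})

test_that("truth labels are consistent with the generative parameters", {
  cfg <- sim_config(n_genes = 2000, n_cells = 4, coupling = 0.8, seed = 47)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  expect_true(all(tr$phi_kd[tr$var_label == "var_up"] ==
                    cfg$phi0 * cfg$disp_fold))
  expect_true(all(tr$phi_kd[tr$var_label == "var_down"] ==
                    cfg$phi0 / cfg$disp_fold))
  expect_true(all(tr$mu_kd[tr$de_label == "de_down"] <
                    tr$mu_wt[tr$de_label == "de_down"]))
  expect_true(all(tr$mu_kd[tr$de_label == "none"] == tr$mu_wt[tr$de_label == "none"]))
  # coupling: 80% of the dispersion-increased pool is mean-decreased
  vu <- tr[tr$var_label == "var_up", ]
  expect_equal(mean(vu$de_label == "de_down"), 0.8, tolerance = 0.01)
  # batch and condition bookkeeping
  expect_equal(as.vector(table(sim$cm$cells$condition)), c(8L, 8L))
  expect_equal(as.vector(table(sim$cm$cells$batch)), c(8L, 8L))
})

test_that("dropout thinning and batch multipliers act on the counts", {
  base <- sim_config(n_genes = 500, n_cells = 50, n_batches = 1, seed = 48,
                     fraction_de = 0, fraction_disp = 0, fraction_disp_down = 0)
  with_drop <- sim_config(n_genes = 500, n_cells = 50, n_batches = 1, seed = 48,
                          fraction_de = 0, fraction_disp = 0, fraction_disp_down = 0,
                          dropout = list(midpoint = 4, slope = 1))
  s0 <- simulate_counts(base)
  s1 <- simulate_counts(with_drop)
  expect_gt(sum(s1$cm$counts == 0), sum(s0$cm$counts == 0))

  bm <- sim_config(n_genes = 400, n_cells = 40, n_batches = 2, seed = 49,
                   fraction_de = 0, fraction_disp = 0, fraction_disp_down = 0,
                   batch_mult = c(1, 3))
  sb <- simulate_counts(bm)
  tot <- colSums(sb$cm$counts)
  expect_gt(mean(tot[sb$cm$cells$batch == "IFC2"]),
            2 * mean(tot[sb$cm$cells$batch == "IFC1"]))
})

test_that("synthetic annotation separates classes by construction and handles edge cases", {
  cfg <- sim_config(n_genes = 600, n_cells = 4, fraction_disp = 0.3,
                    fraction_disp_down = 0, coupling = 0, seed = 50)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotation(sim$truth, lambda_high = 3, lambda_low = 1, seed = 50)
  counts <- count_peaks_near_tss(ann$peaks, ann$tss, 20000)
  joined <- dplyr::inner_join(counts, sim$truth, by = "gene_id")
  m_up <- mean(joined$count[joined$var_label == "var_up"])
  m_other <- mean(joined$count[joined$var_label != "var_up"])
  expect_equal(m_up, 3, tolerance = 0.2)
  expect_equal(m_other, 1, tolerance = 0.2)
  # the BED round trip validates and the peak count equals the Poisson draws
  expect_true(all(ann$peaks$start < ann$peaks$end))
  expect_equal(sum(counts$count), nrow(ann$peaks))
  # null construction: equal rates leave classes indistinguishable
  ann0 <- simulate_annotation(sim$truth, lambda_high = 1, lambda_low = 1, seed = 51)
  c0 <- count_peaks_near_tss(ann0$peaks, ann0$tss, 20000)
  j0 <- dplyr::inner_join(c0, sim$truth, by = "gene_id")
  p0 <- wilcoxon_ranksum(j0$count[j0$var_label == "var_up"],
                         j0$count[j0$var_label != "var_up"])$p_value
  expect_gt(p0, 0.01)
  # zero peaks configured -> all counts zero
  annz <- simulate_annotation(sim$truth, lambda_high = 0, lambda_low = 0, seed = 52)
  expect_equal(nrow(annz$peaks), 0)
  cz <- count_peaks_near_tss(annz$peaks, annz$tss, 20000)
  expect_true(all(cz$count == 0))
})

test_that("written fixtures are re-readable by the package's own readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 120, n_cells = 5, seed = 53)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotation(sim$truth, seed = 53)
  paths <- write_fixtures(sim$cm, sim$truth, ann$peaks, ann$tss, dir, "mtx")
  back <- read_count_matrix(paths["counts"], paths["cells"])
  expect_identical(back$counts, sim$cm$counts)
  expect_identical(back$cells, sim$cm$cells)
  truth_back <- readr::read_tsv(paths["truth"], show_col_types = FALSE)
  expect_equal(nrow(truth_back), cfg$n_genes)
  peaks_back <- read_bed(paths["peaks"])
  expect_equal(nrow(peaks_back), nrow(ann$peaks))
  tss_back <- read_tss_table(paths["tss"])
  expect_equal(tss_back$tss, ann$tss$tss)
  lengths_back <- read_gene_lengths(paths["lengths"])
  expect_equal(lengths_back$length, as.numeric(sim$truth$length))
})

test_that("amplified-dispersion genes are recovered as variation-increased at study scale", {
  # genes with 4x dispersion and decent expression should be enriched in the
  # increased class; hypergeometric enrichment p < 0.01 in most replicates
  hits <- sapply(1:10, function(i) {
    cfg <- sim_config(n_genes = 2000, n_cells = 24, n_batches = 2,
                      fraction_de = 0, fraction_disp = 0.05,
                      fraction_disp_down = 0, disp_fold = 4, coupling = 0,
                      mean_meanlog = log(40), mean_sdlog = 1, seed = 700 + i)
    sim <- simulate_counts(cfg)
    em <- filter_genes_by_prevalence(tpm_normalize(sim$cm))
    vcs <- classify_variation_change(gene_noise_stats(em))
    joined <- dplyr::inner_join(tidy(vcs), sim$truth, by = "gene_id")
    strong <- joined$var_label == "var_up" & joined$mu_wt >= 20
    k <- sum(strong & joined$label == "increased")
    K <- sum(strong)
    n_inc <- sum(joined$label == "increased")
    N <- nrow(joined)
    phyper(k - 1, K, N - K, n_inc, lower.tail = FALSE) < 0.01
  })
  expect_gte(mean(hits), 0.8)
})
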