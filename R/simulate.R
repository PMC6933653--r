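#' Configuration for the two-condition negative-binomial simulator
#'
#' Defines the generative model used throughout the package's validation:
#' negative-binomial counts with per-gene, per-condition mean and dispersion,
#' emulating a full-length plate/microfluidics experiment with two conditions
#' (WT, KD) captured on two batches. Defaults reflect that design: 24 cells
#' per condition per batch (96 cells), 10,000 genes, log-normal baseline
#' means around 5 expected counts with a heavy tail, dispersion `phi0` = 0.3
#' in the `var = mu + phi mu^2` parameterisation (so CV^2 = 1/mu + phi),
#' no dropout and no batch effect.
#'
#' A `fraction_disp` share of genes has its dispersion multiplied by
#' `disp_fold` in KD (true variation-increased genes) and a
#' `fraction_disp_down` share divided by it (variation-decreased). The
#' `coupling` fraction of the dispersion-increased genes additionally has its
#' KD mean divided by `mean_fold` — the mean-decrease/dispersion-increase
#' coupling whose downstream signature is an overlap between down-regulated
#' and variation-increased genes. An independent `fraction_de` share of the
#' remaining genes gets a pure mean fold (half up, half down).
#'
#' @param n_genes Number of genes.
#' @param n_cells Cells per condition per batch.
#' @param n_batches Number of batches per condition.
#' @param conditions Condition labels (reference first).
#' @param seed Integer seed; the same config yields bit-identical output.
#' @param mean_meanlog,mean_sdlog Log-normal parameters of baseline expected
#'   counts.
#' @param phi0 Baseline NB dispersion (`var = mu + phi mu^2`).
#' @param fraction_de Fraction of genes with a pure mean change.
#' @param mean_fold Mean fold change for DE genes (> 1).
#' @param fraction_disp Fraction of genes with dispersion increased in KD.
#' @param fraction_disp_down Fraction with dispersion decreased in KD.
#' @param disp_fold Dispersion fold (> 1).
#' @param coupling Share of dispersion-increased genes that are also
#'   mean-decreased.
#' @param dropout `NULL` (off) or `list(midpoint=, slope=)`: each count is
#'   zeroed with probability `plogis(slope * (midpoint - log2(mu + 1)))`.
#' @param batch_mult Per-batch mean multipliers (length `n_batches`).
#' @param length_meanlog,length_sdlog Log-normal parameters of gene lengths.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000, n_cells = 24, n_batches = 2,
                       conditions = c("WT", "KD"), seed = 1L,
                       mean_meanlog = log(5), mean_sdlog = 1.8,
                       phi0 = 0.3,
                       fraction_de = 0.05, mean_fold = 4,
                       fraction_disp = 0.10, fraction_disp_down = fraction_disp,
                       disp_fold = 4, coupling = 0.5,
                       dropout = NULL, batch_mult = rep(1, n_batches),
                       length_meanlog = log(1500), length_sdlog = 0.5) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    n_batches = as.integer(n_batches), conditions = conditions,
    seed = as.integer(seed),
    mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog, phi0 = phi0,
    fraction_de = fraction_de, mean_fold = mean_fold,
    fraction_disp = fraction_disp, fraction_disp_down = fraction_disp_down,
    disp_fold = disp_fold, coupling = coupling,
    dropout = dropout, batch_mult = batch_mult,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog
  )
  problems <- character()
  fr <- c(cfg$fraction_de, cfg$fraction_disp, cfg$fraction_disp_down, cfg$coupling)
  if (any(fr < 0 | fr > 1)) problems <- c(problems, "fractions must lie in [0, 1]")
  if (cfg$fraction_disp + cfg$fraction_disp_down + cfg$fraction_de > 1) {
    problems <- c(problems, "fraction_de + fraction_disp + fraction_disp_down must be <= 1")
  }
  if (cfg$mean_fold <= 0 || cfg$disp_fold <= 0) problems <- c(problems, "folds must be > 0")
  if (cfg$phi0 < 0) problems <- c(problems, "phi0 must be >= 0")
  if (cfg$n_cells < 2) problems <- c(problems, "need at least 2 cells per condition")
  if (length(cfg$batch_mult) != cfg$n_batches) {
    problems <- c(problems, "batch_mult must have one entry per batch")
  }
  if (length(cfg$conditions) != 2) problems <- c(problems, "exactly 2 conditions required")
  if (length(problems)) abort(paste0("invalid sim_config: ", paste(problems, collapse = "; ")))
  structure(cfg, class = "sim_config")
}

#' Simulate a two-condition single-cell count matrix with known truth
#'
#' Draws counts gene by gene from the negative binomial defined by
#' [sim_config()], applies optional batch multipliers and dropout, and
#' returns both the count matrix and the generative truth table for recovery
#' testing. Deterministic under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list: `cm` (a [count_matrix()]) and `truth` (tibble per gene:
#'   `gene_id`, `mu_wt`, `mu_kd`, `phi_wt`, `phi_kd`, `de_label`,
#'   `var_label`, `length`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  mu0 <- rlnorm(ng, cfg$mean_meanlog, cfg$mean_sdlog)
  lengths <- round(rlnorm(ng, cfg$length_meanlog, cfg$length_sdlog))

  # assign truth labels
  idx <- sample.int(ng)
  n_vu <- round(cfg$fraction_disp * ng)
  n_vd <- round(cfg$fraction_disp_down * ng)
  n_de <- round(cfg$fraction_de * ng)
  var_up <- idx[seq_len(n_vu)]
  var_down <- idx[n_vu + seq_len(n_vd)]
  de_extra <- idx[n_vu + n_vd + seq_len(n_de)]

  de_label <- rep("none", ng)
  var_label <- rep("none", ng)
  var_label[var_up] <- "var_up"
  var_label[var_down] <- "var_down"
  n_coupled <- round(cfg$coupling * n_vu)
  coupled <- var_up[seq_len(n_coupled)]
  de_label[coupled] <- "de_down"
  half <- floor(n_de / 2)
  de_label[de_extra[seq_len(half)]] <- "de_up"
  if (n_de > half) de_label[de_extra[(half + 1):n_de]] <- "de_down"

  mu_wt <- mu0
  mu_kd <- mu0
  mu_kd[de_label == "de_up"] <- mu0[de_label == "de_up"] * cfg$mean_fold
  mu_kd[de_label == "de_down"] <- mu0[de_label == "de_down"] / cfg$mean_fold
  phi_wt <- rep(cfg$phi0, ng)
  phi_kd <- rep(cfg$phi0, ng)
  phi_kd[var_label == "var_up"] <- cfg$phi0 * cfg$disp_fold
  phi_kd[var_label == "var_down"] <- cfg$phi0 / cfg$disp_fold

  n_per_cond <- cfg$n_cells * cfg$n_batches
  batch_of <- rep(seq_len(cfg$n_batches), each = cfg$n_cells)
  # per-gene dispersion; draws vectorised over the gene x cell block
  counts <- matrix(0L, ng, 2 * n_per_cond)
  for (ci in 1:2) {
    mu_c <- if (ci == 1) mu_wt else mu_kd
    phi_c <- if (ci == 1) phi_wt else phi_kd
    offset <- (ci - 1) * n_per_cond
    for (b in seq_len(cfg$n_batches)) {
      cols <- offset + which(batch_of == b)
      mu_b <- mu_c * cfg$batch_mult[b]
      if (cfg$phi0 == 0 && cfg$disp_fold == 1) {
        block <- rpois(ng * length(cols), rep(mu_b, times = length(cols)))
      } else {
        block <- rnbinom(ng * length(cols),
                         size = rep(1 / pmax(phi_c, 1e-12), times = length(cols)),
                         mu = rep(mu_b, times = length(cols)))
        pois <- phi_c == 0
        if (any(pois)) {
          bm <- matrix(block, ng, length(cols))
          bm[pois, ] <- rpois(sum(pois) * length(cols), rep(mu_b[pois], times = length(cols)))
          block <- as.vector(bm)
        }
      }
      counts[, cols] <- matrix(as.integer(block), ng, length(cols))
    }
  }

  if (!is.null(cfg$dropout)) {
    p_drop <- stats::plogis(cfg$dropout$slope * (cfg$dropout$midpoint - log2(mu0 + 1)))
    keep <- matrix(
      rbinom(length(counts), 1, rep(1 - p_drop, times = ncol(counts))),
      nrow(counts), ncol(counts)
    )
    counts <- counts * keep
  }

  cond_of <- rep(cfg$conditions, each = n_per_cond)
  batch_all <- rep(paste0("IFC", batch_of), times = 2)
  cell_ids <- sprintf("cell_%s_%s_%03d", cond_of, batch_all,
                      rep(seq_len(n_per_cond), times = 2))
  dimnames(counts) <- list(gene_ids, cell_ids)
  cm <- count_matrix(counts, tibble(
    cell_id = cell_ids, condition = cond_of, batch = batch_all
  ))
  truth <- tibble(
    gene_id = gene_ids,
    mu_wt = mu_wt, mu_kd = mu_kd, phi_wt = phi_wt, phi_kd = phi_kd,
    de_label = de_label, var_label = var_label,
    length = lengths
  )
  list(cm = cm, truth = truth)
}

#' Simulate peak and TSS annotation tied to the ground truth
#'
#' Lays the simulated genes along one synthetic chromosome with TSSs spaced
#' so their windows never overlap, then scatters peaks: true
#' variation-increased genes receive Poisson(`lambda_high`) peaks inside
#' their TSS window, all other genes Poisson(`lambda_low`). Peak start
#' positions are uniform within the window, so the per-gene peak count
#' recovered by [count_peaks_near_tss()] is exactly the Poisson draw.
#'
#' @param truth Truth tibble from [simulate_counts()].
#' @param lambda_high,lambda_low Expected peak counts per gene for
#'   variation-increased vs other genes.
#' @param window TSS window half-width the layout respects.
#' @param peak_width Peak interval width in bases.
#' @param seed Integer seed.
#' @return A list: `peaks` (BED-style tibble) and `tss` (TSS tibble).
#' @export
simulate_annotation <- function(truth, lambda_high = 3, lambda_low = 1,
                                window = 20000, peak_width = 200, seed = 1L) {
  set.seed(seed)
  ng <- nrow(truth)
  spacing <- 2 * window + peak_width + 1000
  tss_pos <- window + spacing * (seq_len(ng) - 1)
  tss <- tibble(
    gene_id = truth$gene_id, chrom = "chrS", tss = tss_pos,
    strand = rep(c("+", "-"), length.out = ng)
  )
  lam <- ifelse(truth$var_label == "var_up", lambda_high, lambda_low)
  n_peaks <- rpois(ng, lam)
  starts <- unlist(lapply(seq_len(ng), function(i) {
    if (n_peaks[i] == 0) return(numeric(0))
    floor(runif(n_peaks[i], max(tss_pos[i] - window, 0), tss_pos[i] + window))
  }))
  peaks <- tibble(
    chrom = "chrS",
    start = starts,
    end = starts + peak_width,
    name = paste0("peak", seq_along(starts))
  )
  list(peaks = peaks, tss = tss)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Writes the count matrix (MTX with sidecars, or TSV), cell metadata, truth
#' table, gene lengths, peaks (BED) and TSS table (TSV) into a directory, in
#' the formats the package's own readers consume.
#'
#' @param cm A [count_matrix()].
#' @param truth Truth tibble.
#' @param peaks,tss Annotation tibbles from [simulate_annotation()] (optional).
#' @param outdir Output directory (created if absent).
#' @param format Matrix format, `"mtx"` or `"tsv"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixtures <- function(cm, truth, peaks = NULL, tss = NULL, outdir,
                           format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mat_path <- file.path(outdir, if (format == "mtx") "counts.mtx" else "counts.tsv")
  meta_path <- file.path(outdir, "cells.tsv")
  write_count_matrix(cm, mat_path, meta_path, format)
  truth_path <- file.path(outdir, "truth.tsv")
  readr::write_tsv(truth, truth_path)
  len_path <- file.path(outdir, "gene_lengths.tsv")
  readr::write_tsv(select(truth, "gene_id", "length"), len_path)
  paths <- c(counts = mat_path, cells = meta_path, truth = truth_path,
             lengths = len_path)
  if (!is.null(peaks)) {
    bed_path <- file.path(outdir, "peaks.bed")
    readr::write_tsv(peaks, bed_path, col_names = FALSE)
    paths["peaks"] <- bed_path
  }
  if (!is.null(tss)) {
    tss_path <- file.path(outdir, "tss.tsv")
    readr::write_tsv(tss, tss_path)
    paths["tss"] <- tss_path
  }
  invisible(paths)
}
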