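#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with its
#' standard default: the 3000-detected-gene cell filter, the
#' log2(TPM+1) > 1 in >= 2 cells gene filter, the low-expression cutoff of 1
#' for the noise analysis, the 20 kb TSS window, and alpha = 0.05 for the DE
#' stand-in. Input is either a [sim_config()] (synthetic run) or a list of
#' file paths (`counts`, `cells`, optionally `lengths`, `de_table`, `peaks`,
#' `tss`).
#'
#' @param input A `sim_config`, or a named list of input paths.
#' @param min_genes Cell filter threshold.
#' @param prevalence_level,prevalence_min_cells Gene prevalence filter.
#' @param low_expr_cutoff Low-expression cutoff for the noise analysis.
#' @param cv_on CV scale, `"tpm"` or `"log"`.
#' @param de_alpha DE significance threshold.
#' @param ref,alt Condition labels.
#' @param tss_window TSS window half-width (bases).
#' @param n_pcs Number of principal components.
#' @param scale_genes Unit-scale genes before PCA.
#' @param outdir Optional output directory for stage TSVs and the JSON report.
#' @param seed Seed for any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, min_genes = 3000,
                            prevalence_level = 1.0, prevalence_min_cells = 2L,
                            low_expr_cutoff = 1.0, cv_on = "tpm",
                            de_alpha = 0.05, ref = "WT", alt = "KD",
                            tss_window = 20000, n_pcs = 10,
                            scale_genes = FALSE, outdir = NULL, seed = 1L) {
  structure(
    list(
      input = input, min_genes = min_genes,
      prevalence_level = prevalence_level,
      prevalence_min_cells = prevalence_min_cells,
      low_expr_cutoff = low_expr_cutoff, cv_on = cv_on,
      de_alpha = de_alpha, ref = ref, alt = alt,
      tss_window = tss_window, n_pcs = n_pcs,
      scale_genes = scale_genes, outdir = outdir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full variability pipeline
#'
#' Executes QC -> TPM -> noise/CV -> variation classification -> differential
#' expression -> overlap enrichment -> PCA -> (optional) peak proximity and
#' returns a structured report. Stage outputs and the report (JSON) are
#' written when `cfg$outdir` is set. On synthetic input the generative truth
#' is carried into the report for recovery summaries.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_report`; see the fields in the value of
#'   each stage: `dims`, `variation` (glance), `de` (glance), `overlap`
#'   (tables + tests), `pca` (separation tests), `proximity` (or "skipped"),
#'   `config_echo`, `seed`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "input"
  report <- list(seed = cfg$seed,
                 config_echo = cfg[setdiff(names(cfg), c("input", "outdir"))])
  result <- try({
    truth <- NULL
    peaks <- NULL
    tss <- NULL
    if (inherits(cfg$input, "sim_config")) {
      sim <- simulate_counts(cfg$input)
      cm <- sim$cm
      truth <- sim$truth
      lengths <- select(truth, "gene_id", "length")
      ann <- simulate_annotation(truth, seed = cfg$input$seed)
      peaks <- ann$peaks
      tss <- ann$tss
    } else {
      cm <- read_count_matrix(cfg$input$counts, cfg$input$cells)
      lengths <- if (!is.null(cfg$input$lengths)) read_gene_lengths(cfg$input$lengths) else NULL
      if (!is.null(cfg$input$peaks)) peaks <- read_bed(cfg$input$peaks)
      if (!is.null(cfg$input$tss)) tss <- read_tss_table(cfg$input$tss)
    }
    dims <- list(input = dim(cm))

    stage <- "cell_qc"
    cm <- filter_cells_by_detected_genes(cm, cfg$min_genes)
    dims$after_cell_qc <- dim(cm)

    stage <- "tpm"
    em <- tpm_normalize(cm, lengths)

    stage <- "gene_prevalence"
    em <- filter_genes_by_prevalence(em, cfg$prevalence_level, cfg$prevalence_min_cells)
    dims$after_gene_prevalence <- dim(em)

    stage <- "noise"
    gnt <- gene_noise_stats(em, cv_on = cfg$cv_on)
    kept <- low_expression_filter(gnt, cfg$low_expr_cutoff)
    dims$genes_passing_low_expression <- length(kept)

    stage <- "classify"
    vcs <- classify_variation_change(gnt, genes = kept, ref = cfg$ref, alt = cfg$alt)

    stage <- "differential_expression"
    de <- if (!inherits(cfg$input, "sim_config") && !is.null(cfg$input$de_table)) {
      import_de_results(cfg$input$de_table, cfg$de_alpha)
    } else {
      simple_de_test(em, cfg$de_alpha, ref = cfg$ref, alt = cfg$alt)
    }

    stage <- "overlap_enrichment"
    universe <- vcs$gene_id
    down_inc <- build_overlap_table(
      de$gene_id[de$label == "down"],
      vcs$gene_id[vcs$label == "increased"], universe
    )
    up_dec <- build_overlap_table(
      de$gene_id[de$label == "up"],
      vcs$gene_id[vcs$label == "decreased"], universe
    )
    overlap <- list(
      down_vs_increased = list(
        table = as_tibble(down_inc),
        chi2 = if (all(c(down_inc$a + down_inc$b, down_inc$a + down_inc$c) > 0) &&
                   all(c(down_inc$c + down_inc$d, down_inc$b + down_inc$d) > 0)) {
          chi2_test(down_inc)
        } else fisher_exact(down_inc),
        fisher = fisher_exact(down_inc)
      ),
      up_vs_decreased = list(
        table = as_tibble(up_dec),
        chi2 = if (all(c(up_dec$a + up_dec$b, up_dec$a + up_dec$c) > 0) &&
                   all(c(up_dec$c + up_dec$d, up_dec$b + up_dec$d) > 0)) {
          chi2_test(up_dec)
        } else fisher_exact(up_dec),
        fisher = fisher_exact(up_dec)
      )
    )

    stage <- "pca"
    pca <- pca_embed(em, n_pcs = cfg$n_pcs, scale_genes = cfg$scale_genes)
    pca_tests <- list(
      condition_pc1 = separation_test(pca, "condition", pc = 1),
      batch_pc1 = if (dplyr::n_distinct(em$cells$batch) == 2) {
        separation_test(pca, "batch", pc = 1)
      } else NULL
    )

    stage <- "peak_proximity"
    proximity <- if (!is.null(peaks) && !is.null(tss)) {
      gpc <- count_peaks_near_tss(peaks, tss, window = cfg$tss_window)
      compare_class_counts(gpc, vcs)
    } else "skipped"

    vg <- glance(vcs)
    stopifnot(vg$n_increased + vg$n_decreased + vg$n_unchanged == vg$n_genes)

    report$dims <- dims
    report$variation <- vg
    report$de <- glance(de)
    report$overlap <- overlap
    report$pca <- pca_tests
    report$proximity <- proximity
    report$objects <- list(em = em, gnt = gnt, vcs = vcs, de = de, pca = pca,
                           truth = truth)
    report
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    report$failed_stage <- stage
    if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 attr(result, "condition")$message))
  }
  report <- result
  class(report) <- "pipeline_report"
  if (!is.null(cfg$outdir)) {
    write_report(report, cfg$outdir)
    readr::write_tsv(tidy(report$objects$vcs), file.path(cfg$outdir, "variation_calls.tsv"))
    readr::write_tsv(tidy(report$objects$de), file.path(cfg$outdir, "de_results.tsv"))
    readr::write_tsv(report$objects$gnt, file.path(cfg$outdir, "gene_noise.tsv"))
  }
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  slim <- report[setdiff(names(report), "objects")]
  jsonlite::write_json(
    slim, file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null"
  )
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  d <- x$dims
  cat(sprintf("  cells: %d -> %d after QC; genes: %d -> %d after prevalence, %d past low-expression cutoff\n",
              d$input[2], d$after_cell_qc[2], d$input[1],
              d$after_gene_prevalence[1], d$genes_passing_low_expression))
  cat(sprintf("  variation: %d increased / %d decreased / %d unchanged\n",
              x$variation$n_increased, x$variation$n_decreased, x$variation$n_unchanged))
  cat(sprintf("  DE: %d up / %d down (alpha = %g)\n",
              x$de$n_up, x$de$n_down, x$de$alpha))
  cat(sprintf("  down & increased overlap: a = %d, chi2 p = %.3g\n",
              x$overlap$down_vs_increased$table$a,
              x$overlap$down_vs_increased$chi2$p_value))
  cat(sprintf("  PC1 condition separation p = %.3g\n",
              x$pca$condition_pc1$p_value))
  if (!identical(x$proximity, "skipped")) {
    cat("  peak proximity: computed\n")
  } else cat("  peak proximity: skipped\n")
  invisible(x)
}
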