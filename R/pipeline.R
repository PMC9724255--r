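#' Pipeline configuration
#'
#' Bundles every threshold of the marker-discovery and risk-classification
#' pipeline with the synthetic-cohort and chromatogram settings. All
#' printed study constants live here as defaults — none is hard-coded in
#' stage logic: probe call-proportion threshold 0.90, |delta beta| gate
#' 0.1, trend alpha 0.05, stage-1 AUC minimum 0.95, stage-2 specificity
#' minimum 0.85 and the 2-of-n composite rule.
#'
#' @param cohort A [cohort_config()] for the simulated cohort.
#' @param call_threshold Probe detection call-proportion threshold.
#' @param exclude_chromosomes Chromosomes removed before testing.
#' @param alpha_mode `"family"` (0.05 / number of probes tested after QC)
#'   or `"fixed"` (use `alpha_fixed` as the per-test threshold).
#' @param alpha_fixed Explicit per-test alpha used when
#'   `alpha_mode = "fixed"`.
#' @param delta_threshold Minimum |delta beta|.
#' @param stage_order Ordered groups for the trend test.
#' @param trend_alpha One-sided trend-test alpha.
#' @param auc_min,spec_min Panel-selection thresholds.
#' @param k Composite-rule minimum positive markers.
#' @param max_hplc_markers At most this many panel markers (highest AUC
#'   first) are carried into chromatogram quantification.
#' @param hplc A [chrom_spec()] for simulated chromatograms.
#' @param out_dir Optional directory for stage artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            call_threshold = 0.90,
                            exclude_chromosomes = c("X", "Y"),
                            alpha_mode = c("family", "fixed"),
                            alpha_fixed = 1.12e-7,
                            delta_threshold = 0.1,
                            stage_order = c("NLT", "NASH-W", "T"),
                            trend_alpha = 0.05,
                            auc_min = 0.95,
                            spec_min = 0.85,
                            k = 2,
                            max_hplc_markers = 3,
                            hplc = chrom_spec(noise_sd = 0.002),
                            out_dir = NULL) {
  alpha_mode <- match.arg(alpha_mode)
  check_fraction(call_threshold, "call_threshold")
  check_number(alpha_fixed, "alpha_fixed", lower = 1e-300, upper = 1)
  check_number(delta_threshold, "delta_threshold", lower = 1e-12, upper = 1)
  check_fraction(trend_alpha, "trend_alpha")
  check_fraction(auc_min, "auc_min")
  check_fraction(spec_min, "spec_min")
  check_number(k, "k", lower = 1)
  structure(list(cohort = cohort, call_threshold = call_threshold,
                 exclude_chromosomes = exclude_chromosomes,
                 alpha_mode = alpha_mode, alpha_fixed = alpha_fixed,
                 delta_threshold = delta_threshold,
                 stage_order = stage_order, trend_alpha = trend_alpha,
                 auc_min = auc_min, spec_min = spec_min, k = as.integer(k),
                 max_hplc_markers = as.integer(max_hplc_markers),
                 hplc = hplc, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full discovery-to-classification pipeline
#'
#' Executes, in order: cohort simulation, probe QC filtering, the
#' genome-wide Welch screen with Bonferroni and effect-size gates, the
#' stage-trend filter, two-stage marker-panel selection, simulation and
#' quantification of an HPLC run for the selected markers (sample rates
#' taken from the samples' own beta values, scaled to percent), and the
#' composite k-of-n risk call with cohort performance. When `out_dir` is
#' set, each stage's artifact is written along with a JSON run manifest
#' recording seeds, parameters and the per-stage probe counts.
#'
#' @param config A [pipeline_config()].
#' @return List of class `methrisk_pipeline`: `cohort`, `filter`, `screen`,
#'   `differential`, `trend`, `panel`, `rates`, `calls`, `performance`,
#'   `counts` (the probe cascade), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_beta_cohort(config$cohort)
  ann <- cohort$annotation

  pf <- filter_probes(cohort$beta, cohort$manifest,
                      call_threshold = config$call_threshold,
                      exclude_chromosomes = config$exclude_chromosomes)
  ws <- welch_screen(pf$beta, ann, group_a = "NLT", group_b = "NASH-W")
  alpha_family <- if (config$alpha_mode == "family") {
    bonferroni_alpha(nrow(pf$beta))
  } else {
    config$alpha_fixed
  }
  diff_set <- bonferroni_select(ws, alpha_family,
                                delta_threshold = config$delta_threshold)
  trend <- trend_inherited_set(diff_set, pf$beta, ann,
                               stage_order = config$stage_order,
                               alpha = config$trend_alpha)
  panel <- select_panel(trend, pf$beta, ann,
                        auc_threshold = config$auc_min,
                        specificity_threshold = config$spec_min)

  rates <- calls <- perf <- NULL
  hplc_markers <- character(0)
  if (nrow(panel$entries) >= config$k) {
    ord <- order(panel$entries$auc, decreasing = TRUE)
    hplc_markers <- utils::head(panel$entries$marker_id[ord],
                                config$max_hplc_markers)
    eval_groups <- intersect(c("NLT", "NAFL-W", "NASH-W"), ann$group)
    eval_samples <- ann$sample_id[ann$group %in% eval_groups]
    true_rates <- 100 * t(cohort$beta[hplc_markers, eval_samples,
                                      drop = FALSE])
    run <- simulate_hplc_run(hplc_markers, true_rates, config$hplc)
    rates <- quantify_run(run)
    sub_entries <- panel$entries[panel$entries$marker_id %in% hplc_markers, ]
    sub_panel <- marker_panel(sub_entries, panel$selection_params)
    calls <- classify_cohort(rates, sub_panel,
                             k = min(config$k, nrow(sub_entries)),
                             cutoff_scale = 100)
    perf <- cohort_performance(calls, ann,
                               case_groups = intersect(c("NAFL-W", "NASH-W"),
                                                       ann$group),
                               control_groups = "NLT")
  }

  counts <- c(probes_input = pf$summary$n_input,
              probes_retained = pf$summary$n_retained,
              probes_differential = nrow(diff_set),
              probes_trend = nrow(trend),
              probes_auc_stage = panel$selection_params$n_stage1,
              panel_markers = nrow(panel$entries),
              hplc_markers = length(hplc_markers))
  out <- structure(list(cohort = cohort, filter = pf, screen = ws,
                        differential = diff_set, trend = trend,
                        panel = panel, rates = rates, calls = calls,
                        performance = perf, counts = counts,
                        alpha_family = alpha_family, config = config),
                   class = "methrisk_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_bundle(out, config$out_dir)
  out
}

write_pipeline_bundle <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(res$cohort$beta, file.path(dir, "beta.tsv"))
  write_manifest(res$cohort$manifest, file.path(dir, "manifest.csv"))
  write_annotation(res$cohort$annotation, file.path(dir, "annotation.csv"))
  utils::write.table(res$screen, file.path(dir, "screen.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_panel(res$panel, file.path(dir, "panel.json"))
  if (!is.null(res$rates)) {
    write_rates(res$rates, file.path(dir, "rates.tsv"))
    utils::write.table(res$calls, file.path(dir, "calls.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    seed = res$config$cohort$seed,
    hplc_seed = res$config$hplc$seed,
    alpha_mode = res$config$alpha_mode,
    alpha_family = res$alpha_family,
    parameters = list(call_threshold = res$config$call_threshold,
                      delta_threshold = res$config$delta_threshold,
                      trend_alpha = res$config$trend_alpha,
                      auc_min = res$config$auc_min,
                      spec_min = res$config$spec_min,
                      k = res$config$k),
    counts = as.list(res$counts))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.methrisk_pipeline <- function(x, ...) {
  cat("Methylation risk pipeline\n")
  cat("  probe cascade:",
      paste(sprintf("%s=%s", names(x$counts), x$counts), collapse = ", "),
      "\n")
  if (!is.null(x$performance)) {
    cat(sprintf("  composite call: sensitivity %.1f%%, specificity %.1f%%\n",
                100 * x$performance$sensitivity,
                100 * x$performance$specificity))
  }
  invisible(x)
}
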