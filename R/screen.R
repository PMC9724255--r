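#' Probe quality filtering
#'
#' Removes probes whose detection call proportion falls below a threshold
#' (low call proportions are typically attributable to polymorphism at the
#' probe CpG) and probes on excluded chromosomes (X/Y by default, avoiding
#' sex-specific methylation bias). Probe order is preserved and per-rule
#' removal counts, including their overlap, are reported.
#'
#' @param beta Numeric matrix, probes x samples, rownames = probe ids.
#' @param manifest Data frame with columns `probe_id`, `chromosome`,
#'   `call_proportion`, covering every probe in `beta`.
#' @param call_threshold Probes with call_proportion below this are removed
#'   (default 0.90).
#' @param exclude_chromosomes Chromosome labels to drop, matched
#'   case-insensitively (default X and Y).
#' @return List of class `probe_filter`: `beta`, `manifest` (both filtered),
#'   and `summary` with `n_input`, `n_lowcall`, `n_excluded_chrom`,
#'   `n_overlap`, `n_retained`.
#' @export
#' @examples
#' co <- simulate_beta_cohort(cohort_config(n_probes = 300, seed = 2))
#' pf <- filter_probes(co$beta, co$manifest)
#' pf$summary
filter_probes <- function(beta, manifest, call_threshold = 0.90,
                          exclude_chromosomes = c("X", "Y")) {
  check_number(call_threshold, "call_threshold", lower = 1e-9, upper = 1)
  if (anyDuplicated(rownames(beta))) stop_config("duplicate probe ids")
  if (anyDuplicated(colnames(beta))) stop_config("duplicate sample ids")
  m <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
  if (anyNA(m$probe_id)) stop_config("manifest does not cover every probe")
  low <- m$call_proportion < call_threshold
  sexchr <- toupper(m$chromosome) %in% toupper(exclude_chromosomes)
  keep <- !(low | sexchr)
  if (!any(keep)) warning("no probes retained after filtering")
  structure(list(
    beta = beta[keep, , drop = FALSE],
    manifest = m[keep, , drop = FALSE],
    summary = list(n_input = nrow(beta),
                   n_lowcall = sum(low),
                   n_excluded_chrom = sum(sexchr),
                   n_overlap = sum(low & sexchr),
                   n_retained = sum(keep))
  ), class = "probe_filter")
}

#' @export
print.probe_filter <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Probe filter: %d input, %d low-call, %d on excluded",
                     " chromosomes (%d overlap), %d retained\n"),
              s$n_input, s$n_lowcall, s$n_excluded_chrom, s$n_overlap,
              s$n_retained))
  invisible(x)
}

#' Welch's unequal-variance t test for one probe
#'
#' Two-sided Welch t test with Welch-Satterthwaite degrees of freedom. The
#' methylation difference is reported as `delta_beta = mean_b - mean_a`.
#' Degenerate inputs (zero variance in both groups) give t = 0, p = 1 when
#' means are equal and p = 0 with a `degenerate` flag when they differ.
#'
#' @param values_a,values_b Numeric vectors (>= 2 non-missing values each).
#' @return List: `mean_a`, `mean_b`, `delta_beta`, `t_stat`, `df`, `p_value`,
#'   `degenerate`.
#' @export
welch_test <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_config("each group needs >= 2 non-missing values")
  }
  res <- welch_rows(matrix(a, 1), matrix(b, 1))
  c(as.list(res[1, ]), list(degenerate = attr(res, "degenerate")[1]))
}

# Row-wise Welch statistics for a probes x samples split; the vectorised
# core shared by welch_test() and welch_screen().
welch_rows <- function(xa, xb) {
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- rowSums((xa - ma)^2, na.rm = TRUE) / (na - 1)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  tt[degen] <- 0
  p[degen & (ma == mb)] <- 1
  p[degen & (ma != mb)] <- 0
  out <- cbind(mean_a = ma, mean_b = mb, delta_beta = mb - ma,
               t_stat = tt, df = df, p_value = p)
  attr(out, "degenerate") <- degen
  out
}

#' Genome-wide Welch screen between two groups
#'
#' Vectorised row-wise Welch tests of every probe between two annotated
#' sample groups. Probes with fewer than two non-missing values in either
#' group are skipped (returned with NA statistics and a reason).
#'
#' @param beta Probes x samples beta matrix.
#' @param annotation Data frame with `sample_id`, `group`.
#' @param group_a,group_b Group labels; `delta_beta` is group_b - group_a.
#' @return Data frame of class `welch_screen`: `probe_id`, `mean_a`,
#'   `mean_b`, `delta_beta`, `t_stat`, `df`, `p_value`, `skipped`.
#' @export
welch_screen <- function(beta, annotation, group_a = "NLT",
                         group_b = "NASH-W") {
  cols_a <- annotation$sample_id[annotation$group == group_a]
  cols_b <- annotation$sample_id[annotation$group == group_b]
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop_config("groups '%s' and '%s' each need >= 2 samples",
                group_a, group_b)
  }
  xa <- beta[, intersect(cols_a, colnames(beta)), drop = FALSE]
  xb <- beta[, intersect(cols_b, colnames(beta)), drop = FALSE]
  res <- welch_rows(xa, xb)
  skipped <- rowSums(!is.na(xa)) < 2 | rowSums(!is.na(xb)) < 2
  out <- data.frame(probe_id = rownames(beta), res, skipped = skipped,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[skipped, c("t_stat", "p_value")] <- NA_real_
  class(out) <- c("welch_screen", "data.frame")
  out
}

#' Bonferroni family size alpha
#'
#' @param n_tests Number of probes tested.
#' @param alpha Per-family error rate (default 0.05).
#' @return Per-test threshold `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(n_tests, alpha = 0.05) {
  check_number(n_tests, "n_tests", lower = 1)
  alpha / n_tests
}

#' Select differential probes under Bonferroni and effect-size gates
#'
#' Keeps probes with `p_value < alpha_family` and `|delta_beta| >
#' delta_threshold` (strict inequalities on both gates). `alpha_family` is
#' supplied explicitly: either a printed study constant or
#' [bonferroni_alpha()] of the tested-family size.
#'
#' @param results A `welch_screen` data frame (or any data frame with
#'   `probe_id`, `p_value`, `delta_beta`).
#' @param alpha_family Family-wise per-test alpha, in (0, 1).
#' @param delta_threshold Minimum absolute group-mean difference, beta units
#'   (default 0.1).
#' @return The input rows that pass, with a logical `passes` column added to
#'   the full table as attribute `"passes"`; primary return is the subset.
#' @export
bonferroni_select <- function(results, alpha_family,
                              delta_threshold = 0.1) {
  check_number(alpha_family, "alpha_family", lower = 1e-300, upper = 1)
  check_number(delta_threshold, "delta_threshold", lower = 1e-12)
  passes <- !is.na(results$p_value) &
    results$p_value < alpha_family &
    abs(results$delta_beta) > delta_threshold
  out <- results[passes, , drop = FALSE]
  attr(out, "passes") <- passes
  out
}
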