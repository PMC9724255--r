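#' Apply one marker criterion to a methylation measurement
#'
#' A sample is marker-positive when its methylation level lies on the
#' risk-associated side of the marker's cutoff: at or above the cutoff for
#' hypermethylated markers, at or below for hypomethylated markers. Values
#' exactly at the cutoff count as positive (the risk-sensitive tie rule
#' appropriate to a screening assay).
#'
#' @param rate Methylation level (percent or beta units — same scale as
#'   `cutoff`), or a `methylation_rate` object.
#' @param cutoff Marker cutoff.
#' @param direction `"hyper"` or `"hypo"`.
#' @return Logical: TRUE = positive.
#' @export
apply_marker_criterion <- function(rate, cutoff, direction) {
  if (inherits(rate, "methylation_rate")) rate <- rate$rate
  direction <- match.arg(direction, c("hyper", "hypo"))
  if (direction == "hyper") rate >= cutoff else rate <= cutoff
}

#' Composite k-of-n risk call for one sample
#'
#' @param marker_calls Named logical vector of per-marker calls.
#' @param k Minimum number of positive markers for a risk-positive call.
#' @return List of class `risk_call`: `marker_calls`, `n_positive`, `risk`
#'   (`"positive"`/`"negative"`), `rule` (k, n).
#' @export
#' @examples
#' classify_sample(c(m1 = TRUE, m2 = TRUE, m3 = FALSE), k = 2)$risk
classify_sample <- function(marker_calls, k = 2) {
  if (anyNA(marker_calls)) stop_config("missing marker call")
  n <- length(marker_calls)
  if (k > n) stop_config("k (%d) exceeds the number of markers (%d)", k, n)
  n_pos <- sum(marker_calls)
  structure(list(marker_calls = marker_calls, n_positive = n_pos,
                 risk = if (n_pos >= k) "positive" else "negative",
                 rule = c(k = k, n = n)),
            class = "risk_call")
}

#' Classify a cohort from quantified rates and a marker panel
#'
#' Applies every panel marker's criterion to each sample's rates and issues
#' the composite k-of-n call. Samples missing a rate for any panel marker
#' are skipped with a logged reason (no imputation).
#'
#' @param rates Data frame with `sample_id`, `marker_id`, `rate_percent`
#'   (as produced by [quantify_run()]), or with a `rate` column.
#' @param panel A [marker_panel()]; cutoffs must be on the same scale as
#'   the rates (use `cutoff_scale` to convert beta-unit cutoffs to percent).
#' @param k Minimum positive markers (default 2, the 2-of-3 composite rule).
#' @param cutoff_scale Multiplier applied to panel cutoffs before
#'   comparison (e.g., 100 when cutoffs are in beta units and rates in
#'   percent). Default 1.
#' @return Data frame of class `risk_calls`: `sample_id`, one logical
#'   column per marker, `n_positive`, `risk`; attribute `"skipped"` lists
#'   skipped samples and reasons.
#' @export
classify_cohort <- function(rates, panel, k = 2, cutoff_scale = 1) {
  stopifnot(inherits(panel, "marker_panel"))
  entries <- panel$entries
  if (k > nrow(entries)) stop_config("k exceeds panel size")
  rate_col <- if ("rate_percent" %in% names(rates)) "rate_percent" else "rate"
  samples <- unique(rates$sample_id)
  rows <- list(); skipped <- list()
  for (s in samples) {
    sub <- rates[rates$sample_id == s, ]
    calls <- stats::setNames(rep(NA, nrow(entries)), entries$marker_id)
    for (i in seq_len(nrow(entries))) {
      ri <- sub[[rate_col]][sub$marker_id == entries$marker_id[i]]
      if (length(ri) == 1 && !is.na(ri)) {
        calls[i] <- apply_marker_criterion(
          ri, entries$cutoff[i] * cutoff_scale, entries$direction[i])
      }
    }
    if (anyNA(calls)) {
      skipped[[s]] <- sprintf("missing rate for marker(s): %s",
                              paste(names(calls)[is.na(calls)],
                                    collapse = ", "))
      next
    }
    rc <- classify_sample(calls, k = k)
    rows[[s]] <- data.frame(sample_id = s, t(calls),
                            n_positive = rc$n_positive, risk = rc$risk,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), n_positive = integer(0),
               risk = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "rule") <- c(k = k, n = nrow(entries))
  class(out) <- c("risk_calls", "data.frame")
  out
}

#' Cohort-level performance of the composite risk call
#'
#' Sensitivity is the risk-positive fraction among samples from groups in
#' which carcinoma has arisen (default the `-W` groups pooled, matching the
#' reporting of mixed validation cohorts); specificity is the risk-negative
#' fraction among the designated control groups. A histogram of samples by
#' number of satisfied marker criteria is tabulated per group.
#'
#' @param calls A `risk_calls` data frame.
#' @param annotation Sample annotation with `sample_id`, `group`.
#' @param case_groups Groups counted for sensitivity (default NAFL-W and
#'   NASH-W).
#' @param control_groups Groups counted for specificity (default NLT).
#' @return List of class `cohort_performance`: `sensitivity`,
#'   `specificity`, `histogram` (group x n_positive table), `n_case`,
#'   `n_control`.
#' @export
cohort_performance <- function(calls, annotation,
                               case_groups = c("NAFL-W", "NASH-W"),
                               control_groups = "NLT") {
  grp <- annotation$group[match(calls$sample_id, annotation$sample_id)]
  if (anyNA(grp)) stop_config("call sample(s) missing from annotation")
  n_markers <- attr(calls, "rule")[["n"]]
  pos <- calls$risk == "positive"
  in_case <- grp %in% case_groups
  in_ctrl <- grp %in% control_groups
  hist <- table(factor(grp, levels = unique(grp)),
                factor(calls$n_positive, levels = 0:n_markers))
  structure(list(
    sensitivity = if (any(in_case)) mean(pos[in_case]) else NA_real_,
    specificity = if (any(in_ctrl)) mean(!pos[in_ctrl]) else NA_real_,
    histogram = hist,
    n_case = sum(in_case), n_control = sum(in_ctrl)),
    class = "cohort_performance")
}

#' @export
print.cohort_performance <- function(x, ...) {
  cat(sprintf("Composite risk call: sensitivity %d%% (n=%d), specificity %d%% (n=%d)\n",
              round(100 * x$sensitivity), x$n_case,
              round(100 * x$specificity), x$n_control))
  cat("Samples by number of satisfied marker criteria:\n")
  print(x$histogram)
  invisible(x)
}
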