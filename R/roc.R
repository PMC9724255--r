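#' Rank-based AUC with discrimination direction
#'
#' The area under the ROC curve is computed as the Mann-Whitney probability
#' that a random case value exceeds a random control value, ties counting
#' one half. The discrimination direction is `"hyper"` when the case mean
#' exceeds the control mean (positive calls above the cutoff) and `"hypo"`
#' otherwise; the AUC is reported in that direction, matching the field's
#' convention of a single AUC per marker plus a direction column.
#'
#' @param case_values,control_values Non-empty numeric vectors.
#' @return List of class `roc_result`: `auc`, `auc_raw` (probability case >
#'   control), `direction`, `degenerate`.
#' @export
#' @examples
#' roc_auc(c(0.8, 0.9), c(0.1, 0.2)) # auc 1, hyper
roc_auc <- function(case_values, control_values) {
  cs <- case_values[!is.na(case_values)]
  ct <- control_values[!is.na(control_values)]
  if (!length(cs) || !length(ct)) stop_config("both groups must be non-empty")
  r <- rank(c(ct, cs))
  n1 <- length(cs); n0 <- length(ct)
  u <- sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2
  auc_raw <- u / (n1 * n0)
  degenerate <- length(unique(c(cs, ct))) == 1
  direction <- if (mean(cs) > mean(ct)) "hyper"
               else if (mean(cs) < mean(ct)) "hypo"
               else if (auc_raw >= 0.5) "hyper" else "hypo"
  auc <- if (direction == "hyper") auc_raw else 1 - auc_raw
  structure(list(auc = auc, auc_raw = auc_raw, direction = direction,
                 degenerate = degenerate),
            class = "roc_result")
}

#' Youden-index cutoff
#'
#' Finds the threshold maximising J = sensitivity + specificity - 1 over the
#' midpoints of adjacent distinct pooled values. Positive calls are made at
#' value >= cutoff for hyper markers and value <= cutoff for hypo markers;
#' sensitivity is the fraction of case samples called positive and
#' specificity the fraction of control samples called negative. Ties in J
#' are broken toward the smaller cutoff.
#'
#' @param case_values,control_values Numeric vectors.
#' @param direction `"hyper"` or `"hypo"`; defaults to the [roc_auc()]
#'   direction.
#' @return List: `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   `direction`, `degenerate`.
#' @export
youden_cutoff <- function(case_values, control_values, direction = NULL) {
  cs <- case_values[!is.na(case_values)]
  ct <- control_values[!is.na(control_values)]
  if (!length(cs) || !length(ct)) stop_config("both groups must be non-empty")
  if (is.null(direction)) direction <- roc_auc(cs, ct)$direction
  direction <- match.arg(direction, c("hyper", "hypo"))
  pooled <- sort(unique(c(cs, ct)))
  if (length(pooled) == 1) {
    return(list(cutoff = pooled, sensitivity = NA_real_,
                specificity = NA_real_, youden_j = 0,
                direction = direction, degenerate = TRUE))
  }
  cand <- (pooled[-1] + pooled[-length(pooled)]) / 2
  stats_at <- function(cut) {
    if (direction == "hyper") {
      c(mean(cs >= cut), mean(ct < cut))
    } else {
      c(mean(cs <= cut), mean(ct > cut))
    }
  }
  ss <- vapply(cand, stats_at, numeric(2))
  j <- ss[1, ] + ss[2, ] - 1
  best <- which(j == max(j))[1] # ties -> smaller cutoff
  if (max(j) <= 0) {
    return(list(cutoff = stats::median(c(cs, ct)),
                sensitivity = stats_at(stats::median(c(cs, ct)))[1],
                specificity = stats_at(stats::median(c(cs, ct)))[2],
                youden_j = max(j, 0), direction = direction,
                degenerate = TRUE))
  }
  list(cutoff = cand[best], sensitivity = ss[1, best],
       specificity = ss[2, best], youden_j = j[best],
       direction = direction, degenerate = FALSE)
}

#' Sensitivity and specificity of a fixed marker criterion
#'
#' Applies a fixed cutoff and direction to labelled values. Positive calls
#' are value >= cutoff (hyper) or value <= cutoff (hypo). Sensitivity is the
#' fraction of true-positive-class samples called positive; specificity the
#' fraction of the remaining samples called negative.
#'
#' @param values Numeric vector.
#' @param cutoff Finite threshold on the same scale as `values`.
#' @param direction `"hyper"` or `"hypo"`.
#' @param positive_class_truth Logical vector: TRUE for samples belonging to
#'   the positive class.
#' @return List: `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_criterion <- function(values, cutoff, direction,
                               positive_class_truth) {
  if (!is.finite(cutoff)) stop_config("cutoff must be finite")
  direction <- match.arg(direction, c("hyper", "hypo"))
  stopifnot(length(values) == length(positive_class_truth))
  call_pos <- if (direction == "hyper") values >= cutoff else values <= cutoff
  tp <- sum(call_pos & positive_class_truth)
  fn <- sum(!call_pos & positive_class_truth)
  fp <- sum(call_pos & !positive_class_truth)
  tn <- sum(!call_pos & !positive_class_truth)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}
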