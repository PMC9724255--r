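# Jonckheere-Terpstra trend test across ordered groups.
#
# The statistic is the number of concordant cross-group pairs,
#   J = sum over ordered group pairs (g < h) of #{(x in g, y in h): y > x}
# with ties contributing 1/2. Under the null with tie-free data J is
# distributed as the sum of independent Mann-Whitney statistics of group j
# against groups 1..j-1 pooled, which gives a cheap exact null by
# convolution; with ties or larger samples a tie-corrected normal
# approximation (with continuity correction) or a seeded Monte-Carlo
# permutation null is used.

jt_statistic <- function(groups) {
  k <- length(groups)
  j <- 0
  for (g in seq_len(k - 1)) {
    x <- groups[[g]]
    for (h in seq((g + 1), k)) {
      y <- groups[[h]]
      cmp <- outer(x, y, function(a, b) (b > a) + 0.5 * (b == a))
      j <- j + sum(cmp)
    }
  }
  j
}

# Exact null pmf of J for tie-free data: convolution of Wilcoxon
# (Mann-Whitney) pmfs dwilcox(m_j, n_j) with m_j = n_1 + ... + n_{j-1}.
jt_exact_pmf <- function(sizes) {
  pmf <- 1 # point mass at 0
  m <- sizes[1]
  for (j in 2:length(sizes)) {
    n <- sizes[j]
    comp <- stats::dwilcox(0:(m * n), m, n)
    new <- numeric(length(pmf) + length(comp) - 1)
    for (u in seq_along(comp)) {
      if (comp[u] > 0) {
        idx <- seq_along(pmf) + (u - 1)
        new[idx] <- new[idx] + pmf * comp[u]
      }
    }
    pmf <- new
    m <- m + n
  }
  pmf # pmf[i] = P(J = i - 1)
}

jt_normal_p <- function(jstat, groups, alternative) {
  pooled <- unlist(groups)
  n_i <- lengths(groups)
  n <- length(pooled)
  t_j <- as.numeric(table(pooled))
  mu <- (n^2 - sum(n_i^2)) / 4
  a <- n * (n - 1) * (2 * n + 5) -
    sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
    sum(t_j * (t_j - 1) * (2 * t_j + 5))
  b <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_j * (t_j - 1) * (t_j - 2))
  cc_term <- sum(n_i * (n_i - 1)) * sum(t_j * (t_j - 1))
  v <- a / 72 + b / (36 * n * (n - 1) * (n - 2)) +
    cc_term / (8 * n * (n - 1))
  if (v <= 0) return(1)
  if (alternative == "increasing") {
    stats::pnorm((jstat - 0.5 - mu) / sqrt(v), lower.tail = FALSE)
  } else {
    stats::pnorm((jstat + 0.5 - mu) / sqrt(v), lower.tail = TRUE)
  }
}

#' Jonckheere-Terpstra trend test
#'
#' One-sided test for a monotone trend of a continuous response across three
#' or more ordered groups (e.g., disease stages normal -> precancerous ->
#' tumour). See Details for the choice of null distribution.
#'
#' @details `method = "auto"` uses the exact convolution null when the data
#'   are tie-free and the pooled sample size is at most `exact_limit`, and
#'   the tie-corrected normal approximation with continuity correction
#'   otherwise. `"exact"` forces the convolution null (tie-free data only),
#'   `"normal"` the approximation, and `"permutation"` a seeded Monte-Carlo
#'   permutation null with `nperm` draws.
#'
#' @param groups_ordered List of >= 3 non-empty numeric vectors in
#'   hypothesised order.
#' @param alternative `"increasing"` or `"decreasing"`.
#' @param method `"auto"`, `"exact"`, `"normal"` or `"permutation"`.
#' @param exact_limit Largest pooled n for which auto picks the exact null.
#' @param nperm Monte-Carlo permutations.
#' @param seed Seed for the permutation null.
#' @return List of class `jt_test`: `jt_stat`, `p_value`, `direction`,
#'   `method`, `max_stat` (the pairwise-product upper bound on J).
#' @export
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))$p_value # 1/90
jonckheere_terpstra <- function(groups_ordered,
                                alternative = c("increasing", "decreasing"),
                                method = c("auto", "exact", "normal",
                                           "permutation"),
                                exact_limit = 12, nperm = 10000, seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(groups_ordered) < 3) stop_config("need >= 3 ordered groups")
  groups_ordered <- lapply(groups_ordered, function(g) g[!is.na(g)])
  if (any(lengths(groups_ordered) < 1)) {
    stop_config("every group needs at least one value")
  }
  pooled <- unlist(groups_ordered)
  has_ties <- anyDuplicated(pooled) > 0
  sizes <- lengths(groups_ordered)
  jstat <- jt_statistic(groups_ordered)
  max_stat <- (sum(sizes)^2 - sum(sizes^2)) / 2

  if (method == "auto") {
    method <- if (!has_ties && length(pooled) <= exact_limit) "exact"
              else "normal"
  }
  p <- switch(method,
    exact = {
      if (has_ties) stop_config("exact null requires tie-free data")
      pmf <- jt_exact_pmf(sizes)
      if (alternative == "increasing") {
        sum(pmf[(floor(jstat) + 1):length(pmf)])
      } else {
        sum(pmf[1:(ceiling(jstat) + 1)])
      }
    },
    normal = jt_normal_p(jstat, groups_ordered, alternative),
    permutation = {
      set.seed(seed)
      idx <- rep(seq_along(sizes), sizes)
      exceed <- 0L
      for (b in seq_len(nperm)) {
        perm <- split(sample(pooled), idx)
        js <- jt_statistic(perm)
        hit <- if (alternative == "increasing") js >= jstat else js <= jstat
        exceed <- exceed + hit
      }
      (1 + exceed) / (nperm + 1)
    })
  structure(list(jt_stat = jstat, p_value = min(1, p),
                 direction = alternative, method = method,
                 max_stat = max_stat),
            class = "jt_test")
}

#' @export
print.jt_test <- function(x, ...) {
  cat(sprintf("Jonckheere-Terpstra: J = %.1f (max %.0f), one-sided %s p = %.4g [%s]\n",
              x$jt_stat, x$max_stat, x$direction, x$p_value, x$method))
  invisible(x)
}

#' Retain differential probes whose alteration is inherited along stages
#'
#' For each probe already selected as differential, tests whether its
#' methylation change is carried forward (inherited or strengthened) along
#' an ordered stage sequence (e.g., NLT -> NASH-W -> T) with the
#' Jonckheere-Terpstra test, the alternative matching the sign of the
#' probe's `delta_beta`. Probes with one-sided p below `alpha` are kept.
#'
#' @param diff_results Data frame with `probe_id` and `delta_beta` (e.g.,
#'   output of [bonferroni_select()]).
#' @param beta Probes x samples matrix.
#' @param annotation Sample annotation with `sample_id`, `group`.
#' @param stage_order Ordered group labels (>= 3).
#' @param alpha One-sided significance level (default 0.05).
#' @param method Passed to [jonckheere_terpstra()]; the default normal
#'   approximation is appropriate at cohort sample sizes.
#' @return Subset of `diff_results` with columns `jt_stat`, `jt_p`,
#'   `direction` appended.
#' @export
trend_inherited_set <- function(diff_results, beta, annotation,
                                stage_order = c("NLT", "NASH-W", "T"),
                                alpha = 0.05, method = "normal") {
  if (nrow(diff_results) == 0) {
    out <- diff_results
    out$jt_stat <- numeric(0); out$jt_p <- numeric(0)
    out$direction <- character(0)
    return(out)
  }
  missing_g <- setdiff(stage_order, annotation$group)
  if (length(missing_g)) {
    stop_config("stage group(s) absent from annotation: %s",
                paste(missing_g, collapse = ", "))
  }
  cols <- lapply(stage_order, function(g) {
    intersect(annotation$sample_id[annotation$group == g], colnames(beta))
  })
  jt_stat <- jt_p <- numeric(nrow(diff_results))
  dirn <- ifelse(diff_results$delta_beta >= 0, "increasing", "decreasing")
  for (i in seq_len(nrow(diff_results))) {
    pid <- diff_results$probe_id[i]
    gvals <- lapply(cols, function(cc) beta[pid, cc])
    jt <- jonckheere_terpstra(gvals, alternative = dirn[i], method = method)
    jt_stat[i] <- jt$jt_stat
    jt_p[i] <- jt$p_value
  }
  out <- diff_results
  out$jt_stat <- jt_stat
  out$jt_p <- jt_p
  out$direction <- dirn
  out[jt_p < alpha, , drop = FALSE]
}
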