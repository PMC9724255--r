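test_that("maximal ordering gives the maximal statistic and exact p", {
  jt <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(jt$jt_stat, 12)
  expect_equal(jt$max_stat, 12)
  expect_equal(jt$p_value, 1 / 90) # one of 6!/(2!2!2!) arrangements
  expect_equal(jt$method, "exact")
})

test_that("the statistic counts concordant cross-group pairs", {
  jt <- jonckheere_terpstra(list(c(1, 3), c(2, 4), c(5, 6)))
  expect_equal(jt$jt_stat, 11)
  # direct hand count with ties at one half
  jt2 <- jonckheere_terpstra(list(c(1, 2), c(2, 3), c(3, 4)),
                             method = "normal")
  expect_equal(jt2$jt_stat, 3.5 + 4 + 3.5)
})

test_that("identical constant groups show no trend either way", {
  g <- list(rep(0.5, 4), rep(0.5, 4), rep(0.5, 4))
  expect_equal(jonckheere_terpstra(g, "increasing")$p_value, 1)
  expect_equal(jonckheere_terpstra(g, "decreasing")$p_value, 1)
})

test_that("normal approximation tracks the exact null on small samples", {
  set.seed(31)
  worst <- 0
  for (i in 1:30) {
    sizes <- sample(2:4, 3, replace = TRUE)
    g <- split(stats::runif(sum(sizes)), rep(1:3, sizes))
    alt <- sample(c("increasing", "decreasing"), 1)
    pe <- jonckheere_terpstra(g, alt, method = "exact")$p_value
    pn <- jonckheere_terpstra(g, alt, method = "normal")$p_value
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.02)
})

test_that("Monte-Carlo permutation null agrees with the exact null", {
  g <- list(c(0.1, 0.9, 0.4), c(0.5, 0.3), c(0.8, 0.7, 0.2))
  pe <- jonckheere_terpstra(g, method = "exact")$p_value
  pp <- jonckheere_terpstra(g, method = "permutation", nperm = 4000,
                            seed = 2)$p_value
  expect_lt(abs(pe - pp), 0.03)
})

test_that("degenerate inputs are rejected", {
  expect_error(jonckheere_terpstra(list(1:3, 4:6)), ">= 3")
  expect_error(jonckheere_terpstra(list(1:3, numeric(0), 4:6)),
               "at least one value")
  expect_error(jonckheere_terpstra(list(c(1, 1), c(1, 2), c(2, 2)),
                                   method = "exact"), "tie")
})

test_that("trend filter keeps monotone planted probes and drops reversals", {
  set.seed(5)
  n <- 20
  mk_mat <- function(means) {
    vals <- unlist(lapply(means, function(m) stats::rnorm(n, m, 0.08)))
    matrix(vals, nrow = 1, dimnames = list("p1", sprintf("s%02d", 1:(3 * n))))
  }
  ann <- data.frame(sample_id = sprintf("s%02d", 1:(3 * n)),
                    group = rep(c("NLT", "NASH-W", "T"), each = n))
  diffres <- data.frame(probe_id = "p1", delta_beta = 0.3)
  mono <- trend_inherited_set(diffres, mk_mat(c(0.2, 0.5, 0.8)), ann)
  expect_equal(nrow(mono), 1)
  expect_true(mono$jt_p < 0.05)
  rev <- trend_inherited_set(diffres, mk_mat(c(0.2, 0.5, 0.2)), ann)
  expect_equal(nrow(rev), 0)
  # cross-check the retained probe with the permutation null
  g <- split(as.numeric(mk_mat(c(0.2, 0.5, 0.8))), rep(1:3, each = n))
  pp <- jonckheere_terpstra(g, "increasing", method = "permutation",
                            nperm = 2000, seed = 3)$p_value
  expect_lt(pp, 0.05)
})

test_that("an empty differential set passes through as empty", {
  co <- small_cohort(seed = 2, n_probes = 50)
  empty <- data.frame(probe_id = character(0), delta_beta = numeric(0))
  out <- trend_inherited_set(empty, co$beta, co$annotation)
  expect_equal(nrow(out), 0)
})
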