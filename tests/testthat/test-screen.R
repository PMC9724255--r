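test_that("probe filter removes low-call and sex-chromosome probes by union", {
  fx <- filter_fixture(1000, n_low = 30, n_sex = 50, n_both = 5)
  pf <- filter_probes(fx$beta, fx$manifest)
  expect_equal(pf$summary$n_lowcall, 30)
  expect_equal(pf$summary$n_excluded_chrom, 50)
  expect_equal(pf$summary$n_overlap, 5)
  expect_equal(pf$summary$n_retained, 925)
  expect_equal(nrow(pf$beta), 925)
  # removed + retained partition the input
  expect_equal(pf$summary$n_retained +
                 (pf$summary$n_lowcall + pf$summary$n_excluded_chrom -
                    pf$summary$n_overlap),
               pf$summary$n_input)
})

test_that("probe filter is an identity on clean input and is idempotent", {
  fx <- filter_fixture(200, n_low = 10, n_sex = 10, n_both = 0)
  clean <- filter_fixture(50, 0, 0, 0)
  clean$manifest$call_proportion <- 0.99
  pf0 <- filter_probes(clean$beta, clean$manifest,
                       exclude_chromosomes = character(0))
  expect_identical(pf0$beta, clean$beta)
  pf1 <- filter_probes(fx$beta, fx$manifest)
  pf2 <- filter_probes(pf1$beta, pf1$manifest)
  expect_identical(pf1$beta, pf2$beta)
  expect_equal(pf2$summary$n_lowcall, 0)
})

test_that("Welch test matches t.test and reports delta beta", {
  a <- c(0.20, 0.22, 0.18); b <- c(0.35, 0.33, 0.37)
  w <- welch_test(a, b)
  expect_equal(w$delta_beta, 0.15)
  ref <- stats::t.test(c(0.3, 0.4, 0.5, 0.6), c(0.1, 0.2, 0.3, 0.4))
  w2 <- welch_test(c(0.1, 0.2, 0.3, 0.4), c(0.3, 0.4, 0.5, 0.6))
  expect_lt(abs(w2$p_value - ref$p.value), 1e-10)
  expect_lt(abs(abs(w2$t_stat) - abs(ref$statistic)), 1e-10)
  # identical vectors: no difference
  w0 <- welch_test(a, a)
  expect_equal(w0$t_stat, 0)
  expect_equal(w0$p_value, 1)
})

test_that("Welch test is antisymmetric in its groups", {
  set.seed(4)
  for (i in 1:20) {
    a <- stats::runif(5 + i %% 3); b <- stats::runif(4 + i %% 4)
    w1 <- welch_test(a, b); w2 <- welch_test(b, a)
    expect_equal(w1$delta_beta, -w2$delta_beta)
    expect_equal(w1$t_stat, -w2$t_stat)
    expect_equal(w1$p_value, w2$p_value)
  }
})

test_that("degenerate zero-variance groups are handled explicitly", {
  same <- welch_test(c(0.5, 0.5, 0.5), c(0.5, 0.5))
  expect_equal(same$p_value, 1)
  diff <- welch_test(c(0.2, 0.2, 0.2), c(0.8, 0.8))
  expect_equal(diff$p_value, 0)
  expect_true(diff$degenerate)
  expect_error(welch_test(0.5, c(0.1, 0.2)), ">= 2")
})

test_that("vectorised screen agrees with per-probe t.test", {
  co <- small_cohort(seed = 11, n_probes = 60)
  pf <- filter_probes(co$beta, co$manifest)
  ws <- welch_screen(pf$beta, co$annotation)
  ann <- co$annotation
  nlt <- ann$sample_id[ann$group == "NLT"]
  nw <- ann$sample_id[ann$group == "NASH-W"]
  for (i in c(1, 7, 23, nrow(ws))) {
    ref <- stats::t.test(pf$beta[i, nw], pf$beta[i, nlt])
    expect_lt(abs(ws$p_value[i] - ref$p.value), 1e-10)
  }
})

test_that("Bonferroni selection equals the brute-force double filter", {
  set.seed(8)
  res <- data.frame(probe_id = sprintf("p%03d", 1:200),
                    delta_beta = stats::runif(200, -0.4, 0.4),
                    p_value = 10^stats::runif(200, -12, 0))
  alpha <- 1.12e-7
  sel <- bonferroni_select(res, alpha, 0.1)
  brute <- res[res$p_value < alpha & abs(res$delta_beta) > 0.1, ]
  expect_identical(sel$probe_id, brute$probe_id)
  # the effect-size gate alone rejects
  one <- data.frame(probe_id = "p", delta_beta = 0.05, p_value = 1e-8)
  expect_equal(nrow(bonferroni_select(one, alpha, 0.1)), 0)
  one$delta_beta <- 0.15
  expect_equal(nrow(bonferroni_select(one, alpha, 0.1)), 1)
})
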