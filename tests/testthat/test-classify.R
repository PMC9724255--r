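table4_panel <- function() {
  # published-style fixture: five markers with fixed cutoffs; directions
  # follow the hyper/hypo methylation status of each site
  marker_panel(data.frame(
    marker_id = c("cg09580822", "cg15050398", "cg18210511", "cg09580859",
                  "cg13719443"),
    cutoff = c(0.667, 1.000, 0.641, 0.849, 0.408),
    direction = c("hypo", "hyper", "hyper", "hyper", "hypo")))
}

test_that("single-marker criteria respect direction and the tie rule", {
  expect_true(apply_marker_criterion(0.70, 0.641, "hyper"))
  expect_false(apply_marker_criterion(0.60, 0.641, "hyper"))
  expect_true(apply_marker_criterion(0.30, 0.408, "hypo"))
  expect_false(apply_marker_criterion(0.50, 0.408, "hypo"))
  # value exactly at the cutoff counts positive in both directions
  expect_true(apply_marker_criterion(0.641, 0.641, "hyper"))
  expect_true(apply_marker_criterion(0.408, 0.408, "hypo"))
  expect_error(apply_marker_criterion(0.5, 0.5, "sideways"))
})

test_that("the k-of-n composite rule counts satisfied criteria", {
  expect_equal(classify_sample(c(TRUE, TRUE, FALSE), k = 2)$risk, "positive")
  expect_equal(classify_sample(c(FALSE, FALSE, FALSE), k = 2)$risk,
               "negative")
  expect_equal(classify_sample(c(TRUE, FALSE, FALSE), k = 2)$risk,
               "negative")
  expect_error(classify_sample(c(TRUE, NA, TRUE), k = 2), "missing")
  expect_error(classify_sample(c(TRUE, TRUE), k = 3), "exceeds")
})

test_that("cohort classification skips samples with missing rates", {
  panel <- marker_panel(data.frame(
    marker_id = c("m1", "m2", "m3"),
    cutoff = c(50, 50, 50),
    direction = c("hyper", "hyper", "hypo")))
  rates <- data.frame(
    sample_id = c(rep("s1", 3), rep("s2", 2)),
    marker_id = c("m1", "m2", "m3", "m1", "m2"),
    rate_percent = c(60, 70, 30, 60, 70))
  calls <- classify_cohort(rates, panel, k = 2)
  expect_equal(calls$sample_id, "s1")
  expect_equal(calls$n_positive, 3)
  expect_match(attr(calls, "skipped")$s2, "m3")
})

test_that("risk calls are monotone in marker positives and in k", {
  panel <- marker_panel(data.frame(marker_id = paste0("m", 1:3),
                                   cutoff = 50,
                                   direction = "hyper"))
  set.seed(30)
  rates <- expand.grid(sample_id = sprintf("s%02d", 1:20),
                       marker_id = paste0("m", 1:3),
                       stringsAsFactors = FALSE)
  rates$rate_percent <- stats::runif(nrow(rates), 0, 100)
  calls2 <- classify_cohort(rates, panel, k = 2)
  calls1 <- classify_cohort(rates, panel, k = 1)
  calls3 <- classify_cohort(rates, panel, k = 3)
  pos <- function(x) x$sample_id[x$risk == "positive"]
  expect_true(all(pos(calls3) %in% pos(calls2)))
  expect_true(all(pos(calls2) %in% pos(calls1)))
  # flipping one negative marker call positive never lowers n_positive
  bumped <- rates
  bumped$rate_percent[bumped$sample_id == "s01"] <- 99
  calls2b <- classify_cohort(bumped, panel, k = 2)
  expect_gte(calls2b$n_positive[calls2b$sample_id == "s01"],
             calls2$n_positive[calls2$sample_id == "s01"])
})

test_that("cohort performance pools the W groups for sensitivity", {
  # 10 NAFL-W with 9 risk-positive, 11 NASH-W all positive, 22 NLT negative
  ann <- data.frame(
    sample_id = sprintf("v%02d", 1:43),
    group = c(rep("NAFL-W", 10), rep("NASH-W", 11), rep("NLT", 22)))
  n_pos <- c(2, rep(3, 9), rep(2, 11), rep(0, 22))
  n_pos[1] <- 1 # the one risk-negative NAFL-W sample
  calls <- data.frame(sample_id = ann$sample_id, n_positive = n_pos,
                      risk = ifelse(n_pos >= 2, "positive", "negative"))
  attr(calls, "rule") <- c(k = 2, n = 3)
  class(calls) <- c("risk_calls", "data.frame")
  perf <- cohort_performance(calls, ann)
  expect_equal(perf$sensitivity, 20 / 21)
  expect_equal(round(100 * perf$sensitivity), 95)
  expect_equal(perf$specificity, 1)
  # histogram mass conservation per group
  expect_equal(unname(rowSums(perf$histogram)),
               unname(as.vector(table(ann$group)[rownames(perf$histogram)])))
})

test_that("performance equals a hand-computed confusion matrix", {
  set.seed(31)
  ann <- data.frame(sample_id = sprintf("x%02d", 1:30),
                    group = sample(c("NASH-W", "NLT"), 30, replace = TRUE))
  risk <- sample(c("positive", "negative"), 30, replace = TRUE)
  calls <- data.frame(sample_id = ann$sample_id,
                      n_positive = ifelse(risk == "positive", 2, 0),
                      risk = risk)
  attr(calls, "rule") <- c(k = 2, n = 3)
  class(calls) <- c("risk_calls", "data.frame")
  perf <- cohort_performance(calls, ann, case_groups = "NASH-W",
                             control_groups = "NLT")
  w <- ann$group == "NASH-W"
  expect_equal(perf$sensitivity, sum(risk == "positive" & w) / sum(w))
  expect_equal(perf$specificity, sum(risk == "negative" & !w) / sum(!w))
})

test_that("a published-style five-marker panel classifies typical profiles", {
  panel <- table4_panel()
  # a risk-like profile: hyper sites high, hypo sites low (beta scale)
  rates <- data.frame(
    sample_id = "w1", marker_id = panel$entries$marker_id,
    rate_percent = c(0.40, 1.00, 0.80, 0.90, 0.20))
  calls <- classify_cohort(rates, panel, k = 2)
  expect_equal(calls$risk, "positive")
  expect_equal(calls$n_positive, 5)
})
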