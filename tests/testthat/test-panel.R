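panel_fixture <- function(seed, n_null = 95, n_marker = 5) {
  # 5 strong planted markers (|delta beta| = 0.4, low noise) among nulls
  set.seed(seed)
  groups <- c(rep("NLT", 20), rep("NASH-O", 20), rep("NASH-W", 15))
  ids <- sprintf("s%02d", seq_along(groups))
  n <- n_null + n_marker
  probe_id <- sprintf("cg%05d", 1:n)
  beta <- matrix(NA_real_, n, length(groups),
                 dimnames = list(probe_id, ids))
  base <- stats::runif(n, 0.25, 0.55)
  phi <- 300 # low noise
  for (j in seq_along(groups)) {
    mu <- base
    if (groups[j] == "NASH-W") mu[1:n_marker] <- mu[1:n_marker] + 0.4
    beta[, j] <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  }
  ann <- data.frame(sample_id = ids, group = groups)
  list(beta = beta, annotation = ann, planted = probe_id[1:n_marker])
}

test_that("two-stage selection recovers exactly the planted markers", {
  for (seed in 1:10) {
    fx <- panel_fixture(seed)
    panel <- select_panel(rownames(fx$beta), fx$beta, fx$annotation,
                          auc_threshold = 0.95,
                          specificity_threshold = 0.85)
    expect_setequal(panel$entries$marker_id, fx$planted)
    expect_true(all(panel$entries$direction == "hyper"))
  }
})

test_that("selection thresholds behave as strict and inclusive gates", {
  fx <- panel_fixture(3)
  none <- select_panel(rownames(fx$beta), fx$beta, fx$annotation,
                       auc_threshold = 1.01)
  expect_equal(nrow(none$entries), 0)
  stage1 <- select_panel(rownames(fx$beta), fx$beta, fx$annotation,
                         auc_threshold = 0.95, specificity_threshold = 0)
  expect_setequal(stage1$entries$marker_id,
                  stage1$selection_params$stage1_ids)
})

test_that("stage-2 panel is nested in stage 1 and the input set", {
  fx <- panel_fixture(4)
  input <- rownames(fx$beta)
  panel <- select_panel(input, fx$beta, fx$annotation)
  s1 <- panel$selection_params$stage1_ids
  expect_true(all(panel$entries$marker_id %in% s1))
  expect_true(all(s1 %in% input))
  # hyper + hypo counts partition the AUC-stage set
  expect_equal(panel$selection_params$n_hyper +
                 panel$selection_params$n_hypo,
               panel$selection_params$n_stage1)
})

test_that("missing groups are an error", {
  fx <- panel_fixture(5)
  ann <- fx$annotation
  ann$group[ann$group == "NASH-O"] <- "OTHER"
  expect_error(select_panel(rownames(fx$beta), fx$beta, ann), "NASH-O")
})

test_that("panels round-trip through JSON and validate their schema", {
  entries <- data.frame(
    marker_id = c("cg09580822", "cg15050398", "cg18210511", "cg09580859",
                  "cg13719443"),
    cutoff = c(0.667, 1.000, 0.641, 0.849, 0.408),
    direction = c("hypo", "hyper", "hyper", "hyper", "hypo"),
    auc = c(0.965, 0.980, 0.865, 0.812, 0.850),
    specificity = c(0.933, 0.933, 0.759, 0.770, 0.730))
  panel <- marker_panel(entries)
  path <- tempfile(fileext = ".json")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back$entries$marker_id, entries$marker_id)
  expect_equal(back$entries$cutoff, entries$cutoff)
  # schema error names the missing field
  bad <- entries[, setdiff(names(entries), "direction")]
  badpath <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, badpath, dataframe = "rows")
  expect_error(read_panel(badpath), "direction")
  expect_error(marker_panel(data.frame(marker_id = "x")), "cutoff")
})
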