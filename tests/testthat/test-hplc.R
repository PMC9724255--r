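noiseless <- function(..., seed = 1) {
  simulate_chromatogram(chrom_spec(..., noise_sd = 0, seed = seed))
}

test_that("baseline correction removes constants and linear drift", {
  flat <- chromatogram(seq(0, 10, by = 0.02), rep(5, 501))
  corr <- correct_baseline(flat)
  expect_lt(max(abs(corr$absorbance)), 1e-9)
  # drift: peak area preserved within 1%
  drifted <- simulate_chromatogram(chrom_spec(noise_sd = 0, drift = 0.2,
                                              baseline = 1))
  clean <- noiseless()
  corr2 <- correct_baseline(drifted)
  trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
  expect_lt(abs(trapz(corr2$time, corr2$absorbance) -
                  trapz(clean$time, clean$absorbance)) /
              trapz(clean$time, clean$absorbance), 0.01)
  # idempotence
  corr3 <- correct_baseline(corr2)
  expect_lt(max(abs(corr3$absorbance - corr2$absorbance)), 1e-6)
})

test_that("baseline windows overlapping the peak produce a warning", {
  near_edge <- simulate_chromatogram(
    chrom_spec(noise_sd = 0, rt_unmeth = 0.4, rt_meth = 9,
               component_rates = cbind(0, 1)))
  expect_warning(correct_baseline(near_edge), "peak")
})

test_that("a noiseless single peak is fit exactly", {
  tr <- noiseless()
  fit <- fit_peaks(tr)
  expect_equal(fit$pattern, "single")
  expect_equal(nrow(fit$peaks), 1)
  expect_lt(abs(fit$peaks$rt - 6.0), 1 / 120)
  expect_lt(abs(fit$peaks$area - 1), 0.01)
})

test_that("resolved two-component traces are bimodal with true area split", {
  tr <- noiseless(pattern = "bimodal",
                  component_rates = cbind(c(25, 75), c(2, 1)))
  fit <- fit_peaks(tr)
  expect_equal(fit$pattern, "bimodal")
  ratio <- fit$peaks$area[1] / fit$peaks$area[2]
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("unresolved components classify as a shoulder by the valley rule", {
  # separation of one width unit: modes merge, no 20% valley
  tr <- noiseless(pattern = "shoulder", peak_width = 0.15,
                  component_rates = cbind(c(46.25, 53.75), c(2, 1)))
  fit <- fit_peaks(tr)
  expect_equal(fit$pattern, "single_with_shoulder")
  # an analytic check of the valley rule on the noiseless sum
  t <- tr$time; y <- tr$absorbance
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  expect_lt(length(locmax[y[locmax] > 0.02 * max(y)]), 2)
})

test_that("a flat trace raises a no-peak error", {
  flat <- chromatogram(seq(0, 10, by = 0.02),
                       stats::rnorm(501, 0, 1e-4))
  expect_error(fit_peaks(flat), "no peak")
})

test_that("calibration is exact at its anchors and order-agnostic", {
  cal <- make_cal(5, 7)
  expect_equal(cal_percent(cal, 5), 0)
  expect_equal(cal_percent(cal, 7), 100)
  expect_equal(cal_percent(cal, 6), 50)
  rev <- make_cal(7, 5)
  expect_equal(cal_percent(rev, 6.5), 25)
  # controls fitted from traces
  c0 <- noiseless(component_rates = cbind(0, 1), seed = 2)
  c0$role <- "control_0"
  c100 <- noiseless(component_rates = cbind(100, 1), seed = 3)
  c100$role <- "control_100"
  fitted_cal <- calibrate(c0, c100)
  expect_lt(abs(fitted_cal$rt_0 - 5), 0.01)
  expect_lt(abs(fitted_cal$rt_100 - 7), 0.01)
})

test_that("unresolved controls are a calibration error", {
  c0 <- noiseless(component_rates = cbind(0, 1))
  c100 <- noiseless(component_rates = cbind(0.5, 1))
  expect_error(calibrate(c0, c100), "not resolved")
})

test_that("rates are area-weighted, clamped, and scale-invariant", {
  cal <- make_cal(5, 7)
  fit <- structure(list(
    peaks = data.frame(rt = c(5.5, 6.5), area = c(2, 1),
                       width = 0.15, tailing = 0),
    pattern = "bimodal", fit_quality = 0, run_id = "run1",
    marker_id = "marker1", sample_id = "s1"), class = "peak_fit")
  mr <- methylation_rate(fit, cal)
  expect_equal(mr$rate, (2 * 25 + 1 * 75) / 3, tolerance = 1e-12)
  expect_false(mr$clamped)
  # uniform absorbance rescaling: areas scale together, rate unchanged
  fit2 <- fit; fit2$peaks$area <- fit$peaks$area * 7.3
  expect_equal(methylation_rate(fit2, cal)$rate, mr$rate)
  # beyond the 100% anchor: clamped
  fit3 <- fit; fit3$peaks <- data.frame(rt = 7.5, area = 1, width = 0.15,
                                        tailing = 0)
  mr3 <- methylation_rate(fit3, cal)
  expect_equal(mr3$rate, 100)
  expect_true(mr3$clamped)
  # run mismatch is an error
  cal2 <- make_cal(5, 7, run_id = "other")
  expect_error(methylation_rate(fit, cal2), "different run")
})

test_that("single peak at the calibration midpoint reads 50%", {
  tr <- noiseless()
  fit <- fit_peaks(tr)
  mr <- methylation_rate(fit, make_cal(5, 7))
  expect_lt(abs(mr$rate - 50), 0.5)
})
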