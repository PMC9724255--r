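#' Baseline correction of a chromatogram
#'
#' Subtracts the straight line through the median absorbance of a leading
#' and a trailing baseline window. A warning is issued when either window
#' appears to contain peak signal (its excursion above its own median is
#' large relative to the local noise level).
#'
#' @param chrom A [chromatogram()].
#' @param window Width of each baseline window, minutes (default 0.5).
#' @return The corrected `chromatogram`.
#' @export
correct_baseline <- function(chrom, window = 0.5) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$time; y <- chrom$absorbance
  if (2 * window >= diff(range(t))) {
    stop_config("baseline windows exceed the trace span")
  }
  lead <- t <= t[1] + window
  trail <- t >= t[length(t)] - window
  for (w in list(lead, trail)) {
    # curvature check: a clean baseline window (constant or drifting) is
    # linear; residuals far above its noise mean a peak intrudes
    tw <- t[w]; yw <- y[w]
    b <- stats::cov(tw, yw) / stats::var(tw)
    resid <- yw - (mean(yw) + b * (tw - mean(tw)))
    noise <- stats::mad(diff(yw)) / sqrt(2)
    if (max(abs(resid)) > 5 * noise + 0.002 * max(abs(y)) + 1e-9) {
      warning("baseline window appears to overlap peak signal")
      break
    }
  }
  x1 <- stats::median(t[lead]); y1 <- stats::median(y[lead])
  x2 <- stats::median(t[trail]); y2 <- stats::median(y[trail])
  slope <- (y2 - y1) / (x2 - x1)
  chrom$absorbance <- y - (y1 + slope * (t - x1))
  chrom
}

# Robust noise estimate from the outer 10% of the trace.
trace_noise <- function(chrom) {
  n <- length(chrom$absorbance)
  edge <- c(seq_len(max(5, n %/% 10)),
            seq(n - max(5, n %/% 10) + 1, n))
  stats::mad(diff(chrom$absorbance[edge])) / sqrt(2)
}

# Initial peak guesses from a Savitzky-Golay smoothed trace.
peak_guesses <- function(chrom, n_wanted) {
  t <- chrom$time; y <- chrom$absorbance
  dt <- t[2] - t[1]
  fl <- max(5, round(0.08 / dt))
  if (fl %% 2 == 0) fl <- fl + 1
  ys <- if (length(y) > fl) signal::sgolayfilt(y, p = 3, n = fl) else y
  # local maxima above 5% of the global max, at least 3 points from edges
  idx <- which(diff(sign(diff(ys))) == -2) + 1
  idx <- idx[ys[idx] > 0.05 * max(ys)]
  idx <- idx[order(ys[idx], decreasing = TRUE)]
  if (!length(idx)) idx <- which.max(ys)
  mus <- t[idx]
  if (length(mus) < n_wanted) {
    # split the tallest peak symmetrically for the extra component
    width0 <- 0.1 * diff(range(t))
    mus <- c(mus, mus[1] + rep(c(-1, 1), length.out = n_wanted - length(mus)) *
               width0 / 2)
  }
  mus[seq_len(n_wanted)]
}

fit_k_components <- function(chrom, k, shape, equal_width, max_iter = 200) {
  t <- chrom$time; y <- chrom$absorbance
  dt <- t[2] - t[1]
  span <- diff(range(t))
  mus0 <- sort(peak_guesses(chrom, k))
  area0 <- max(sum(y) * dt, 1e-8) / k
  use_tau <- shape == "emg"
  n_sigma <- if (equal_width) 1L else k
  lower <- c(rep(1e-12, k), rep(min(t), k), rep(dt / 2, n_sigma),
             if (use_tau) 0)
  upper <- c(rep(Inf, k), rep(max(t), k), rep(span / 2, n_sigma),
             if (use_tau) span / 4)
  # multi-start over plausible widths; tau starts near the Gaussian limit
  starts <- lapply(c(0.015, 0.04, 0.1) * span, function(sigma0) {
    c(rep(area0, k), mus0, rep(sigma0, n_sigma), if (use_tau) 0.05 * sigma0)
  })
  unpack <- function(p) {
    areas <- p[seq_len(k)]
    mus <- p[k + seq_len(k)]
    sigmas <- p[2 * k + seq_len(n_sigma)]
    if (equal_width) sigmas <- rep(sigmas, k)
    tau <- if (use_tau) p[length(p)] else 0
    list(areas = areas, mus = mus, sigmas = sigmas, tau = tau)
  }
  model_at <- function(p, tt) {
    q <- unpack(p)
    out <- numeric(length(tt))
    for (i in seq_len(k)) {
      out <- out + emg_profile(tt, q$mus[i], q$sigmas[i], q$tau, q$areas[i])
    }
    out
  }
  best <- NULL
  for (par0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = function(p) y - model_at(p, t),
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = res$par, rss = rss, k = k,
                   n_par = length(par0) + 1,
                   unpack = unpack, model_at = model_at,
                   converged = res$info %in% 1:4)
    }
  }
  best
}

aicc <- function(rss, n, k_par, floor_sd) {
  rss <- max(rss, n * floor_sd^2)
  n * log(rss / n) + 2 * k_par + 2 * k_par * (k_par + 1) / (n - k_par - 1)
}

#' Deconvolve a chromatogram into structural peaks
#'
#' Fits 1- and 2-component peak models (exponentially modified Gaussian by
#' default; pure Gaussian via `shape = "gauss"`) by bounded least squares,
#' selects the component count with the small-sample-corrected Akaike
#' criterion, and classifies the pattern: `single` when one component wins;
#' otherwise `bimodal` when the fitted curve shows two modes whose valley
#' drops below 80% of the lower mode height, else `single_with_shoulder`.
#'
#' @param chrom Baseline-corrected [chromatogram()].
#' @param max_components 1 or 2.
#' @param shape `"emg"` or `"gauss"`.
#' @param equal_width Constrain all components to a common width.
#' @param valley_frac Valley/lower-mode height ratio below which two modes
#'   count as resolved (default 0.8).
#' @param snr_min Minimum peak height in noise SD units to accept signal.
#' @param aicc_margin The 2-component model is selected only when its
#'   corrected Akaike score beats the single peak by at least this much,
#'   preventing noise-driven phantom components.
#' @return Object of class `peak_fit`: `peaks` (data.frame `rt`, `area`,
#'   `width`, `tailing`, in elution order), `pattern`, `fit_quality`
#'   (root-mean-square residual), `n_components_tested`, plus the source
#'   `run_id`/`marker_id`/`role`/`sample_id`.
#' @export
fit_peaks <- function(chrom, max_components = 2, shape = c("emg", "gauss"),
                      equal_width = FALSE, valley_frac = 0.8, snr_min = 5,
                      aicc_margin = 10) {
  stopifnot(inherits(chrom, "chromatogram"))
  shape <- match.arg(shape)
  max_components <- as.integer(max_components)
  stopifnot(max_components %in% 1:2)
  noise <- trace_noise(chrom)
  if (max(chrom$absorbance) <= max(snr_min * noise, 1e-9)) {
    stop_config("no peak: trace maximum below the detection threshold")
  }
  n <- length(chrom$time)
  fits <- list()
  for (k in seq_len(max_components)) {
    fits[[k]] <- fit_k_components(chrom, k, shape, equal_width)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop_config("peak fit failed to converge for all models")
  floor_sd <- max(noise, 1e-10 * max(chrom$absorbance))
  scores <- vapply(fits, function(f) aicc(f$rss, n, f$n_par, floor_sd), 0)
  # the richer model must beat the single peak by a decisive margin, and
  # negligible components (under 1% of the area) do not count as structure
  best <- fits[[1]]
  if (length(fits) > 1 && scores[2] < scores[1] - aicc_margin) {
    best <- fits[[2]]
    q2 <- best$unpack(best$par)
    if (min(q2$areas) / sum(q2$areas) < 0.01) best <- fits[[1]]
  }
  q <- best$unpack(best$par)

  if (best$k == 1) {
    pattern <- "single"
  } else {
    grid <- seq(min(chrom$time), max(chrom$time), length.out = 4000)
    curve <- best$model_at(best$par, grid)
    im <- which(diff(sign(diff(curve))) == -2) + 1
    im <- im[curve[im] > 0.02 * max(curve)]
    if (length(im) >= 2) {
      im <- im[order(curve[im], decreasing = TRUE)][1:2]
      lo <- min(im); hi <- max(im)
      valley <- min(curve[lo:hi])
      lower_mode <- min(curve[c(lo, hi)])
      pattern <- if (valley < valley_frac * lower_mode) "bimodal"
                 else "single_with_shoulder"
    } else {
      pattern <- "single_with_shoulder"
    }
  }

  ord <- order(q$mus)
  peaks <- data.frame(
    rt = vapply(ord, function(i) emg_apex(q$mus[i], q$sigmas[i], q$tau), 0),
    area = q$areas[ord],
    width = q$sigmas[ord],
    tailing = rep(q$tau, best$k))
  structure(list(peaks = peaks, pattern = pattern,
                 fit_quality = sqrt(best$rss / n),
                 n_components_tested = length(fits),
                 run_id = chrom$run_id, marker_id = chrom$marker_id,
                 role = chrom$role, sample_id = chrom$sample_id %||% NA),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("Peak fit [%s]: %d component(s), pattern '%s', RMS resid %.3g\n",
              x$marker_id, nrow(x$peaks), x$pattern, x$fit_quality))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Retention-time calibration from 0% and 100% controls
#'
#' Builds the affine standard curve `percent(rt) = 100 * (rt - rt_0) /
#' (rt_100 - rt_0)` from the dominant peak retention times of the fully
#' unmethylated and fully methylated control chromatograms of a run. Either
#' elution order is allowed.
#'
#' @param control_0,control_100 Baseline-corrected control chromatograms.
#' @param resolution_floor Minimum |rt_100 - rt_0| in minutes.
#' @return Object of class `calibration_curve`: `rt_0`, `rt_100`, `run_id`,
#'   `marker_id`.
#' @export
calibrate <- function(control_0, control_100, resolution_floor = 0.05) {
  rt0 <- dominant_rt(control_0)
  rt100 <- dominant_rt(control_100)
  if (abs(rt100 - rt0) < resolution_floor) {
    stop_config("controls are not resolved: |rt_100 - rt_0| = %.3g min",
                abs(rt100 - rt0))
  }
  structure(list(rt_0 = rt0, rt_100 = rt100,
                 run_id = control_0$run_id, marker_id = control_0$marker_id),
            class = "calibration_curve")
}

dominant_rt <- function(chrom) {
  fit <- fit_peaks(chrom, max_components = 1)
  fit$peaks$rt[which.max(fit$peaks$area)]
}

#' Evaluate a calibration curve
#'
#' @param cal A `calibration_curve`.
#' @param rt Retention time(s), minutes.
#' @return Methylation percent (unclamped; may fall outside \[0, 100\]).
#' @export
cal_percent <- function(cal, rt) {
  100 * (rt - cal$rt_0) / (cal$rt_100 - cal$rt_0)
}

#' Area-weighted methylation rate from a peak fit
#'
#' Each fitted component is mapped through the run calibration at its own
#' retention time; the sample's relative methylation rate is the
#' area-weighted mean of the per-component rates (the single-peak case
#' degenerates to the calibrated rate of that peak). Rates outside
#' \[0, 100\] are clamped to the boundary and flagged.
#'
#' @param fit A [fit_peaks()] result.
#' @param cal A [calibrate()] result from the same run and marker.
#' @return Object of class `methylation_rate`: `sample_id`, `marker_id`,
#'   `rate` (percent), `clamped`, `pattern`, `fit_quality`.
#' @export
methylation_rate <- function(fit, cal) {
  stopifnot(inherits(fit, "peak_fit"), inherits(cal, "calibration_curve"))
  if (!identical(fit$run_id, cal$run_id) ||
      !identical(fit$marker_id, cal$marker_id)) {
    stop_config("fit and calibration come from different runs or markers")
  }
  w <- fit$peaks$area / sum(fit$peaks$area)
  raw <- sum(w * cal_percent(cal, fit$peaks$rt))
  clamped <- raw < 0 || raw > 100
  structure(list(sample_id = fit$sample_id, marker_id = fit$marker_id,
                 rate = clamp(raw, 0, 100), clamped = clamped,
                 pattern = fit$pattern, fit_quality = fit$fit_quality),
            class = "methylation_rate")
}

#' Quantify every sample chromatogram in an HPLC run
#'
#' Groups chromatograms by marker, calibrates each marker from its own
#' 0%/100% control pair, deconvolves each sample trace and reports
#' calibrated area-weighted methylation rates.
#'
#' @param run An `hplc_run` (from [simulate_hplc_run()]) or a plain list of
#'   `chromatogram` objects.
#' @param baseline_window Passed to [correct_baseline()]; NULL skips
#'   baseline correction.
#' @param ... Passed to [fit_peaks()].
#' @return Data frame: `sample_id`, `marker_id`, `rate_percent`, `pattern`,
#'   `clamped`, `fit_quality`.
#' @export
quantify_run <- function(run, baseline_window = 0.5, ...) {
  chroms <- if (inherits(run, "hplc_run")) run$chromatograms else run
  if (!is.null(baseline_window)) {
    chroms <- lapply(chroms, correct_baseline, window = baseline_window)
  }
  markers <- unique(vapply(chroms, `[[`, "", "marker_id"))
  out <- NULL
  for (m in markers) {
    mc <- Filter(function(x) x$marker_id == m, chroms)
    roles <- vapply(mc, `[[`, "", "role")
    if (!any(roles == "control_0") || !any(roles == "control_100")) {
      stop_config("marker '%s' is missing a 0%% or 100%% control", m)
    }
    cal <- calibrate(mc[[which(roles == "control_0")[1]]],
                     mc[[which(roles == "control_100")[1]]])
    for (ch in mc[roles == "sample"]) {
      fit <- fit_peaks(ch, ...)
      mr <- methylation_rate(fit, cal)
      out <- rbind(out, data.frame(
        sample_id = mr$sample_id %||% NA_character_, marker_id = m,
        rate_percent = mr$rate, pattern = mr$pattern,
        clamped = mr$clamped, fit_quality = mr$fit_quality,
        stringsAsFactors = FALSE))
    }
  }
  out
}
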