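#' Chromatogram constructor
#'
#' A chromatogram is a (time, absorbance) trace from anion-exchange HPLC of
#' bisulfite-PCR products, detected by UV absorbance. Methylated and
#' unmethylated products elute at different retention times, so the trace
#' encodes the methylation level of the amplicon.
#'
#' @param time Strictly increasing time axis, minutes.
#' @param absorbance Signal, same length as `time`.
#' @param run_id,marker_id Identifiers linking samples to their control pair.
#' @param role One of `"sample"`, `"control_0"`, `"control_100"`.
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(time, absorbance, run_id = "run1",
                         marker_id = "marker1", role = "sample") {
  if (length(time) != length(absorbance)) {
    stop_config("time and absorbance must have equal length")
  }
  if (length(time) < 50) stop_config("a chromatogram needs >= 50 points")
  if (any(diff(time) <= 0)) stop_config("time must be strictly increasing")
  if (anyNA(time) || anyNA(absorbance)) {
    stop_config("chromatogram contains missing values")
  }
  role <- match.arg(role, c("sample", "control_0", "control_100"))
  structure(list(time = as.numeric(time), absorbance = as.numeric(absorbance),
                 run_id = run_id, marker_id = marker_id, role = role),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram [%s / %s / %s]: %d points, %.2f-%.2f min\n",
              x$run_id, x$marker_id, x$role, length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Specification for a simulated chromatogram
#'
#' The acquisition window defaults to the 10-minute elution gradient typical
#' of anion-exchange methylation assays. Each component is an exponentially
#' modified Gaussian peak whose retention time is placed by linear
#' interpolation between the retention times of the fully unmethylated (0%)
#' and fully methylated (100%) controls; either elution order is allowed.
#'
#' @param time_window Length-2 numeric, minutes.
#' @param sampling_rate Points per minute (default 120, about 2 Hz, enough
#'   to resolve shoulder patterns at default widths).
#' @param rt_unmeth,rt_meth Retention times (min) of the 0% and 100%
#'   methylated products; must differ and lie inside the window.
#' @param peak_width Gaussian width parameter sigma, minutes.
#' @param tailing EMG tail constant tau, minutes; 0 = symmetric Gaussian.
#' @param noise_sd Gaussian noise SD, absorbance units.
#' @param baseline Constant baseline offset.
#' @param drift Linear baseline drift, absorbance units per minute.
#' @param pattern Ground-truth pattern label: `"single"`, `"shoulder"` or
#'   `"bimodal"`; must be consistent with the number of components.
#' @param component_rates Two-column matrix-like (rate, weight): true
#'   methylation percent in \[0, 100\] and positive area weight per
#'   component.
#' @param seed Integer seed.
#' @return Object of class `chrom_spec`.
#' @export
chrom_spec <- function(time_window = c(0, 10), sampling_rate = 120,
                       rt_unmeth = 5, rt_meth = 7, peak_width = 0.15,
                       tailing = 0, noise_sd = 0.002, baseline = 0,
                       drift = 0, pattern = "single",
                       component_rates = cbind(rate = 50, weight = 1),
                       seed = 1L) {
  stopifnot(length(time_window) == 2, diff(time_window) > 0)
  check_number(sampling_rate, "sampling_rate", lower = 10)
  check_number(peak_width, "peak_width", lower = 1e-3)
  check_number(tailing, "tailing", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (rt_unmeth == rt_meth) stop_config("rt_unmeth must differ from rt_meth")
  for (rt in c(rt_unmeth, rt_meth)) {
    if (rt <= time_window[1] || rt >= time_window[2]) {
      stop_config("control retention times must lie inside the time window")
    }
  }
  pattern <- match.arg(pattern, c("single", "shoulder", "bimodal"))
  cr <- as.matrix(component_rates)
  if (ncol(cr) != 2) stop_config("component_rates needs columns (rate, weight)")
  colnames(cr) <- c("rate", "weight")
  if (any(cr[, "rate"] < 0 | cr[, "rate"] > 100)) {
    stop_config("component rates must lie in [0, 100]")
  }
  if (any(cr[, "weight"] <= 0)) stop_config("area weights must be positive")
  n_expected <- if (pattern == "single") 1L else 2L
  if (nrow(cr) != n_expected) {
    stop_config("pattern '%s' requires %d component(s), got %d",
                pattern, n_expected, nrow(cr))
  }
  structure(list(time_window = time_window, sampling_rate = sampling_rate,
                 rt_unmeth = rt_unmeth, rt_meth = rt_meth,
                 peak_width = peak_width, tailing = tailing,
                 noise_sd = noise_sd, baseline = baseline, drift = drift,
                 pattern = pattern, component_rates = cr,
                 seed = as.integer(seed)),
            class = "chrom_spec")
}

# Map a true methylation percent to a retention time under the linear
# simulation calibration.
rate_to_rt <- function(spec, rate) {
  spec$rt_unmeth + rate / 100 * (spec$rt_meth - spec$rt_unmeth)
}

#' Simulate one chromatogram
#'
#' Builds the trace as the sum of EMG component peaks (one per ground-truth
#' methylation component), a constant-plus-drift baseline, and Gaussian
#' noise. Component areas are proportional to the configured weights and sum
#' to 1 absorbance-minute before noise.
#'
#' @param spec A [chrom_spec()].
#' @param run_id,marker_id,role Metadata passed to [chromatogram()].
#' @return A `chromatogram` whose attribute `"truth"` records the component
#'   rates, weights and the area-weighted true methylation rate.
#' @export
#' @examples
#' tr <- simulate_chromatogram(chrom_spec(noise_sd = 0))
#' tr$time[which.max(tr$absorbance)] # near 6 min for a 50% component
simulate_chromatogram <- function(spec, run_id = "run1", marker_id = "marker1",
                                  role = "sample") {
  stopifnot(inherits(spec, "chrom_spec"))
  set.seed(spec$seed)
  time <- seq(spec$time_window[1], spec$time_window[2],
              by = 1 / spec$sampling_rate)
  cr <- spec$component_rates
  w <- cr[, "weight"] / sum(cr[, "weight"])
  signal <- numeric(length(time))
  for (i in seq_len(nrow(cr))) {
    signal <- signal + emg_profile(time, mu = rate_to_rt(spec, cr[i, "rate"]),
                                   sigma = spec$peak_width,
                                   tau = spec$tailing, area = w[i])
  }
  trace <- signal + spec$baseline + spec$drift * (time - time[1]) +
    stats::rnorm(length(time), 0, spec$noise_sd)
  out <- chromatogram(time, trace, run_id = run_id, marker_id = marker_id,
                      role = role)
  attr(out, "truth") <- list(
    pattern = spec$pattern,
    components = data.frame(rate = cr[, "rate"], weight = w,
                            rt = rate_to_rt(spec, cr[, "rate"])),
    rate = sum(w * cr[, "rate"])
  )
  out
}

#' Simulate a full HPLC run for a marker panel
#'
#' One run comprises, for every marker, the pair of fully unmethylated (0%)
#' and fully methylated (100%) control chromatograms plus one sample
#' chromatogram per sample, all sharing a run identifier so that samples can
#' be calibrated against their own controls.
#'
#' @param markers Character vector of marker identifiers (or a
#'   `marker_panel`, whose marker ids are used).
#' @param rates_by_sample Numeric matrix of true methylation percents,
#'   samples in rows (rownames = sample ids), markers in columns (colnames
#'   must cover `markers`).
#' @param spec A [chrom_spec()] providing window, controls, width, noise; its
#'   `pattern`/`component_rates` are ignored (each simulated trace is a
#'   single component at its true rate).
#' @param run_id Run identifier.
#' @return List of class `hplc_run`: elements `chromatograms` (list of
#'   `chromatogram`), `truth` (data.frame sample_id, marker_id, rate) and
#'   `run_id`.
#' @export
simulate_hplc_run <- function(markers, rates_by_sample, spec,
                              run_id = "run1") {
  if (inherits(markers, "marker_panel")) markers <- markers$entries$marker_id
  rates_by_sample <- as.matrix(rates_by_sample)
  if (is.null(rownames(rates_by_sample)) || is.null(colnames(rates_by_sample))) {
    stop_config("rates_by_sample needs sample rownames and marker colnames")
  }
  missing_m <- setdiff(markers, colnames(rates_by_sample))
  if (length(missing_m)) {
    stop_config("no rates supplied for marker(s): %s",
                paste(missing_m, collapse = ", "))
  }
  if (anyNA(rates_by_sample[, markers])) {
    stop_config("every sample needs a rate for every panel marker")
  }
  chroms <- list()
  truth <- NULL
  k <- 0L
  for (m in markers) {
    for (ctrl in c(0, 100)) {
      k <- k + 1L
      s <- spec
      s$pattern <- "single"
      s$component_rates <- cbind(rate = ctrl, weight = 1)
      s$seed <- child_seed(spec$seed, k)
      chroms[[k]] <- simulate_chromatogram(
        s, run_id = run_id, marker_id = m,
        role = if (ctrl == 0) "control_0" else "control_100")
    }
    for (sm in rownames(rates_by_sample)) {
      k <- k + 1L
      s <- spec
      s$pattern <- "single"
      s$component_rates <- cbind(rate = rates_by_sample[sm, m], weight = 1)
      s$seed <- child_seed(spec$seed, k)
      tr <- simulate_chromatogram(s, run_id = run_id, marker_id = m,
                                  role = "sample")
      tr$sample_id <- sm
      chroms[[k]] <- tr
      truth <- rbind(truth, data.frame(sample_id = sm, marker_id = m,
                                       rate = rates_by_sample[sm, m]))
    }
  }
  structure(list(chromatograms = chroms, truth = truth, run_id = run_id),
            class = "hplc_run")
}

#' @export
print.hplc_run <- function(x, ...) {
  roles <- vapply(x$chromatograms, `[[`, "", "role")
  cat(sprintf("HPLC run '%s': %d chromatograms (%d controls, %d samples)\n",
              x$run_id, length(roles), sum(roles != "sample"),
              sum(roles == "sample")))
  invisible(x)
}
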