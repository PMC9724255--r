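# Shared fixture builders. Everything is generated in code at test time.

small_cohort <- function(seed = 1, n_probes = 400, n_differential = 8,
                         group_sizes = c("NLT" = 10, "NASH-O" = 12,
                                         "NASH-W" = 8, "T" = 8), ...) {
  simulate_beta_cohort(cohort_config(group_sizes = group_sizes,
                                     n_probes = n_probes,
                                     n_differential = n_differential,
                                     seed = seed, ...))
}

# Manifest + beta matrix with prescribed low-call / sex-chromosome overlap,
# for exercising the probe filter arithmetic directly.
filter_fixture <- function(n, n_low, n_sex, n_both) {
  probe_id <- sprintf("p%06d", seq_len(n))
  chrom <- rep("1", n)
  call <- rep(0.99, n)
  low_only <- seq_len(n_low - n_both)
  sex_only <- seq(n_low - n_both + 1, length.out = n_sex - n_both)
  both <- seq(n_low + n_sex - 2 * n_both + 1, length.out = n_both)
  call[c(low_only, both)] <- 0.5
  chrom[c(sex_only, both)] <- "X"
  manifest <- data.frame(probe_id = probe_id, chromosome = chrom,
                         call_proportion = call)
  beta <- matrix(0.5, n, 2, dimnames = list(probe_id, c("s1", "s2")))
  list(beta = beta, manifest = manifest)
}

# Straight-line calibration object without going through control fits.
make_cal <- function(rt_0 = 5, rt_100 = 7, run_id = "run1",
                     marker_id = "marker1") {
  structure(list(rt_0 = rt_0, rt_100 = rt_100, run_id = run_id,
                 marker_id = marker_id),
            class = "calibration_curve")
}

# Brute-force AUC by pair enumeration (ties count one half).
auc_bruteforce <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(controls))
}

# Exhaustive Youden search over a dense threshold set.
youden_bruteforce <- function(cases, controls, direction) {
  vals <- sort(unique(c(cases, controls)))
  cand <- sort(unique(c(vals - 1e-9, vals + 1e-9,
                        (vals[-1] + vals[-length(vals)]) / 2)))
  best <- -Inf
  for (cut in cand) {
    if (direction == "hyper") {
      j <- mean(cases >= cut) + mean(controls < cut) - 1
    } else {
      j <- mean(cases <= cut) + mean(controls > cut) - 1
    }
    if (j > best) best <- j
  }
  best
}
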