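#' Configuration for a synthetic methylation-array cohort
#'
#' Describes a cohort of liver-tissue samples typed by disease stage together
#' with the planted differential-methylation structure. Group labels follow
#' the field's convention for NASH tissue studies: `NLT` (normal liver
#' tissue), `NAFL-O`/`NASH-O` (fatty liver / steatohepatitis without
#' hepatocellular carcinoma), `NAFL-W`/`NASH-W` (the same histologies from
#' patients in whom HCC has arisen) and `T` (tumour tissue). Differential
#' probes are planted as a signed shift of the group-mean beta value in the
#' `-W` groups relative to `NLT`, and that shift is inherited and optionally
#' strengthened in `T`, producing a monotone stage trend.
#'
#' @param group_sizes Named integer vector of samples per group. Defaults to
#'   the initial-cohort design of a typical NASH methylation study:
#'   36 NLT, 91 NASH-O, 22 NASH-W and 22 T samples (171 in total).
#' @param n_probes Total number of probes simulated.
#' @param n_differential Number of planted differential probes; half are
#'   hypermethylated and half hypomethylated in `-W` groups.
#' @param delta_planted Magnitude of the planted group-mean shift, in beta
#'   units. Sign per probe alternates hyper/hypo.
#' @param trend_gain Additional shift (same sign as the planted effect)
#'   applied in `T` relative to `NASH-W`, in beta units.
#' @param beta_precision Concentration parameter of the Beta noise
#'   distribution around each group mean; larger is less noisy. The default
#'   50 gives a within-group SD of roughly 0.07 at beta = 0.5, typical of
#'   array replicates.
#' @param frac_lowcall Fraction of probes flagged with a detection call
#'   proportion below 0.90 (default matches 751/485,764).
#' @param frac_sex Fraction of probes assigned to chromosomes X/Y (default
#'   matches 11,648/485,764).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c("NLT" = 36, "NASH-O" = 91,
                                          "NASH-W" = 22, "T" = 22),
                          n_probes = 10000L,
                          n_differential = 50L,
                          delta_planted = 0.3,
                          trend_gain = 0.1,
                          beta_precision = 50,
                          frac_lowcall = 751 / 485764,
                          frac_sex = 11648 / 485764,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop_config("`group_sizes` must be a named vector of group sample counts")
  }
  if (any(group_sizes <= 0) || any(group_sizes != round(group_sizes))) {
    stop_config("all referenced group sizes must be positive integers")
  }
  check_number(n_probes, "n_probes", lower = 1)
  check_number(n_differential, "n_differential", lower = 0, upper = n_probes)
  check_number(delta_planted, "delta_planted", lower = -1, upper = 1)
  check_number(trend_gain, "trend_gain", lower = -1, upper = 1)
  check_number(beta_precision, "beta_precision", lower = 1)
  check_fraction(frac_lowcall, "frac_lowcall")
  check_fraction(frac_sex, "frac_sex")
  check_number(seed, "seed")
  structure(list(group_sizes = group_sizes,
                 n_probes = as.integer(n_probes),
                 n_differential = as.integer(n_differential),
                 delta_planted = delta_planted,
                 trend_gain = trend_gain,
                 beta_precision = beta_precision,
                 frac_lowcall = frac_lowcall,
                 frac_sex = frac_sex,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Validation-cohort group sizes
#'
#' Convenience constant matching the 55-sample validation design (22 NLT,
#' 9 NAFL-O, 3 NASH-O, 10 NAFL-W, 11 NASH-W).
#' @return Named integer vector.
#' @export
validation_group_sizes <- function() {
  c("NLT" = 22L, "NAFL-O" = 9L, "NASH-O" = 3L, "NAFL-W" = 10L, "NASH-W" = 11L)
}

#' Simulate a beta-value cohort with planted differential probes
#'
#' Generates a probes x samples matrix of beta values in \[0, 1\] with a
#' probe manifest (chromosome, gene annotation, detection call proportion), a
#' sample annotation table (group, cohort, histology scores) and a
#' ground-truth table of planted effects. Group means of planted probes are
#' shifted by `delta_planted` in groups whose label ends in `-W` relative to
#' `NLT`, and by `delta_planted + trend_gain` in `T`; `-O` groups stay at the
#' `NLT` baseline, reflecting the observation that non-cancer-associated
#' tissue resembles normal liver at risk-marker sites. All group means are
#' clamped to \[0.01, 0.99\] before Beta noise is added.
#'
#' @param config A [cohort_config()].
#' @param cohort_name Cohort label written to the annotation table.
#' @return A list of class `beta_cohort` with elements `beta` (numeric
#'   matrix, probes x samples), `manifest` (data.frame), `annotation`
#'   (data.frame) and `truth` (data.frame of planted probes with signed
#'   effects).
#' @export
#' @examples
#' cohort <- simulate_beta_cohort(cohort_config(n_probes = 500, seed = 7))
#' dim(cohort$beta)
simulate_beta_cohort <- function(config, cohort_name = "initial") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  gs <- config$group_sizes
  n_samples <- sum(gs)
  n_probes <- config$n_probes

  probe_id <- sprintf("cg%08d", seq_len(n_probes))
  groups <- rep(names(gs), times = gs)
  sample_id <- sprintf("S%03d_%s", seq_len(n_samples), gsub("-", "", groups))

  # Manifest: sex-chromosome and low-call flags are disjoint draws so that
  # overlap statistics are exercised only when fractions are large.
  chrom <- sample(as.character(1:22), n_probes, replace = TRUE)
  n_sex <- round(config$frac_sex * n_probes)
  sex_idx <- if (n_sex > 0) sample.int(n_probes, n_sex) else integer(0)
  chrom[sex_idx] <- sample(c("X", "Y"), length(sex_idx), replace = TRUE,
                           prob = c(0.8, 0.2))
  n_low <- round(config$frac_lowcall * n_probes)
  low_idx <- if (n_low > 0) sample.int(n_probes, n_low) else integer(0)
  call_prop <- stats::runif(n_probes, 0.95, 1.0)
  call_prop[low_idx] <- stats::runif(length(low_idx), 0.50, 0.899)

  gene_pool <- c("ZC3H3", "STK17A", "APOM", "NRBF2", "ZSWIM6", "SLC45A3",
                 "NIPAL2", "FOXD4L1", "GPR125", "C7orf50", NA_character_)
  manifest <- data.frame(
    probe_id = probe_id,
    chromosome = chrom,
    gene_symbol = sample(gene_pool, n_probes, replace = TRUE),
    gene_region = sample(c("TSS1500", "TSS200", "Gene body", "1st intron",
                           NA_character_), n_probes, replace = TRUE),
    cpg_class = sample(c("Island", "N_shore", "S_shore", "N_shelf", "S_shelf",
                         "Open sea"), n_probes, replace = TRUE),
    call_proportion = call_prop,
    stringsAsFactors = FALSE
  )

  # Baseline per-probe means: bimodal mixture typical of array beta values.
  base_mean <- ifelse(stats::runif(n_probes) < 0.5,
                      stats::rbeta(n_probes, 2, 8),
                      stats::rbeta(n_probes, 8, 2))

  # Planted differential probes: autosomal, adequately called, with baseline
  # means leaving room for the shift. Alternating signs: hyper, hypo, ...
  eligible <- setdiff(seq_len(n_probes), union(sex_idx, low_idx))
  n_diff <- config$n_differential
  truth <- data.frame(probe_id = character(0), effect = numeric(0),
                      trend_gain = numeric(0))
  effects <- numeric(n_probes)
  if (n_diff > 0) {
    planted <- sample(eligible, n_diff)
    sgn <- rep_len(c(1, -1), n_diff) * sign(config$delta_planted %||% 1)
    if (config$delta_planted == 0) sgn <- rep_len(c(1, -1), n_diff)
    d <- abs(config$delta_planted)
    g <- abs(config$trend_gain)
    # keep baseline + full shift inside (0.05, 0.95)
    room <- d + g
    base_mean[planted] <- stats::runif(n_diff, 0.05 + ifelse(sgn < 0, room, 0),
                                       0.95 - ifelse(sgn > 0, room, 0))
    effects[planted] <- sgn * d
    truth <- data.frame(probe_id = probe_id[planted],
                        effect = sgn * d,
                        trend_gain = sgn * g,
                        stringsAsFactors = FALSE)
  }

  # Group mean per probe: -W groups shifted, T shifted + trend gain.
  shift_for_group <- function(gname) {
    if (gname == "T") {
      effects + sign(effects) * abs(config$trend_gain)
    } else if (grepl("-W$", gname)) {
      effects
    } else {
      numeric(n_probes)
    }
  }

  beta <- matrix(NA_real_, n_probes, n_samples,
                 dimnames = list(probe_id, sample_id))
  phi <- config$beta_precision
  for (gname in names(gs)) {
    cols <- which(groups == gname)
    mu <- clamp(base_mean + shift_for_group(gname), 0.01, 0.99)
    for (j in cols) {
      beta[, j] <- stats::rbeta(n_probes, mu * phi, (1 - mu) * phi)
    }
  }

  # Histology scores correlate with disease stage.
  ball_prob <- ifelse(groups %in% c("NLT"), 0.02,
               ifelse(grepl("-W$|^T$", groups), 0.8, 0.4))
  annotation <- data.frame(
    sample_id = sample_id,
    group = groups,
    cohort = cohort_name,
    ballooning = stats::rbinom(n_samples, 1, ball_prob),
    brunt_stage = ifelse(groups == "NLT", 0L,
                         pmin(4L, stats::rpois(n_samples, 1.5) +
                                as.integer(grepl("-W$|^T$", groups)))),
    stringsAsFactors = FALSE
  )

  structure(list(beta = beta, manifest = manifest, annotation = annotation,
                 truth = truth, config = config),
            class = "beta_cohort")
}

#' @export
print.beta_cohort <- function(x, ...) {
  cat("Synthetic beta-value cohort\n")
  cat(sprintf("  %d probes x %d samples (%d planted differential probes)\n",
              nrow(x$beta), ncol(x$beta), nrow(x$truth)))
  tab <- table(x$annotation$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
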