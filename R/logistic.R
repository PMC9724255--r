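#' Multivariate logistic model for coincidence of HCC
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome
#' (typically: tissue comes from a patient in whom HCC has arisen) on
#' hepatocyte ballooning (binary, from the NAFLD activity score), Brunt
#' fibrosis stage (ordinal, coded 0-4) and the methylation level of one
#' marker (continuous, beta or percent units). Reports per-term odds
#' ratios with Wald 95% confidence intervals and p values. Complete or
#' quasi-complete separation is detected and flagged; when flagged, a
#' profile-likelihood interval is reported instead of the (meaningless)
#' Wald interval.
#'
#' @param outcome Binary vector (0/1 or logical).
#' @param ballooning,brunt_stage,methylation Covariate vectors; any may be
#'   NULL to omit that term. Constant covariates are dropped with a
#'   warning.
#' @param conf_level Confidence level for intervals.
#' @return Object of class `risk_fit`: `terms` data frame (`term`,
#'   `coefficient`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`),
#'   `separation_flag`, `n`, `fit` (the underlying `glm`).
#' @export
#' @examples
#' set.seed(1)
#' meth <- c(rnorm(40, 0.3, 0.05), rnorm(40, 0.6, 0.05))
#' out <- rep(c(0, 1), each = 40)
#' multivariate_risk_model(out, methylation = meth)$terms
multivariate_risk_model <- function(outcome, ballooning = NULL,
                                    brunt_stage = NULL, methylation = NULL,
                                    conf_level = 0.95) {
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) stop_config("outcome must be binary")
  n_per_class <- table(factor(outcome, levels = c(0, 1)))
  if (any(n_per_class < 10)) {
    warning("fewer than 10 samples in an outcome class; estimates unstable")
  }
  covs <- list(ballooning = ballooning, brunt_stage = brunt_stage,
               methylation = methylation)
  covs <- covs[!vapply(covs, is.null, TRUE)]
  if (!length(covs)) stop_config("at least one covariate is required")
  keep <- vapply(covs, function(v) length(unique(v)) > 1, TRUE)
  if (any(!keep)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(names(covs)[!keep], collapse = ", ")))
    covs <- covs[keep]
    if (!length(covs)) stop_config("all covariates constant")
  }
  df <- data.frame(.outcome = outcome, covs)
  fml <- stats::as.formula(paste(".outcome ~", paste(names(covs),
                                                     collapse = " + ")))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coefs <- summary(fit)$coefficients
  est <- coefs[-1, 1]; se <- coefs[-1, 2]; p <- coefs[-1, 4]
  separation <- sep_warned || any(abs(est) > 15) || any(se > 100)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (separation) {
    ci <- suppressWarnings(suppressMessages(
      tryCatch(stats::confint(fit, level = conf_level)[-1, , drop = FALSE],
               error = function(e) cbind(est - z * se, est + z * se))))
  } else {
    ci <- cbind(est - z * se, est + z * se)
  }
  terms <- data.frame(term = names(covs),
                      coefficient = unname(est),
                      odds_ratio = exp(unname(est)),
                      ci_low = exp(unname(ci[, 1])),
                      ci_high = exp(unname(ci[, 2])),
                      p_value = unname(p),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, separation_flag = separation,
                 n = length(outcome), fit = fit),
            class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic risk model (n = %d)%s\n", x$n,
              if (x$separation_flag) " [separation detected]" else ""))
  tt <- x$terms
  tt$odds_ratio <- signif(tt$odds_ratio, digits)
  tt$ci_low <- signif(tt$ci_low, digits)
  tt$ci_high <- signif(tt$ci_high, digits)
  tt$p_value <- signif(tt$p_value, digits)
  print(tt[, c("term", "odds_ratio", "ci_low", "ci_high", "p_value")],
        row.names = FALSE)
  invisible(x)
}
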