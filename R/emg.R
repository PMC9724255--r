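# Chromatographic peak shape: exponentially modified Gaussian (EMG).
#
# Parameterised by the Gaussian centre mu (min), width sigma (min), the
# exponential tailing constant tau (min, >= 0) and the total area under the
# peak. tau -> 0 degenerates smoothly to a pure Gaussian; the crossover is
# handled explicitly to avoid the classical overflow of the naive
# exp() * erfc() formula (the erfcx-based form is numerically stable).

# Scaled complementary error function erfcx(x) = exp(x^2) erfc(x), patched
# with the asymptotic series for large x where the library form degrades to
# 0 * Inf.
erfcx_safe <- function(x) {
  out <- pracma::erfcx(x)
  big <- which(x > 25)
  if (length(big)) {
    x2 <- x[big]^2
    out[big] <- (1 - 1 / (2 * x2) + 3 / (4 * x2^2) - 15 / (8 * x2^3)) /
      (x[big] * sqrt(pi))
  }
  out
}

emg_profile <- function(t, mu, sigma, tau, area = 1) {
  stopifnot(sigma > 0, tau >= 0)
  if (tau < 1e-4 * sigma) {
    return(area * stats::dnorm(t, mu, sigma))
  }
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  g <- exp(-(t - mu)^2 / (2 * sigma^2))
  out <- numeric(length(t))
  pos <- z >= 0
  # exp(s^2/(2 tau^2) - (t-mu)/tau) * erfc(z) == erfcx(z) * g, stable for z >= 0
  out[pos] <- erfcx_safe(z[pos]) * g[pos] / (2 * tau)
  if (any(!pos)) {
    # far right tail: erfcx(z) overflows; use erfcx(z) = 2 exp(z^2) - erfcx(-z),
    # where exp(z^2) * g = exp(s^2/(2 tau^2) - (t-mu)/tau) stays bounded here
    e1 <- sigma^2 / (2 * tau^2) - (t[!pos] - mu) / tau
    out[!pos] <- exp(e1) / tau - erfcx_safe(-z[!pos]) * g[!pos] / (2 * tau)
  }
  area * pmax(out, 0)
}

# Apex (mode) retention time of one EMG component, found numerically on a
# fine grid around mu; for tau = 0 this is mu exactly.
emg_apex <- function(mu, sigma, tau) {
  if (tau < 1e-4 * sigma) return(mu)
  grid <- seq(mu - sigma, mu + 3 * (sigma + tau), length.out = 2001)
  grid[which.max(emg_profile(grid, mu, sigma, tau))]
}
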