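# Independent fixed-grid quadrature oracles, written before the package
# internals they check. The JZS oracle integrates the noncentral-t
# likelihood over the Cauchy effect-size prior via the angular
# substitution delta = scale * tan(theta) (so the Cauchy measure becomes
# flat) with a dense composite Simpson rule; the package's two-sided path
# instead integrates over the variance-scale parameter g and its
# one-sided path uses its own log-scale noncentral-t density, so the two
# routes share no code.

simpson <- function(f, lo, hi, n = 40001L) {
  x <- seq(lo, hi, length.out = n)
  h <- x[2] - x[1]
  w <- c(1, rep(c(4, 2), length.out = n - 2L), 1)
  w[n] <- 1
  sum(w * f(x)) * h / 3
}

oracle_jzs_bf <- function(t, n1, n2 = NULL, scale = 1, sided = "two") {
  if (is.null(n2)) {
    n_eff <- n1; df <- n1 - 1
  } else {
    n_eff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
  }
  lik <- function(theta) {
    suppressWarnings(stats::dt(t, df, ncp = scale * tan(theta) * sqrt(n_eff)))
  }
  num <- if (sided == "two") {
    simpson(lik, -pi / 2 + 1e-9, pi / 2 - 1e-9) / pi
  } else {
    2 * simpson(lik, 0, pi / 2 - 1e-9) / pi
  }
  num / stats::dt(t, df)
}

# Correlation BF oracle: dense Simpson over rho with the stretched-beta
# prior (uniform for kappa = 1), against the package's adaptive quadrature.
oracle_corr_bf <- function(r, n, kappa = 1) {
  a <- 1 / kappa
  f <- function(rho) {
    vapply(rho, function(p) {
      exp(switchbf:::log_corr_lik_ratio(p, r, n) +
            (a - 1) * log1p(-p^2) - (2 * a - 1) * log(2) - lbeta(a, a))
    }, numeric(1))
  }
  simpson(f, -1 + 1e-10, 1 - 1e-10)
}
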