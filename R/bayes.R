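# ---- JZS default-prior Bayes factors ---------------------------------------
#
# Two-sided BF10 is computed by Rouder et al.'s reduction: the marginal
# likelihood under H1 integrates the scaled t likelihood over the JZS
# prior on g (inverse-gamma(1/2, r^2/2)); the null likelihood is the
# central t term. One-sided BF10 integrates the noncentral-t likelihood
# directly over the (half-)Cauchy effect-size prior.

jzs_prior_g <- function(g, r) {
  r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
}

# Log density of the noncentral t distribution, stable over the whole
# range. Uses the exact integral representation
#   f(x; nu, mu) = C(x, nu) exp(-nu mu^2 / (2 (x^2+nu))) I(a, nu),
#   I(a, nu) = int_0^inf u^nu exp(-(u - a)^2 / 2) du,
#   a = x mu / sqrt(x^2 + nu),
# with I evaluated by quadrature around its peak on the log scale. R's
# stats::dt(ncp=) has an absolute error floor that swamps far-tail values;
# this form does not.
log_dnt <- function(x, df, ncp) {
  if (!is.finite(ncp)) return(-Inf)
  if (ncp == 0) return(stats::dt(x, df, log = TRUE))
  a <- x * ncp / sqrt(x^2 + df)
  u_star <- (a + sqrt(a^2 + 4 * df)) / 2
  log_h <- function(u) df * log(u) - (u - a)^2 / 2
  l_star <- log_h(u_star)
  width <- 1 / sqrt(df / u_star^2 + 1)
  lo <- max(0, u_star - 12 * width)
  hi <- u_star + 12 * width
  int <- stats::integrate(function(u) exp(log_h(u) - l_star), lo, hi,
                          rel.tol = 1e-10, abs.tol = 0)$value
  (df / 2) * log(df) + (1 - df) / 2 * log(2) - 0.5 * log(pi) -
    lgamma(df / 2) - (df + 1) / 2 * log(x^2 + df) -
    df * ncp^2 / (2 * (x^2 + df)) + l_star + log(int)
}

# BF10 for a t statistic; n2 = NULL means a one-sample design.
jzs_bf_t <- function(t, n1, n2 = NULL, scale = 1,
                     sided = c("two", "positive", "negative")) {
  sided <- match.arg(sided)
  if (is.null(n2)) {
    n_eff <- n1
    df <- n1 - 1
  } else {
    n_eff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  }
  if (df < 1) stop("not enough observations for a t-test", call. = FALSE)

  if (sided == "two") {
    # log-scale integrand to keep large-|t| cases stable
    log_lik1 <- function(g) {
      -0.5 * log1p(n_eff * g) -
        (df + 1) / 2 * log1p(t^2 / ((1 + n_eff * g) * df))
    }
    log_lik0 <- -(df + 1) / 2 * log1p(t^2 / df)
    num <- stats::integrate(function(g) {
      exp(log_lik1(g) - log_lik0) * jzs_prior_g(g, scale)
    }, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
    return(num)
  }

  # One-sided: truncate the Cauchy prior to the predicted direction.
  # Substituting delta = scale * tan(theta) maps the half-Cauchy measure to
  # the flat measure (2/pi) dtheta on (0, pi/2), keeping the domain finite;
  # the noncentral-t likelihood is evaluated on the log scale so extreme
  # wrong-direction statistics stay stable.
  sgn <- if (sided == "positive") 1 else -1
  log_g <- function(theta) {
    vapply(theta, function(th) {
      log_dnt(sgn * t, df, scale * tan(th) * sqrt(n_eff))
    }, numeric(1))
  }
  log_peak <- max(log_g(atan(max(0, sgn * t / sqrt(n_eff)) / scale)),
                  log_dnt(sgn * t, df, 0))
  int <- stats::integrate(function(theta) exp(log_g(theta) - log_peak),
                          0, pi / 2, rel.tol = 1e-9, abs.tol = 0,
                          subdivisions = 2000L)$value
  exp(log_peak + log(int * 2 / pi) - stats::dt(t, df, log = TRUE))
}

#' Jeffreys evidence category for a Bayes factor
#'
#' Maps BF10 to the conventional evidence labels: anecdotal (1..3),
#' substantial (3..10), strong (10..30), very strong (30..100) and
#' decisive (>100) for H1, with the reciprocal bands for H0. Boundary
#' values fall in the weaker category; BF10 = 1 is anecdotal with no
#' direction.
#'
#' @param bf10 Positive Bayes factor for H1 over H0.
#' @return A string such as `"H1: substantial"` or `"H0: strong"`.
#' @export
evidence_category <- function(bf10) {
  if (!is.finite(bf10) && !is.infinite(bf10)) {
    stop("bf10 must be a positive number", call. = FALSE)
  }
  if (bf10 <= 0) stop("bf10 must be positive", call. = FALSE)
  if (bf10 == 1) return("anecdotal")
  b <- max(bf10, 1 / bf10)
  strength <- if (b <= 3) "anecdotal" else if (b <= 10) "substantial"
    else if (b <= 30) "strong" else if (b <= 100) "very strong"
    else "decisive"
  paste0(if (bf10 > 1) "H1: " else "H0: ", strength)
}

#' Effect sizes from a two-sample t statistic
#'
#' @param t The t statistic.
#' @param n1,n2 Group sizes.
#' @return List with Cohen's `d` (`t * sqrt(1/n1 + 1/n2)`) and partial
#'   eta squared (`t^2 / (t^2 + n1 + n2 - 2)`).
#' @export
effect_sizes <- function(t, n1, n2) {
  list(d = t * sqrt(1 / n1 + 1 / n2),
       eta_partial = t^2 / (t^2 + n1 + n2 - 2))
}

bf_result <- function(bf10, direction, d, eta, n1, n2, statistic) {
  structure(list(bf10 = bf10, evidence = evidence_category(bf10),
                 direction = direction, d = d, eta_partial = eta,
                 n1 = n1, n2 = n2, statistic = statistic),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, digits = 3, ...) {
  cat(sprintf("BF10 = %s (%s)\n", format(x$bf10, digits = digits),
              x$evidence))
  if (!is.null(x$statistic)) {
    cat(sprintf("  %s = %.3f, n = %s\n", names(x$statistic),
                x$statistic,
                paste(c(x$n1, x$n2), collapse = "/")))
  }
  if (!is.null(x$d)) {
    cat(sprintf("  d = %.3f, partial eta^2 = %.4f\n", x$d, x$eta_partial))
  }
  invisible(x)
}

#' Two-sample JZS Bayes-factor t-test
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factor for a difference in
#' means, with a Cauchy prior of scale `scale` on the standardized effect
#' size. The two-sided factor integrates over the full prior;
#' `"positive"`/`"negative"` truncate it to the predicted direction
#' (positive means `mean(x) > mean(y)` under H1).
#'
#' @param x,y Numeric samples.
#' @param scale Cauchy prior scale (default 1, as used with high-powered
#'   sequential designs).
#' @param direction `"two"`, `"positive"` or `"negative"`.
#' @return A `bf_result` with `bf10`, the evidence category, Cohen's d
#'   and partial eta squared.
#' @export
jzs_bf_two_sample <- function(x, y, scale = 1,
                              direction = c("two", "positive",
                                            "negative")) {
  direction <- match.arg(direction)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    stop("degenerate input: zero variance in both samples", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  bf <- jzs_bf_t(t, n1, n2, scale, sided = direction)
  es <- effect_sizes(t, n1, n2)
  bf_result(bf, direction, es$d, es$eta_partial, n1, n2, c(t = t))
}

#' One-sample JZS Bayes-factor t-test
#'
#' Tests the mean against `mu` with a Cauchy prior of scale `scale` on
#' the standardized effect.
#'
#' @param x Numeric sample.
#' @param mu Null value (default 0).
#' @inheritParams jzs_bf_two_sample
#' @return A `bf_result`.
#' @export
jzs_bf_one_sample <- function(x, mu = 0, scale = 1,
                              direction = c("two", "positive",
                                            "negative")) {
  direction <- match.arg(direction)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  t <- (mean(x) - mu) / (stats::sd(x) / sqrt(n))
  bf <- jzs_bf_t(t, n, NULL, scale, sided = direction)
  d <- t / sqrt(n)
  bf_result(bf, direction, d, t^2 / (t^2 + n - 1), n, NULL, c(t = t))
}

# Log marginal likelihood ratio of a Pearson correlation r at population
# value rho (Jeffreys's exact sampling-distribution form, with the
# Gaussian hypergeometric term computed by series).
log_corr_lik_ratio <- function(rho, r, n) {
  (n - 1) / 2 * log1p(-rho^2) + (3 - 2 * n) / 2 * log1p(-rho * r) +
    log_hyp2f1_half(n, (rho * r + 1) / 2)
}

# log 2F1(1/2, 1/2; n - 1/2; z) for z in [0, 1)
log_hyp2f1_half <- function(n, z, max_iter = 5000, tol = 1e-14) {
  c0 <- n - 0.5
  term <- 1; s <- 1; k <- 0
  while (k < max_iter) {
    term <- term * (k + 0.5)^2 / ((k + c0) * (k + 1)) * z
    s <- s + term
    k <- k + 1
    if (term < tol * s) break
  }
  log(s)
}

#' Default Bayesian correlation test
#'
#' Bayes factor for a nonzero Pearson correlation with the stretched-beta
#' prior of width `kappa` on rho (width 1 is the uniform default).
#'
#' @param x,y Paired numeric samples (n >= 3).
#' @param kappa Prior width (default 1).
#' @return A `bf_result` whose `statistic` is the observed correlation.
#' @export
bayes_correlation_bf <- function(x, y, kappa = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant sample", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    return(bf_result(Inf, "two", NULL, NULL, n, NULL, c(r = r)))
  }
  a <- 1 / kappa
  # Beta(a, a) stretched to (-1, 1): (1 - rho^2)^(a-1) / (2^(2a-1) B(a, a))
  log_prior <- function(rho) {
    (a - 1) * log1p(-rho^2) - (2 * a - 1) * log(2) - lbeta(a, a)
  }
  bf <- stats::integrate(function(rho) {
    vapply(rho, function(p) {
      exp(log_corr_lik_ratio(p, r, n) + log_prior(p))
    }, numeric(1))
  }, -1, 1, rel.tol = 1e-10, abs.tol = 0)$value
  bf_result(bf, "two", NULL, NULL, n, NULL, c(r = r))
}

#' Exact power of an independent-samples t-test
#'
#' Noncentral-t power for a standardized mean difference `d` with
#' `n_per_group` per group.
#'
#' @param d True standardized effect size.
#' @param n_per_group Sample size per group.
#' @param alpha Significance level (default .05).
#' @param sided `"one"` or `"two"`.
#' @return Power in \[0, 1\].
#' @export
power_ttest <- function(d, n_per_group, alpha = 0.05,
                        sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (n_per_group < 2 || alpha <= 0 || alpha >= 1) {
    stop("need n_per_group >= 2 and 0 < alpha < 1", call. = FALSE)
  }
  if (d == 0 && sided == "one") return(alpha)
  stats::power.t.test(n = n_per_group, delta = d, sd = 1,
                      sig.level = alpha, type = "two.sample",
                      alternative = switch(sided, one = "one.sided",
                                           two = "two.sided"))$power
}
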