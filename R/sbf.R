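#' Specify a Sequential Bayes Factor sampling design
#'
#' A sequential plan that starts with `n_min` participants per group,
#' computes the default-prior (JZS) two-sample Bayes factor after every
#' additional `step` participants per group, stops as soon as BF10
#' crosses the `upper` or `lower` evidence boundary, and otherwise stops
#' at `n_max`, where the final BF is interpreted against the Jeffreys
#' thresholds (3 and 1/3 by default).
#'
#' @param n_min,n_max Minimum and maximum sample size per group
#'   (defaults 60 and 100).
#' @param upper,lower Stopping boundaries on BF10 (defaults 10 and 1/10).
#' @param step Participants added per group per look (default 1).
#' @param scale Cauchy prior scale of the BF (default 1).
#' @param d True standardized effect size of the data-generating model
#'   (group means d and 0, unit variance).
#' @param sided `"positive"` for the directional BF (H1 predicts the
#'   first group larger, the convention matching the printed operating
#'   characteristics; see the methods vignette) or `"two"`.
#' @param thresholds Terminal evidence thresholds at `n_max`
#'   (default `c(3, 1/3)`).
#' @return An object of class `sbf_design`.
#' @export
sbf_design <- function(n_min = 60, n_max = 100, upper = 10, lower = 1 / 10,
                       step = 1, scale = 1, d = 0.5,
                       sided = c("positive", "two"),
                       thresholds = c(3, 1 / 3)) {
  sided <- match.arg(sided)
  if (!(lower > 0 && lower < 1 && upper > 1)) {
    stop("boundaries must satisfy 0 < lower < 1 < upper", call. = FALSE)
  }
  if (n_min > n_max || n_min < 2 || step < 1) {
    stop("need 2 <= n_min <= n_max and step >= 1", call. = FALSE)
  }
  structure(list(n_min = n_min, n_max = n_max, upper = upper,
                 lower = lower, step = step, scale = scale, d = d,
                 sided = sided, thresholds = sort(thresholds,
                                                  decreasing = TRUE)),
            class = "sbf_design")
}

#' @export
print.sbf_design <- function(x, ...) {
  cat(sprintf("SBF design: n %d..%d per group (step %d), boundaries %g / %g\n",
              x$n_min, x$n_max, x$step, x$upper, x$lower))
  cat(sprintf("  JZS BF, Cauchy scale %g, %s-sided; true d = %g; terminal thresholds %g / %g\n",
              x$scale, x$sided, x$d, x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

sbf_looks <- function(design) {
  looks <- seq(design$n_min, design$n_max, by = design$step)
  if (looks[length(looks)] != design$n_max) looks <- c(looks, design$n_max)
  looks
}

#' Classify the terminal state of a sequential study
#'
#' @param final_bf BF10 at the stopping look.
#' @param design An `sbf_design`.
#' @param at_max_n Whether the study reached `n_max` without crossing a
#'   boundary.
#' @return One of `"hit_upper"`, `"hit_lower"`, `"max_n_evidence_h1"`,
#'   `"max_n_inconclusive"`, `"max_n_evidence_h0"`.
#' @export
classify_terminal <- function(final_bf, design, at_max_n) {
  if (final_bf <= 0) stop("final_bf must be positive", call. = FALSE)
  if (!at_max_n) {
    if (final_bf > design$upper) return("hit_upper")
    if (final_bf < design$lower) return("hit_lower")
    stop("study stopped before n_max without crossing a boundary",
         call. = FALSE)
  }
  if (final_bf > design$upper) return("hit_upper")
  if (final_bf < design$lower) return("hit_lower")
  if (final_bf > design$thresholds[1]) return("max_n_evidence_h1")
  if (final_bf < design$thresholds[2]) return("max_n_evidence_h0")
  "max_n_inconclusive"
}

TERMINAL_LEVELS <- c("hit_upper", "hit_lower", "max_n_evidence_h1",
                     "max_n_inconclusive", "max_n_evidence_h0")

pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Simulate a single sequential study with its full BF trajectory
#'
#' Draws `n_max` observations per group from Normal(d, 1) and
#' Normal(0, 1), then replays the sequential plan look by look, computing
#' the Bayes factor at each look until a boundary is crossed or `n_max`
#' is reached.
#'
#' @param design An `sbf_design`.
#' @param seed Optional seed.
#' @param data Optional list with numeric vectors `x` and `y` of length
#'   `n_max` (for replaying fixed data).
#' @return An object of class `sbf_outcome`: `terminal`, `stop_n`,
#'   `final_bf` and the `trajectory` data frame of (n, bf10).
#' @export
simulate_sbf_study <- function(design, seed = NULL, data = NULL) {
  stopifnot(inherits(design, "sbf_design"))
  if (is.null(data)) {
    data <- with_seed(seed, list(x = stats::rnorm(design$n_max, design$d, 1),
                                 y = stats::rnorm(design$n_max, 0, 1)))
  }
  looks <- sbf_looks(design)
  traj <- data.frame(n = integer(0), bf10 = numeric(0))
  for (n in looks) {
    t <- pooled_t(data$x[1:n], data$y[1:n])
    bf <- jzs_bf_t(t, n, n, design$scale,
                   sided = if (design$sided == "two") "two" else "positive")
    traj <- rbind(traj, data.frame(n = n, bf10 = bf))
    if (bf > design$upper || bf < design$lower || n == design$n_max) {
      terminal <- classify_terminal(bf, design,
                                    at_max_n = n == design$n_max &&
                                      bf <= design$upper &&
                                      bf >= design$lower)
      return(structure(list(terminal = terminal, stop_n = n,
                            final_bf = bf, trajectory = traj),
                       class = "sbf_outcome"))
    }
  }
}

#' @export
print.sbf_outcome <- function(x, ...) {
  cat(sprintf("SBF study: %s at n = %d/group, final BF10 = %.3g\n",
              x$terminal, x$stop_n, x$final_bf))
  invisible(x)
}

#' @export
plot.sbf_outcome <- function(x, ...) {
  graphics::plot(x$trajectory$n, x$trajectory$bf10, log = "y", type = "b",
                 xlab = "n per group", ylab = "BF10", ...)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}

.sbf_cache <- new.env(parent = emptyenv())

# Invert the BF to a t threshold at group size n: smallest t with
# bf10(t) = target (the BF is strictly increasing in t one-sided, and in
# |t| two-sided). Returns NA when the target is unreachable. Thresholds
# do not depend on the true effect, so they are cached per session.
sbf_t_threshold <- function(target, n, scale, sided) {
  key <- paste(format(target, digits = 12), n, scale, sided, sep = "|")
  if (!is.null(.sbf_cache[[key]])) return(.sbf_cache[[key]])
  .sbf_cache[[key]] <- sbf_t_threshold_impl(target, n, scale, sided)
  .sbf_cache[[key]]
}

sbf_t_threshold_impl <- function(target, n, scale, sided) {
  f <- function(t) {
    jzs_bf_t(t, n, n, scale,
             sided = if (sided == "two") "two" else "positive") - target
  }
  if (sided == "two") {
    if (f(0) >= 0) return(NA_real_)  # even t = 0 exceeds the target
    upr <- 10
    while (f(upr) < 0 && upr < 200) upr <- upr * 2
    return(stats::uniroot(f, c(0, upr), tol = 1e-8)$root)
  }
  lwr <- -10; upr <- 10
  while (f(lwr) > 0 && lwr > -200) lwr <- lwr * 2
  while (f(upr) < 0 && upr < 200) upr <- upr * 2
  if (f(lwr) > 0 || f(upr) < 0) return(NA_real_)
  stats::uniroot(f, c(lwr, upr), tol = 1e-8)$root
}

#' Monte-Carlo operating characteristics of an SBF design
#'
#' Runs `n_sims` simulated sequential studies and aggregates the five
#' terminal categories, the combined evidence proportions and the mean
#' stopping sample size. The engine inverts the Bayes factor once per
#' look into a t-statistic threshold and then runs all studies on
#' incremental sufficient statistics, so ten thousand simulations remain
#' desk-scale; single studies simulated with [simulate_sbf_study()]
#' follow the identical decision rule.
#'
#' @param design An `sbf_design`.
#' @param n_sims Number of simulated studies (default 10000).
#' @param seed Optional seed.
#' @return Object of class `sbf_design_analysis`: `proportions` over the
#'   five terminal categories, `evidence_h1` / `evidence_h0` (boundary
#'   hits plus terminal-threshold evidence), `mean_stop_n`, `stop_n` and
#'   `terminal` per study, `n_sims`, `seed` and the design.
#' @export
sbf_design_analysis <- function(design, n_sims = 10000, seed = NULL) {
  stopifnot(inherits(design, "sbf_design"), n_sims >= 1)
  looks <- sbf_looks(design)
  two <- design$sided == "two"
  t_up <- vapply(looks, function(n)
    sbf_t_threshold(design$upper, n, design$scale, design$sided),
    numeric(1))
  t_lo <- vapply(looks, function(n)
    sbf_t_threshold(design$lower, n, design$scale, design$sided),
    numeric(1))
  n_last <- design$n_max
  t_h1 <- sbf_t_threshold(design$thresholds[1], n_last, design$scale,
                          design$sided)
  t_h0 <- sbf_t_threshold(design$thresholds[2], n_last, design$scale,
                          design$sided)

  with_seed(seed, {
    X <- matrix(stats::rnorm(design$n_max * n_sims, design$d, 1),
                nrow = design$n_max)
    Y <- matrix(stats::rnorm(design$n_max * n_sims, 0, 1),
                nrow = design$n_max)
    terminal <- rep(NA_character_, n_sims)
    stop_n <- rep(design$n_max, n_sims)
    active <- rep(TRUE, n_sims)

    sx <- colSums(X[1:looks[1], , drop = FALSE])
    sxx <- colSums(X[1:looks[1], , drop = FALSE]^2)
    sy <- colSums(Y[1:looks[1], , drop = FALSE])
    syy <- colSums(Y[1:looks[1], , drop = FALSE]^2)

    for (i in seq_along(looks)) {
      n <- looks[i]
      if (i > 1) {
        add <- (looks[i - 1] + 1):n
        sx <- sx + colSums(X[add, , drop = FALSE])
        sxx <- sxx + colSums(X[add, , drop = FALSE]^2)
        sy <- sy + colSums(Y[add, , drop = FALSE])
        syy <- syy + colSums(Y[add, , drop = FALSE]^2)
      }
      if (!any(active)) next
      mx <- sx / n; my <- sy / n
      sp2 <- (sxx - n * mx^2 + syy - n * my^2) / (2 * n - 2)
      t <- (mx - my) / sqrt(sp2 * 2 / n)

      up_hit <- if (is.na(t_up[i])) rep(FALSE, n_sims)
                else if (two) abs(t) > t_up[i] else t > t_up[i]
      lo_hit <- if (is.na(t_lo[i])) rep(FALSE, n_sims)
                else if (two) abs(t) < t_lo[i] else t < t_lo[i]

      newly_up <- active & up_hit
      newly_lo <- active & !up_hit & lo_hit
      terminal[newly_up] <- "hit_upper"
      terminal[newly_lo] <- "hit_lower"
      stop_n[newly_up | newly_lo] <- n
      active <- active & !up_hit & !lo_hit

      if (n == design$n_max && any(active)) {
        h1 <- if (is.na(t_h1)) rep(FALSE, n_sims)
              else if (two) abs(t) > t_h1 else t > t_h1
        h0 <- if (is.na(t_h0)) rep(FALSE, n_sims)
              else if (two) abs(t) < t_h0 else t < t_h0
        terminal[active & h1] <- "max_n_evidence_h1"
        terminal[active & !h1 & h0] <- "max_n_evidence_h0"
        terminal[active & !h1 & !h0] <- "max_n_inconclusive"
        active <- rep(FALSE, n_sims)
      }
    }
    props <- as.numeric(table(factor(terminal, TERMINAL_LEVELS))) / n_sims
    names(props) <- TERMINAL_LEVELS
    structure(list(
      proportions = props,
      evidence_h1 = props[["hit_upper"]] + props[["max_n_evidence_h1"]],
      evidence_h0 = props[["hit_lower"]] + props[["max_n_evidence_h0"]],
      mean_stop_n = mean(stop_n),
      stop_n = stop_n, terminal = terminal,
      n_sims = n_sims, seed = seed, design = design),
      class = "sbf_design_analysis")
  })
}

#' @export
print.sbf_design_analysis <- function(x, ...) {
  cat(sprintf("SBF design analysis (%d simulations, true d = %g, %s-sided):\n",
              x$n_sims, x$design$d, x$design$sided))
  p <- x$proportions * 100
  cat(sprintf("  hit upper boundary (BF10 > %g): %5.1f%%\n",
              x$design$upper, p[["hit_upper"]]))
  cat(sprintf("  hit lower boundary (BF10 < %g): %5.1f%%\n",
              x$design$lower, p[["hit_lower"]]))
  cat(sprintf("  at n_max: evidence H1 %5.1f%%, inconclusive %5.1f%%, evidence H0 %5.1f%%\n",
              p[["max_n_evidence_h1"]], p[["max_n_inconclusive"]],
              p[["max_n_evidence_h0"]]))
  cat(sprintf("  total evidence for H1: %.1f%%; for H0: %.1f%%\n",
              100 * x$evidence_h1, 100 * x$evidence_h0))
  cat(sprintf("  mean stopping n per group: %.1f\n", x$mean_stop_n))
  invisible(x)
}

#' @export
summary.sbf_design_analysis <- function(object, ...) print(object, ...)

#' @export
plot.sbf_design_analysis <- function(x, ...) {
  graphics::hist(x$stop_n, breaks = seq(x$design$n_min - 0.5,
                                        x$design$n_max + 0.5, by = 1),
                 main = "Stopping sample size", xlab = "n per group", ...)
  invisible(x)
}
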