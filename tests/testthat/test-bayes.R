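test_that("the JZS engine matches the quadrature oracle on a (t, n) grid", {
  for (tt in c(0, 0.5, 1.3, 2, 2.739, 3.5, 5)) {
    for (nn in list(c(60, 60), c(30, 45), c(100, 100))) {
      for (r in c(1, sqrt(2) / 2)) {
        mine <- switchbf:::jzs_bf_t(tt, nn[1], nn[2], r, "two")
        ref <- oracle_jzs_bf(tt, nn[1], nn[2], r, "two")
        expect_lt(abs(mine - ref) / ref, 1e-6)
      }
    }
  }
  # one-sample route
  for (tt in c(0, 1.5, 3)) {
    mine <- switchbf:::jzs_bf_t(tt, 40, NULL, 1, "two")
    expect_lt(abs(mine - oracle_jzs_bf(tt, 40, NULL, 1, "two")) /
                mine, 1e-6)
  }
  # directional BFs against the oracle, and the exact sidedness identity
  for (tt in c(-2, -0.5, 0, 1, 2.5, 4)) {
    pos <- switchbf:::jzs_bf_t(tt, 60, 60, 1, "positive")
    neg <- switchbf:::jzs_bf_t(tt, 60, 60, 1, "negative")
    two <- switchbf:::jzs_bf_t(tt, 60, 60, 1, "two")
    expect_lt(abs(pos - oracle_jzs_bf(tt, 60, 60, 1, "positive")) / pos,
              1e-6)
    expect_lt(abs((pos + neg) / 2 - two) / two, 1e-8)
  }
})

test_that("BF10 is null-favouring at t = 0 and increases with |t| and prior concentration", {
  expect_lt(switchbf:::jzs_bf_t(0, 60, 60, 1, "two"), 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, function(t) switchbf:::jzs_bf_t(t, 60, 60, 1, "two"),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  # wider priors favour H0 more strongly at t = 0
  scales <- c(0.5, 0.707, 1, 1.5)
  bf0 <- vapply(scales, function(r) switchbf:::jzs_bf_t(0, 60, 60, r,
                                                        "two"), numeric(1))
  expect_true(all(diff(bf0) < 0))
})

test_that("sample-interface BF tests handle evidence and degenerate input", {
  set.seed(5)
  x <- rnorm(500, 1); y <- rnorm(500, 0)
  strong <- jzs_bf_two_sample(x, y)
  expect_gt(strong$bf10, 100)
  expect_match(strong$evidence, "decisive")
  expect_error(jzs_bf_two_sample(rep(1, 5), rep(2, 5)), "degenerate")

  null_bfs <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    jzs_bf_one_sample(rnorm(300))$bf10
  }, numeric(1))
  expect_gt(mean(null_bfs < 1 / 3), 0.8)
  set.seed(9)
  sig <- jzs_bf_one_sample(rnorm(100, 3, 1))
  expect_gt(sig$bf10, 100)
  expect_error(jzs_bf_one_sample(rep(2, 10)), "degenerate")
})

test_that("the Bayesian correlation test matches its oracle and limits", {
  set.seed(14)
  x <- rnorm(100); y <- rnorm(100)
  res <- bayes_correlation_bf(x, y)
  expect_lt(res$bf10, 1)
  expect_lt(abs(res$bf10 - oracle_corr_bf(res$statistic[["r"]], 100)) /
              res$bf10, 1e-5)
  z <- rnorm(60); w <- 0.6 * z + rnorm(60, 0, 0.6)
  res2 <- bayes_correlation_bf(z, w)
  expect_lt(abs(res2$bf10 - oracle_corr_bf(res2$statistic[["r"]], 60)) /
              res2$bf10, 1e-5)
  expect_gt(bayes_correlation_bf(z, z)$bf10, 100)
  expect_error(bayes_correlation_bf(z, rep(1, 60)), "degenerate")
})

test_that("evidence categories follow the Jeffreys bands with weak-side boundaries", {
  expect_equal(evidence_category(0.045), "H0: strong")
  expect_equal(evidence_category(5), "H1: substantial")
  expect_equal(evidence_category(150), "H1: decisive")
  expect_equal(evidence_category(1), "anecdotal")
  expect_equal(evidence_category(3), "H1: anecdotal")
  expect_equal(evidence_category(10), "H1: substantial")
  expect_equal(evidence_category(1 / 3), "H0: anecdotal")
  expect_equal(evidence_category(0.005), "H0: decisive")
  expect_error(evidence_category(0), "positive")
  expect_error(evidence_category(-2), "positive")
})

test_that("effect sizes follow their closed forms", {
  es0 <- effect_sizes(0, 60, 60)
  expect_equal(es0$d, 0)
  expect_equal(es0$eta_partial, 0)
  es <- effect_sizes(2, 60, 60)
  expect_equal(es$d, 2 * sqrt(1 / 30))
  expect_equal(es$eta_partial, 4 / (4 + 118))
  etas <- vapply(seq(0, 5, 0.5), function(t) {
    effect_sizes(t, 40, 50)$eta_partial
  }, numeric(1))
  expect_true(all(diff(etas) > 0))
})

test_that("noncentral-t power reproduces the design's power statements", {
  expect_equal(round(power_ttest(0.5, 60, 0.05, "one"), 2), 0.86)
  expect_equal(round(power_ttest(0.5, 73, 0.05, "one"), 2), 0.91)
  expect_equal(power_ttest(0, 60, 0.05, "one"), 0.05)
  expect_lt(power_ttest(0.5, 60, 0.05, "two"),
            power_ttest(0.5, 60, 0.05, "one"))
})
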