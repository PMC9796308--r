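test_that("the degenerate trial model is exactly linear", {
  p0 <- gen_params(base_rt = 500, spatial_advantage = 0,
                   congruency_slope = 0, bi_cost = 0, crs_cost = 0,
                   intercept_sd = 0, congruency_slope_sd = 0,
                   bi_cost_sd = 0, crs_cost_sd = 0, sigma = 0, tau = 0,
                   base_error_rate = 0, error_slope = 0)
  tr <- simulate_trial(0, "CBA", "ineligible", "colour", p0, seed = 1)
  expect_equal(tr$rt, 500)
  expect_true(tr$correct)

  p1 <- gen_params(base_rt = 500, spatial_advantage = 0,
                   congruency_slope = 20, bi_cost = 0, crs_cost = 0,
                   intercept_sd = 0, congruency_slope_sd = 0,
                   bi_cost_sd = 0, crs_cost_sd = 0, sigma = 0, tau = 0)
  expect_equal(simulate_trial(3, "CBA", "ineligible", "colour", p1,
                              seed = 1)$rt, 560)
  expect_error(simulate_trial(4, params = p0), "0..3")
  expect_error(simulate_trial(0, "CBA", "ineligible", "vertical",
                              gen_params(base_rt = 10,
                                         spatial_advantage = 50)),
               "mean RT")
})

test_that("parameter validation rejects impossible settings", {
  expect_error(gen_params(sigma = -1), "sd/tau")
  expect_error(gen_params(base_error_rate = 1.2), "base_error_rate")
  expect_error(simulate_participant("p1", "neither"), "pro")
})

test_that("a simulated session has the right structure and error rate", {
  p <- gen_params(base_error_rate = 0.1, error_slope = 0)
  tr <- simulate_participant("p1", "anti", mapping = 3, params = p,
                             seed = 21)
  expect_equal(nrow(tr), 448L)
  expect_equal(unique(tr$mapping), 3L)
  expect_equal(unique(tr$group), "anti")
  expect_true(all(tr$rt_ms > 0))
  expect_identical(tr$correct, tr$response_key == tr$correct_key)
  # error rate ~ Binomial(448, .1)
  expect_lt(abs(mean(!tr$correct) - 0.1), 4 * sqrt(0.1 * 0.9 / 448))
  expect_identical(tr, simulate_participant("p1", "anti", mapping = 3,
                                            params = p, seed = 21))
})

test_that("groups are balanced and mappings counterbalanced within group", {
  sim <- simulate_group(8, gen_params(), seed = 4,
                        n_blocks = 1, trials_per_block = 8)
  expect_equal(nrow(sim$trials), 2 * 8 * 8)
  per_part <- unique(sim$trials[c("participant", "group", "mapping")])
  expect_equal(as.integer(table(per_part$group)), c(8L, 8L))
  for (g in c("pro", "anti")) {
    expect_setequal(per_part$mapping[per_part$group == g], 1:8)
  }
  expect_equal(nrow(sim$questionnaires), 16L)
})

test_that("group effect sizes shift the anti group's effect parameters", {
  p <- gen_params(group_d = c(lin_cong = 0.5, bi = -0.2, crs = 0))
  pro <- switchbf:::group_effect_means(p, "pro")
  anti <- switchbf:::group_effect_means(p, "anti")
  expect_equal(pro$slope, 34)
  expect_equal(anti$slope, 34 + 0.5 * 283 / 10)
  expect_equal(anti$bi, 25 - 0.2 * 53)
  expect_equal(anti$crs, pro$crs)
})

test_that("generator effects are recovered by the index pipeline", {
  # moderate heterogeneity so the group mean pins down the truth quickly
  p <- gen_params(congruency_slope = 20, bi_cost = 30, crs_cost = 25,
                  congruency_slope_sd = 5, bi_cost_sd = 10,
                  crs_cost_sd = 15, base_error_rate = 0.05,
                  error_slope = 0.02)
  idx <- do.call(rbind, lapply(1:120, function(i) {
    tr <- simulate_participant(sprintf("p%03d", i), "pro",
                               mapping = (i - 1) %% 8 + 1, params = p,
                               seed = 3000 + i)
    compute_indices(classify_trials(tr))
  }))
  for (spec in list(list(col = "lin_cong_rt", truth = 200),
                    list(col = "bi_rt", truth = 30),
                    list(col = "crs_rt", truth = 25))) {
    v <- idx[[spec$col]]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - spec$truth), 3 * se)
  }
})

test_that("the questionnaire generator reproduces the FWI manipulation effect", {
  n <- 4000
  q <- switchbf:::with_seed(91, switchbf:::simulate_questionnaires(
    sprintf("p%04d", 1:(2 * n)), rep(c("pro", "anti"), each = n),
    gen_params(fwi_group_d = 0.70)))
  sc <- score_questionnaires(q)
  d_hat <- (mean(sc$fwi[sc$group == "pro"]) -
              mean(sc$fwi[sc$group == "anti"])) /
    sqrt((stats::var(sc$fwi[sc$group == "pro"]) +
            stats::var(sc$fwi[sc$group == "anti"])) / 2)
  expect_lt(abs(d_hat - 0.70), 0.08)
  expect_true(all(q[paste0("fwi_", 1:5)] >= 1 & q[paste0("fwi_", 1:5)] <= 7))
})
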