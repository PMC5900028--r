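noise_free <- function(co2 = 400, true_params = NULL, ...) {
  simulate_progressive_drying(drying_config(
    co2 = co2, true_params = true_params, gs_noise_sd = 0, pn_cv = 0,
    t_leaf_sd = 0, e_a_sd = 0, ...))
}

test_that("zero-noise data return the generating parameters exactly", {
  dat <- noise_free(400)
  fit <- fit_bb(dat, "modified")
  expect_true(fit$converged)
  expect_equal(unname(fit$estimate),
               c(33.43, 0.019, -1.98), tolerance = 1e-6)

  dat_o <- noise_free(400, true_params = tomato_params(400, "original"))
  fit_o <- fit_bb(dat_o, "original")
  expect_equal(unname(fit_o$estimate), c(26.85, -0.024), tolerance = 1e-6)
})

test_that("zero-noise recovery holds over random true parameters", {
  set.seed(11)
  for (i in 1:5) {
    truth <- bb_params(runif(1, 15, 50), runif(1, -0.02, 0.04),
                       beta = runif(1, -3, -0.5))
    dat <- noise_free(400, true_params = truth)
    fit <- fit_bb(dat, "modified")
    expect_equal(unname(fit$estimate), c(truth$slope, truth$g0, truth$beta),
                 tolerance = 1e-5)
  }
})

test_that("confidence intervals bracket the estimates and scale sanely", {
  dat <- simulate_progressive_drying(drying_config(co2 = 400, seed = 3))
  fit <- fit_bb(dat, "modified")
  expect_true(all(fit$ci_low < fit$estimate & fit$estimate < fit$ci_high))
  expect_equal(fit$n, 25)
  expect_true(fit$converged)
})

test_that("constant soil water potential makes beta unidentifiable", {
  dat <- simulate_progressive_drying(drying_config(co2 = 400, seed = 5))
  dat$psi_s_mpa <- -0.2
  expect_error(fit_bb(dat, "modified"), "rank-deficient")
})

test_that("modified fit to constant-slope wet-range data gives beta near 0", {
  truth <- tomato_params(400, "original")
  dat <- simulate_progressive_drying(drying_config(
    co2 = 400, true_params = truth, psi_start = -0.001, psi_final = -0.02,
    seed = 9))
  fit <- fit_bb(dat, "modified")
  expect_true(fit$ci_low[["beta"]] <= 0 && 0 <= fit$ci_high[["beta"]])
})

test_that("goodness metrics match hand-computed values", {
  g <- goodness(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g$mae, 1 / 3)
  expect_equal(g$rmse, sqrt(1 / 3))
  gid <- goodness(1:5, 1:5 + 0)
  expect_equal(gid$r2, 1)
  expect_equal(gid$mae, 0)
  expect_equal(gid$rmse, 0)
})

test_that("goodness properties: mae <= rmse, order and scale behaviour", {
  set.seed(4)
  o <- rnorm(50, 5); p <- o + rnorm(50, 0, 0.5)
  g <- goodness(o, p)
  expect_lte(g$mae, g$rmse)
  idx <- sample(50)
  g2 <- goodness(o[idx], p[idx])
  expect_equal(g[c("r2", "mae", "rmse")], g2[c("r2", "mae", "rmse")])
  # joint affine rescale: r2 invariant, mae/rmse scale linearly
  g3 <- goodness(3 * o + 1, 3 * p + 1)
  expect_equal(g3$r2, g$r2)
  expect_equal(g3$mae, 3 * g$mae)
  expect_equal(g3$rmse, 3 * g$rmse)
  expect_error(goodness(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(goodness(1:3, 1:4), "equal length")
})
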