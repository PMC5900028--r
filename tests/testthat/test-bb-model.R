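test_that("saturation vapour pressure follows the Magnus form", {
  expect_equal(saturation_vapor_pressure(0), 6.11)
  # frozen from high-precision evaluation of the formula at 20 C
  expect_equal(saturation_vapor_pressure(20), 23.3893564, tolerance = 1e-7)
  t <- seq(-5, 40, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(t)) > 0))
  expect_error(saturation_vapor_pressure(NA_real_), "finite")
  expect_error(saturation_vapor_pressure(-240), "-237.3")
})

test_that("leaf-surface CO2 drawdown is 1.37 P_n / g_b", {
  expect_equal(leaf_surface_co2(400, 0), 400)
  expect_equal(leaf_surface_co2(400, 15.3, 9.29), 397.7438, tolerance = 1e-6)
  expect_equal(leaf_surface_co2(800, 18.3, 9.29), 797.3015, tolerance = 1e-6)
  expect_error(leaf_surface_co2(1, 100, 0.1), "implausibly large")
  expect_error(leaf_surface_co2(-400, 0), "> 0")
})

test_that("leaf-surface humidity interpolates between air and saturation", {
  ei <- saturation_vapor_pressure(20)
  expect_equal(leaf_surface_humidity(0, 14, ei), 14 / ei)
  expect_equal(leaf_surface_humidity(9.29, 14, ei, g_b = 9.29),
               (14 / ei + 1) / 2)
  expect_equal(leaf_surface_humidity(9.29e6, 14, ei, g_b = 9.29), 1,
               tolerance = 1e-5)
  gs <- seq(0, 2, by = 0.05)
  h <- leaf_surface_humidity(gs, 14, ei)
  expect_true(all(diff(h) > 0))
  expect_true(all(h >= 14 / ei & h < 1))
  expect_error(leaf_surface_humidity(0.5, 25, ei), "supersaturation")
})

test_that("effective slope decays exponentially with soil water potential", {
  pm <- bb_params(33.43, 0.019, beta = -1.98)
  expect_equal(effective_slope(pm, 0), 33.43)
  expect_equal(effective_slope(pm, -0.53), 11.70544, tolerance = 1e-5)
  po <- bb_params(26.85, -0.024, variant = "original")
  expect_equal(effective_slope(po, c(0, -0.3, -2)), rep(26.85, 3))
  # with beta < 0 the slope shrinks as the soil dries
  psi <- seq(0, -0.6, by = -0.05)
  expect_true(all(diff(effective_slope(pm, psi)) < 0))
  expect_error(effective_slope(pm, 0.1), "<= 0")
  expect_error(bb_params(-1, 0), "> 0")
  expect_error(bb_params(10, 0, variant = "modified"), "beta")
})

test_that("quadratic conductance solution matches the fixed-point oracle", {
  g <- solve_gs(bb_params(33.43, 0.019, variant = "original"),
                p_n = 15.3, c_a = 400, t_leaf = 20, e_a = 14)
  expect_equal(g, gs_fixed_point(33.43, 0.019, 15.3, 400, 20, 14),
               tolerance = 1e-8)
  expect_equal(g, 0.831, tolerance = 1e-3)

  # zero Ball index: g_s is exactly the residual conductance
  expect_equal(solve_gs(bb_params(20, 0.019, variant = "original"),
                        p_n = 0, c_a = 400, t_leaf = 20, e_a = 14), 0.019)

  # infinite boundary layer: h_s -> e_a/e_i, C_s -> C_a
  big <- bb_constants(g_b = 1e9)
  ei <- saturation_vapor_pressure(20)
  closed <- 33.43 * 15.3 * (14 / ei) / 400 + 0.019
  expect_equal(solve_gs(bb_params(33.43, 0.019, variant = "original"),
                        15.3, 400, 20, 14, const = big),
               closed, tolerance = 1e-6)
})

test_that("solved conductance satisfies the Ball-Berry fixed point", {
  draws <- random_bb_draws(200)
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    ei <- saturation_vapor_pressure(d$t_leaf)
    ea <- d$ea_frac * ei
    res <- solve_gs(bb_params(d$m, d$g0, variant = "original"),
                    p_n = d$pn, c_a = d$ca, t_leaf = d$t_leaf, e_a = ea,
                    diagnostics = TRUE)
    if (!res$valid) next
    hs <- leaf_surface_humidity(res$g_s, ea, ei)
    rhs <- d$m * d$pn * hs / res$c_s + d$g0
    expect_lt(abs(res$g_s - rhs) / res$g_s, 1e-9)
    expect_true(hs > ea / ei && hs < 1)
  }
})

test_that("conductance is monotone in slope, photosynthesis and potential", {
  base <- function(m) solve_gs(bb_params(m, 0.01, variant = "original"),
                               10, 400, 20, 14)
  expect_true(all(diff(vapply(c(10, 20, 30, 40), base, numeric(1))) > 0))
  pm <- bb_params(33.43, 0.019, beta = -1.98)
  g_pn <- solve_gs(pm, p_n = c(2, 5, 10, 15), c_a = 400, t_leaf = 20,
                   e_a = 14, psi_s = -0.1)
  expect_true(all(diff(g_pn) > 0))
  g_psi <- solve_gs(pm, 10, 400, 20, 14, psi_s = c(0, -0.1, -0.3, -0.6))
  expect_true(all(diff(g_psi) < 0))
})

test_that("transpiration is the series-conductance vapour flux", {
  expect_equal(transpiration(0.831, 20, 14), 7.0702, tolerance = 1e-4)
  # linear in the vapour gradient at fixed conductances
  ei <- saturation_vapor_pressure(20)
  t1 <- transpiration(0.5, 20, ei - 2)
  t2 <- transpiration(0.5, 20, ei - 4)
  expect_equal(t2 / t1, 2, tolerance = 1e-12)
  expect_lt(transpiration(0.5, 20, ei - 1e-9), 1e-8)
  expect_error(transpiration(0, 20, 14), "> 0")
})

test_that("WUE times transpiration returns photosynthesis exactly", {
  tr <- transpiration(0.831, 20, 14)
  wue <- water_use_efficiency(15.3, tr)
  expect_equal(wue, 2.164, tolerance = 1e-3)
  expect_equal(wue * tr, 15.3, tolerance = 1e-12)
  expect_equal(water_use_efficiency(0, 5), 0)
  expect_error(water_use_efficiency(10, 0), "> 0")
})
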