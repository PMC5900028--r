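test_that("photosynthesis driver hits its calibration anchors", {
  expect_equal(generate_pn(0, co2 = 400), 15.3)
  expect_equal(generate_pn(0, co2 = 800), 18.3)
  expect_equal(generate_pn(-0.52, co2 = 400), 1.54, tolerance = 1e-6)
  expect_equal(generate_pn(-0.60, co2 = 800), 3.77, tolerance = 1e-6)
  expect_error(generate_pn(0.1), "<= 0")
  expect_error(generate_pn(0, co2 = 600), "400 or 800")
})

test_that("drying generator is deterministic and seed-separable", {
  a <- simulate_progressive_drying(drying_config(co2 = 400, seed = 21))
  b <- simulate_progressive_drying(drying_config(co2 = 400, seed = 21))
  expect_identical(a, b)
  c <- simulate_progressive_drying(drying_config(co2 = 400, seed = 22))
  # same deterministic driver schedule, different noise
  expect_equal(c$psi_s_mpa, a$psi_s_mpa)
  expect_false(any(c$gs_obs_mol_m2_s == a$gs_obs_mol_m2_s))
})

test_that("drying trajectory matches the reported dry-down", {
  dat <- simulate_progressive_drying(drying_config(co2 = 400))
  expect_equal(nrow(dat), 25)
  st <- attr(dat, "state")
  expect_equal(st$psi[1], -0.01, tolerance = 1e-9)
  expect_gt(st$psi[5], -0.65)
  expect_lt(st$psi[5], -0.45)
  expect_equal(st$pn[5] / st$pn[1], 0.10, tolerance = 0.02)
  # water balance: content change equals transpiration-driven loss
  cfg <- attr(dat, "config")
  expect_equal(diff(st$theta) * cfg$pot_volume_l, -st$loss_l[1:4],
               tolerance = 1e-12)
})

test_that("generated observations satisfy the schema invariants", {
  dat <- simulate_progressive_drying(drying_config(co2 = 800, seed = 2))
  expect_true(all(dat$psi_s_mpa <= 0))
  expect_true(all(dat$gs_obs_mol_m2_s > 0))
  expect_true(all(dat$e_a_hpa < saturation_vapor_pressure(dat$t_leaf_c)))
  pri <- simulate_split_root(split_root_config(co2 = 800,
                                               treatment = "PRI", seed = 2))
  expect_true(all(pri$psi_s_mpa <= 0))
  expect_true(all(pri$gs_obs_mol_m2_s > 0))
})

test_that("full irrigation keeps both columns effectively saturated", {
  fi <- simulate_split_root(split_root_config(co2 = 400, treatment = "FI"))
  st <- attr(fi, "state")
  expect_equal(nrow(fi), 48)
  expect_true(all(st$psi1 >= -0.001 & st$psi2 >= -0.001))
  expect_equal(max(st$cycles), 0)
})

test_that("deficit irrigation settles in the reported potential band", {
  di <- simulate_split_root(split_root_config(co2 = 400, treatment = "DI"))
  st <- attr(di, "state")
  expect_true(all(st$psi_mean >= -0.112 & st$psi_mean <= -0.0001))
  # both columns behave identically under even splitting
  expect_equal(st$theta1, st$theta2, tolerance = 1e-12)
})

test_that("partial root-zone drying alternates sides about five times", {
  pri <- simulate_split_root(split_root_config(co2 = 400, treatment = "PRI"))
  st <- attr(pri, "state")
  expect_true(max(st$cycles) >= 4 && max(st$cycles) <= 6)
  # the dry column approaches the retention-curve anchor, the wet stays wet
  expect_lt(min(c(st$psi1, st$psi2)), -0.25)
  wet_psi <- ifelse(st$wet_side == 1, st$psi1, st$psi2)
  expect_true(all(wet_psi >= -0.05))
  expect_equal(nrow(pri), 48)
})

test_that("split-root water balance conserves water day by day", {
  for (trt in c("FI", "DI", "PRI")) {
    d <- simulate_split_root(split_root_config(co2 = 400, treatment = trt))
    st <- attr(d, "state")
    cfg <- attr(d, "config")
    V <- cfg$column_volume_l
    n <- nrow(st)
    for (col in 1:2) {
      theta <- st[[paste0("theta", col)]]
      irr <- st[[paste0("irrigation", col)]]
      upt <- st[[paste0("uptake", col)]]
      drn <- st[[paste0("drainage", col)]]
      # theta[d+1] = theta[d] - uptake[d]/V + (irrigation - drainage)[d+1]/V
      lhs <- theta[2:n] * V
      rhs <- theta[1:(n - 1)] * V - upt[1:(n - 1)] + irr[2:n] - drn[2:n]
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("split-root generator is deterministic with shared schedules", {
  a <- simulate_split_root(split_root_config(treatment = "PRI", seed = 5))
  b <- simulate_split_root(split_root_config(treatment = "PRI", seed = 5))
  expect_identical(a, b)
  c <- simulate_split_root(split_root_config(treatment = "PRI", seed = 6))
  expect_equal(attr(c, "state"), attr(a, "state"))
  expect_false(any(c$gs_obs_mol_m2_s == a$gs_obs_mol_m2_s))
})

test_that("a tiny uptake scale never triggers a side switch", {
  cfg <- split_root_config(co2 = 400, treatment = "PRI")
  st <- ballberry:::split_root_trajectory(cfg, uptake_scale = 1e-7)
  expect_equal(max(st$cycles), 0)
  expect_true(all(st$wet_side == 1))
})

test_that("fits to default synthetic drying data recover the truth in CI", {
  truth <- tomato_params(400, "modified")
  tv <- c(truth$slope, truth$g0, truth$beta)
  hits <- matrix(FALSE, 10, 3)
  for (i in 1:10) {
    dat <- simulate_progressive_drying(drying_config(co2 = 400, seed = 30 + i))
    fit <- fit_bb(dat, "modified")
    hits[i, ] <- fit$ci_low < tv & tv < fit$ci_high
  }
  # 95% intervals: expect only occasional misses across ten replicates
  expect_true(all(colSums(hits) >= 8))
})
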