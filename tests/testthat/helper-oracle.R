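# Independent oracles used across test files.

# Damped fixed-point iteration for the conductance-humidity coupling:
# repeatedly substitute g_s into the leaf-surface humidity balance and the
# Ball-Berry relation until self-consistent. Written from the definitions,
# independently of the package's quadratic solution.
gs_fixed_point <- function(m, g0, pn, ca, t_leaf, ea, gb = 9.29,
                           start = 0.1, damp = 0.5, tol = 1e-12,
                           maxit = 100000) {
  ei <- 6.11 * 10^(7.5 * t_leaf / (t_leaf + 237.3))
  cs <- ca - 1.37 * pn / gb
  g <- start
  for (i in seq_len(maxit)) {
    hs <- (ea / ei + g / gb) / (1 + g / gb)
    gnew <- (1 - damp) * g + damp * (m * pn * hs / cs + g0)
    if (abs(gnew - g) < tol * max(1, abs(gnew))) return(gnew)
    g <- gnew
  }
  stop("fixed-point iteration did not converge")
}

# random valid driver/parameter draws for equivalence properties
random_bb_draws <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    m = runif(n, 5, 60),
    g0 = runif(n, -0.05, 0.08),
    pn = runif(n, 0.5, 25),
    ca = sample(c(400, 800), n, replace = TRUE),
    t_leaf = runif(n, 15, 30),
    ea_frac = runif(n, 0.3, 0.9)  # e_a as a fraction of e_i
  )
}

reference_param_rows <- list(
  list(co2 = 400, variant = "modified", slope = 33.43,
       slope_lo = 29.57, slope_hi = 37.29, g0 = 0.019,
       beta = -1.98, beta_lo = -2.86, beta_hi = -1.10),
  list(co2 = 800, variant = "modified", slope = 41.55,
       slope_lo = 37.02, slope_hi = 46.07, g0 = -0.004,
       beta = -2.07, beta_lo = -3.21, beta_hi = -0.93),
  list(co2 = 400, variant = "original", slope = 26.85,
       slope_lo = 23.53, slope_hi = 30.17, g0 = -0.024),
  list(co2 = 800, variant = "original", slope = 37.62,
       slope_lo = 33.96, slope_hi = 41.29, g0 = -0.085)
)

# one canonical observation row for forward-model tests
one_obs <- function(pn = 15.3, co2 = 400, t_leaf = 20, e_a = 14,
                    psi = -0.01) {
  data.frame(day = 1, unit_id = "p1", treatment = "drying", co2_ppm = co2,
             t_leaf_c = t_leaf, e_a_hpa = e_a, psi_s_mpa = psi,
             pn_umol_m2_s = pn)
}
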