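#' Photosynthesis driver for the synthetic experiments
#'
#' The generators treat net photosynthesis as a measured driver that
#' declines exponentially with soil drying: P_n = P_n_wet * exp(k * psi_s)
#' (psi_s <= 0), optionally with multiplicative Gaussian noise. Per CO2
#' level, `P_n_wet` is the well-watered rate and `k` is calibrated from the
#' well-watered and end-of-drying rates of a 5-day pot dry-down
#' (400 ppm: 15.3 -> 1.54 umol m-2 s-1 over delta-psi 0.52 MPa, k ~ 4.42;
#' 800 ppm: 18.3 -> 3.77 over 0.60 MPa, k ~ 2.63).
#'
#' @param psi_s Mean root-zone soil water potential, MPa (<= 0).
#' @param co2 400 or 800 (selects the default `pn_wet`/`k` pair).
#' @param cv Coefficient of variation of multiplicative Gaussian noise
#'   (0 = deterministic). Uses the current RNG state.
#' @param pn_wet,k Overrides for the well-watered rate and decay constant.
#' @return Net photosynthetic rate, umol m-2 s-1.
#' @examples
#' generate_pn(0, co2 = 400)       # 15.3
#' generate_pn(-0.52, co2 = 400)   # about 1.54
#' @export
generate_pn <- function(psi_s, co2 = 400, cv = 0, pn_wet = NULL, k = NULL) {
  if (any(psi_s > 0)) stop("`psi_s` must be <= 0", call. = FALSE)
  d <- pn_defaults(co2)
  if (is.null(pn_wet)) pn_wet <- d$pn_wet
  if (is.null(k)) k <- d$k
  pn <- pn_wet * exp(k * psi_s)
  if (cv > 0) pn <- pn * (1 + stats::rnorm(length(pn), 0, cv))
  pmax(pn, 1e-6)
}

pn_defaults <- function(co2) {
  co2 <- as.character(co2)
  anchors <- list(
    "400" = list(pn_wet = 15.3, pn_dry = 1.54, dpsi = 0.52),
    "800" = list(pn_wet = 18.3, pn_dry = 3.77, dpsi = 0.60)
  )
  if (!co2 %in% names(anchors))
    stop("`co2` must be 400 or 800", call. = FALSE)
  a <- anchors[[co2]]
  list(pn_wet = a$pn_wet, k = log(a$pn_wet / a$pn_dry) / a$dpsi)
}

tomato_param_sets <- function(co2, variant = c("modified", "original")) {
  variant <- match.arg(variant)
  co2 <- as.character(co2)
  sets <- list(
    "400" = list(modified = bb_params(33.43, 0.019, beta = -1.98),
                 original = bb_params(26.85, -0.024, variant = "original")),
    "800" = list(modified = bb_params(41.55, -0.004, beta = -2.07),
                 original = bb_params(37.62, -0.085, variant = "original"))
  )
  sets[[co2]][[variant]]
}

#' Reference parameter sets for the tomato experiments
#'
#' The fitted Ball-Berry parameter sets for greenhouse tomato at ambient
#' (400 ppm) and elevated (800 ppm) CO2, for both the original
#' (constant-slope) and the soil-water-modified model variant. These are the
#' default "true" parameters of the synthetic generators.
#'
#' @param co2 400 or 800.
#' @param variant `"modified"` or `"original"`.
#' @return A [bb_params()] object.
#' @examples
#' tomato_params(400, "modified")
#' @export
tomato_params <- function(co2 = 400, variant = c("modified", "original")) {
  tomato_param_sets(co2, match.arg(variant))
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Gaussian draws truncated below, by redraw
rtrunc_norm <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in which(x <= lower)) {
    while (x[i] <= lower) x[i] <- stats::rnorm(1, mean, sd)
  }
  x
}

#' Configuration for the progressive-drying experiment generator
#'
#' Describes a 5-day pot dry-down: plants in peat-filled pots with
#' irrigation withheld, gas exchange measured daily at midday. Soil water
#' declines by the leaf transpiration predicted from the forward model
#' itself, scaled by an effective-leaf-area constant that is auto-calibrated
#' so the noise-free trajectory reaches `psi_final` on the last day.
#'
#' @param co2 Growth and measurement CO2, 400 or 800 ppm.
#' @param days,plants Measurement days and plants (one leaf each):
#'   `days * plants` rows.
#' @param true_params Generating [bb_params()]; defaults to the modified
#'   tomato set for `co2`.
#' @param psi_start Soil water potential on day 1, MPa.
#' @param psi_final Noise-free day-`days` soil water potential, MPa
#'   (calibration target; defaults -0.53 at 400 ppm, -0.61 at 800 ppm).
#' @param pot_volume_l Pot volume, litres.
#' @param curve Substrate [retention_curve()] (default peat preset).
#' @param t_leaf_mean,t_leaf_sd Leaf temperature schedule, degrees C.
#' @param e_a_mean,e_a_sd Air vapour pressure schedule, hPa.
#' @param gs_noise_sd Additive Gaussian sd on observed conductance,
#'   mol m-2 s-1 (truncated > 0).
#' @param pn_cv Multiplicative Gaussian cv on observed photosynthesis.
#' @param seed RNG seed for the observation noise.
#' @return List of class `drying_config`.
#' @export
drying_config <- function(co2 = 400, days = 5, plants = 5,
                          true_params = NULL,
                          psi_start = -0.01, psi_final = NULL,
                          pot_volume_l = 1.5,
                          curve = retention_preset("peat"),
                          t_leaf_mean = 20, t_leaf_sd = 0.5,
                          e_a_mean = 14, e_a_sd = 1,
                          gs_noise_sd = 0.02, pn_cv = 0.05,
                          seed = 1L) {
  co2 <- as.numeric(co2)
  if (is.null(true_params)) true_params <- tomato_param_sets(co2, "modified")
  if (is.null(psi_final))
    psi_final <- if (co2 == 800) -0.61 else -0.53
  stopifnot(inherits(true_params, "bb_params"),
            inherits(curve, "retention_curve"),
            psi_start <= 0, psi_final < psi_start, days >= 2, plants >= 1)
  structure(list(co2 = co2, treatment = "drying", days = days,
                 plants = plants, true_params = true_params,
                 psi_start = psi_start, psi_final = psi_final,
                 pot_volume_l = pot_volume_l, curve = curve,
                 t_leaf_mean = t_leaf_mean, t_leaf_sd = t_leaf_sd,
                 e_a_mean = e_a_mean, e_a_sd = e_a_sd,
                 gs_noise_sd = gs_noise_sd, pn_cv = pn_cv,
                 seed = seed, const = bb_constants()),
            class = "drying_config")
}

# noise-free daily pot trajectory for a given uptake scale (L per unit T_r)
drying_trajectory <- function(cfg, uptake_scale) {
  curve <- cfg$curve
  theta <- theta_from_psi(curve, cfg$psi_start)
  days <- cfg$days
  out <- data.frame(day = seq_len(days), theta = NA_real_, psi = NA_real_,
                    pn = NA_real_, gs = NA_real_, tr = NA_real_,
                    loss_l = NA_real_)
  truncated <- FALSE
  for (d in seq_len(days)) {
    if (theta <= curve$theta_r + 1e-9) { truncated <- TRUE; break }
    psi <- psi_from_theta(curve, theta)
    pn <- generate_pn(psi, co2 = cfg$co2, cv = 0)
    gs <- solve_gs(cfg$true_params, p_n = pn, c_a = cfg$co2,
                   t_leaf = cfg$t_leaf_mean, e_a = cfg$e_a_mean,
                   psi_s = psi, const = cfg$const)
    # stomata effectively closed: no transpiration-driven loss
    tr <- if (is.na(gs) || gs <= 0) 0 else
      transpiration(gs, cfg$t_leaf_mean, cfg$e_a_mean, cfg$const)
    loss <- uptake_scale * tr
    out[d, ] <- c(d, theta, psi, pn, gs, tr, loss)
    theta <- theta - loss / cfg$pot_volume_l
  }
  attr(out, "truncated") <- truncated
  out
}

calibrate_drying_uptake <- function(cfg) {
  final_psi <- function(scale) {
    tr <- drying_trajectory(cfg, scale)
    if (attr(tr, "truncated") || anyNA(tr$psi)) return(-10)
    tr$psi[cfg$days]
  }
  gap <- function(scale) final_psi(scale) - cfg$psi_final
  upper <- 1e-3
  while (gap(upper) > 0 && upper < 1e3) upper <- upper * 4
  stats::uniroot(gap, c(1e-9, upper), tol = 1e-12)$root
}

#' Simulate a progressive soil-drying gas-exchange experiment
#'
#' Generates daily midday gas-exchange observations for `plants` potted
#' plants over `days` days without irrigation. The deterministic driver
#' schedule (soil water, photosynthesis decline, transpiration-driven water
#' loss) is identical across seeds; the seed controls only the observation
#' noise (leaf temperature, air vapour pressure, multiplicative P_n noise,
#' additive g_s noise). Observed conductance is the forward-model solution
#' at the observed drivers plus Gaussian noise truncated above zero, so
#' zero-noise runs are exactly reproducible by the fitting module.
#'
#' @param cfg A [drying_config()].
#' @return Observation data frame in the canonical gas-exchange schema, with
#'   attributes `state` (the noise-free daily pot trajectory, including the
#'   per-day water loss in litres), `uptake_scale`, and `config`.
#' @examples
#' dat <- simulate_progressive_drying(drying_config(co2 = 400))
#' range(dat$psi_s_mpa)
#' @export
simulate_progressive_drying <- function(cfg) {
  stopifnot(inherits(cfg, "drying_config"))
  scale <- calibrate_drying_uptake(cfg)
  state <- drying_trajectory(cfg, scale)
  if (attr(state, "truncated"))
    stop("pot water content reached the residual content; dry-down truncated",
         call. = FALSE)

  obs <- with_seed(cfg$seed, {
    rows <- vector("list", cfg$days)
    for (d in seq_len(cfg$days)) {
      np <- cfg$plants
      t_leaf <- rtrunc_norm(np, cfg$t_leaf_mean, cfg$t_leaf_sd)
      e_a <- rtrunc_norm(np, cfg$e_a_mean, cfg$e_a_sd, lower = 0)
      pn <- state$pn[d] * (1 + if (cfg$pn_cv > 0)
        stats::rnorm(np, 0, cfg$pn_cv) else numeric(np))
      pn <- pmax(pn, 1e-6)
      gs_true <- solve_gs(cfg$true_params, p_n = pn, c_a = cfg$co2,
                          t_leaf = t_leaf, e_a = e_a,
                          psi_s = state$psi[d], const = cfg$const)
      gs_obs <- rtrunc_norm_vec(gs_true, cfg$gs_noise_sd, lower = 0)
      rows[[d]] <- data.frame(
        day = d, unit_id = paste0("plant", seq_len(np)),
        treatment = "drying", co2_ppm = cfg$co2,
        t_leaf_c = t_leaf, e_a_hpa = e_a,
        psi_s_mpa = state$psi[d], pn_umol_m2_s = pn,
        gs_obs_mol_m2_s = gs_obs)
    }
    do.call(rbind, rows)
  })
  check_observations(obs, require_gs = TRUE)
  attr(obs, "state") <- state
  attr(obs, "uptake_scale") <- scale
  attr(obs, "config") <- cfg
  obs
}

# element-wise truncated additive noise around a vector of means
rtrunc_norm_vec <- function(mean, sd, lower = 0) {
  if (sd == 0) return(mean)
  vapply(mean, function(m) rtrunc_norm(1L, m, sd, lower = lower), numeric(1))
}

#' Configuration for the split-root irrigation experiment generator
#'
#' Describes a 40-day experiment on plants whose roots are divided between
#' two sand-filled soil columns, under one of three regimes:
#' \describe{
#'   \item{FI}{full irrigation — both columns refilled daily to the target
#'     water content (18 vol-%).}
#'   \item{PRI}{alternate partial root-zone irrigation — one column receives
#'     70% of the full-irrigation daily amount, the other dries until its
#'     water content falls to 6 vol-%, then the watered side is switched.}
#'   \item{DI}{deficit irrigation — the PRI amount split evenly between the
#'     two columns.}
#' }
#' Daily plant water uptake is the forward-model transpiration at the mean
#' root-zone water potential, scaled by an effective-leaf-area constant
#' auto-calibrated so a PRI run completes `target_cycles` drying/wetting
#' cycles over the `days`-day run. Uptake is split between columns
#' in proportion to their plant-available water. Columns drain to the
#' full-irrigation water content when over-filled.
#'
#' @param co2 400 or 800 ppm.
#' @param treatment `"FI"`, `"DI"` or `"PRI"`.
#' @param days Treatment duration, days.
#' @param n_measure_days Number of (evenly spaced) measurement days.
#' @param reps_per_day Plants measured per measurement day.
#' @param column_volume_l Volume of each soil column, litres.
#' @param curve Substrate [retention_curve()] (default sand preset).
#' @param theta_fi Full-irrigation target water content (fraction).
#' @param theta_switch PRI side-switch threshold water content (fraction).
#' @param pri_fraction PRI (and DI) irrigation as a fraction of the
#'   full-irrigation daily amount.
#' @param target_cycles Calibration target: PRI side switches over the run.
#' @param true_params,t_leaf_mean,t_leaf_sd,e_a_mean,e_a_sd,gs_noise_sd,pn_cv,seed
#'   As in [drying_config()].
#' @return List of class `split_root_config`.
#' @export
split_root_config <- function(co2 = 400, treatment = c("FI", "DI", "PRI"),
                              days = 40, n_measure_days = 24,
                              reps_per_day = 2, column_volume_l = 5,
                              curve = retention_preset("sand"),
                              theta_fi = 0.18, theta_switch = 0.06,
                              pri_fraction = 0.7, target_cycles = 5,
                              true_params = NULL,
                              t_leaf_mean = 20, t_leaf_sd = 0.5,
                              e_a_mean = 14, e_a_sd = 1,
                              gs_noise_sd = 0.02, pn_cv = 0.05,
                              seed = 1L) {
  treatment <- match.arg(treatment)
  co2 <- as.numeric(co2)
  if (is.null(true_params)) true_params <- tomato_param_sets(co2, "modified")
  stopifnot(inherits(true_params, "bb_params"),
            inherits(curve, "retention_curve"),
            theta_switch > curve$theta_r, theta_fi > theta_switch,
            theta_fi <= curve$theta_s, pri_fraction > 0, pri_fraction <= 1,
            days >= 2, n_measure_days >= 2, n_measure_days <= days)
  structure(list(co2 = co2, treatment = treatment, days = days,
                 n_measure_days = n_measure_days, reps_per_day = reps_per_day,
                 column_volume_l = column_volume_l, curve = curve,
                 theta_fi = theta_fi, theta_switch = theta_switch,
                 pri_fraction = pri_fraction, target_cycles = target_cycles,
                 true_params = true_params,
                 t_leaf_mean = t_leaf_mean, t_leaf_sd = t_leaf_sd,
                 e_a_mean = e_a_mean, e_a_sd = e_a_sd,
                 gs_noise_sd = gs_noise_sd, pn_cv = pn_cv,
                 seed = seed, const = bb_constants()),
            class = "split_root_config")
}

# transpiration-driven total daily uptake (litres) at mean potential
split_root_uptake <- function(cfg, psi_mean, uptake_scale) {
  pn <- generate_pn(psi_mean, co2 = cfg$co2, cv = 0)
  gs <- solve_gs(cfg$true_params, p_n = pn, c_a = cfg$co2,
                 t_leaf = cfg$t_leaf_mean, e_a = cfg$e_a_mean,
                 psi_s = psi_mean, const = cfg$const)
  if (is.na(gs) || gs <= 0) return(0)
  uptake_scale * transpiration(gs, cfg$t_leaf_mean, cfg$e_a_mean, cfg$const)
}

# deterministic daily state of one split-root pot; order each day:
# switch check (PRI) -> irrigate -> drain -> record -> uptake
split_root_trajectory <- function(cfg, uptake_scale,
                                  switching = TRUE) {
  curve <- cfg$curve
  V <- cfg$column_volume_l
  theta <- c(cfg$theta_fi, cfg$theta_fi)
  wet_side <- 1L
  cycles <- 0L
  # daily FI reference demand: wet-state uptake of a fully irrigated plant
  psi_wet0 <- psi_from_theta(curve, cfg$theta_fi)
  fi_amount <- split_root_uptake(cfg, psi_wet0, uptake_scale)

  out <- data.frame(day = seq_len(cfg$days), theta1 = NA_real_,
                    theta2 = NA_real_, psi1 = NA_real_, psi2 = NA_real_,
                    psi_mean = NA_real_, wet_side = NA_integer_,
                    cycles = NA_integer_, irrigation1 = NA_real_,
                    irrigation2 = NA_real_, uptake1 = NA_real_,
                    uptake2 = NA_real_, drainage1 = NA_real_,
                    drainage2 = NA_real_)
  for (d in seq_len(cfg$days)) {
    # PRI: switch sides once the drying column reaches the threshold
    if (cfg$treatment == "PRI" && switching &&
        theta[3L - wet_side] <= cfg$theta_switch + 1e-12) {
      wet_side <- 3L - wet_side
      cycles <- cycles + 1L
    }
    irr <- c(0, 0)
    if (cfg$treatment == "FI") {
      irr <- pmax(cfg$theta_fi - theta, 0) * V
    } else if (cfg$treatment == "PRI") {
      irr[wet_side] <- cfg$pri_fraction * fi_amount
    } else { # DI
      irr <- rep(cfg$pri_fraction * fi_amount / 2, 2)
    }
    theta <- theta + irr / V
    drain <- pmax(theta - cfg$theta_fi, 0) * V
    theta <- theta - drain / V
    if (any(theta > curve$theta_s + 1e-12))
      stop("irrigation exceeds pot capacity; infeasible configuration",
           call. = FALSE)
    psi <- psi_from_theta(curve, theta)
    psi_mean <- mean(psi)
    out[d, ] <- list(d, theta[1], theta[2], psi[1], psi[2], psi_mean,
                     wet_side, cycles, irr[1], irr[2], NA_real_, NA_real_,
                     drain[1], drain[2])
    # uptake after the midday measurement, split by plant-available water
    U <- split_root_uptake(cfg, psi_mean, uptake_scale)
    avail <- pmax(theta - curve$theta_r, 0)
    w <- if (sum(avail) > 0) avail / sum(avail) else c(0.5, 0.5)
    upt <- pmin(U * w, avail * V * 0.9)
    theta <- theta - upt / V
    out$uptake1[d] <- upt[1]; out$uptake2[d] <- upt[2]
  }
  attr(out, "fi_amount") <- fi_amount
  out
}

calibrate_split_root_uptake <- function(cfg) {
  pri_cfg <- cfg
  pri_cfg$treatment <- "PRI"
  target <- cfg$target_cycles
  n_cycles <- function(scale)
    max(split_root_trajectory(pri_cfg, scale)$cycles)
  # switch count is a monotone step function of the uptake scale: bracket
  # the target, then bisect onto its plateau
  lo <- 1e-6; hi <- 1e-3
  while (n_cycles(hi) < target && hi < 1e3) hi <- hi * 4
  if (n_cycles(hi) < target)
    stop("cannot reach the target PRI cycle count; infeasible configuration",
         call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (n_cycles(mid) < target) lo <- mid else hi <- mid
  }
  # hi is the smallest scale attaining >= target cycles; keep it only if it
  # lands exactly, otherwise take the closer side of the jump
  if (n_cycles(hi) == target) hi else lo
}

#' Simulate a split-root irrigation gas-exchange experiment
#'
#' Runs the two-compartment daily water balance for one irrigation regime
#' (see [split_root_config()]) and samples gas-exchange observations on
#' evenly spaced measurement days (`reps_per_day` plants per day, noise as
#' in [simulate_progressive_drying()]). The reported soil water potential is
#' the arithmetic mean of the two columns' potentials — the whole-root-zone
#' mean the conductance model responds to — recorded at measurement time,
#' after the morning irrigation.
#'
#' @param cfg A [split_root_config()].
#' @return Observation data frame in the canonical schema with attributes
#'   `state` (daily water balance: contents, potentials, irrigation, uptake,
#'   drainage, wet side and completed drying/wetting cycles), `uptake_scale`
#'   and `config`.
#' @examples
#' pri <- simulate_split_root(split_root_config(co2 = 400, treatment = "PRI"))
#' max(attr(pri, "state")$cycles)
#' @export
simulate_split_root <- function(cfg) {
  stopifnot(inherits(cfg, "split_root_config"))
  scale <- calibrate_split_root_uptake(cfg)
  state <- split_root_trajectory(cfg, scale)

  mdays <- unique(round(seq(1, cfg$days, length.out = cfg$n_measure_days)))
  obs <- with_seed(cfg$seed, {
    rows <- lapply(mdays, function(d) {
      np <- cfg$reps_per_day
      t_leaf <- rtrunc_norm(np, cfg$t_leaf_mean, cfg$t_leaf_sd)
      e_a <- rtrunc_norm(np, cfg$e_a_mean, cfg$e_a_sd, lower = 0)
      psi <- state$psi_mean[d]
      pn <- generate_pn(rep(psi, np), co2 = cfg$co2, cv = cfg$pn_cv)
      gs_true <- solve_gs(cfg$true_params, p_n = pn, c_a = cfg$co2,
                          t_leaf = t_leaf, e_a = e_a, psi_s = psi,
                          const = cfg$const)
      data.frame(day = d, unit_id = paste0("plant", seq_len(np)),
                 treatment = cfg$treatment, co2_ppm = cfg$co2,
                 t_leaf_c = t_leaf, e_a_hpa = e_a, psi_s_mpa = psi,
                 pn_umol_m2_s = pn,
                 gs_obs_mol_m2_s = rtrunc_norm_vec(gs_true, cfg$gs_noise_sd,
                                                   lower = 0))
    })
    do.call(rbind, rows)
  })
  check_observations(obs, require_gs = TRUE)
  attr(obs, "state") <- state
  attr(obs, "uptake_scale") <- scale
  attr(obs, "config") <- cfg
  obs
}
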