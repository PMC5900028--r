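#' Saturation vapour pressure at leaf temperature
#'
#' Magnus-type formula giving the saturation water vapour pressure inside the
#' leaf (`e_i`) as a function of leaf temperature.
#'
#' @param t_leaf Leaf temperature, degrees C. Vectorised.
#' @return Saturation vapour pressure, hPa.
#' @examples
#' saturation_vapor_pressure(20) # about 23.39 hPa
#' @export
saturation_vapor_pressure <- function(t_leaf) {
  if (!is.numeric(t_leaf) || any(!is.finite(t_leaf)))
    stop("`t_leaf` must be finite numeric", call. = FALSE)
  if (any(t_leaf <= -237.3))
    stop("`t_leaf` must exceed -237.3 C", call. = FALSE)
  6.11 * exp(7.5 * log(10) * t_leaf / (t_leaf + 237.3))
}

#' Leaf-surface CO2 mole fraction
#'
#' CO2 at the leaf surface is drawn down from the atmospheric value by net
#' assimilation across the boundary layer; 1.37 is the ratio of boundary-layer
#' diffusivities of water vapour and CO2.
#'
#' @param c_a Atmospheric CO2 mole fraction, umol mol-1.
#' @param p_n Net photosynthetic rate, umol m-2 s-1.
#' @param g_b Boundary-layer conductance, mol m-2 s-1.
#' @return Leaf-surface CO2, umol mol-1.
#' @examples
#' leaf_surface_co2(400, 15.3, 9.29)
#' @export
leaf_surface_co2 <- function(c_a, p_n, g_b = bb_constants()$g_b) {
  stopifnot(is.numeric(c_a), is.numeric(p_n), is.numeric(g_b))
  if (any(c_a <= 0)) stop("`c_a` must be > 0", call. = FALSE)
  if (any(g_b <= 0)) stop("`g_b` must be > 0", call. = FALSE)
  c_s <- c_a - 1.37 * p_n / g_b
  if (any(c_s <= 0))
    stop("leaf-surface CO2 <= 0: P_n implausibly large relative to g_b",
         call. = FALSE)
  c_s
}

#' Leaf-surface relative humidity
#'
#' The vapour pressure at the leaf surface sits between the air value and
#' leaf saturation, weighted by the stomatal and boundary-layer conductances
#' in series: h_s = (e_a/e_i + g_s/g_b) / (1 + g_s/g_b).
#'
#' @param g_s Stomatal conductance, mol m-2 s-1 (>= 0).
#' @param e_a Air vapour pressure, hPa.
#' @param e_i Saturation vapour pressure at leaf temperature, hPa.
#' @param g_b Boundary-layer conductance, mol m-2 s-1.
#' @return Relative humidity at the leaf surface, fraction in (e_a/e_i, 1).
#' @export
leaf_surface_humidity <- function(g_s, e_a, e_i, g_b = bb_constants()$g_b) {
  stopifnot(is.numeric(g_s), is.numeric(e_a), is.numeric(e_i))
  if (any(g_s < 0)) stop("`g_s` must be >= 0", call. = FALSE)
  if (any(e_a >= e_i))
    stop("supersaturation: `e_a` must be below `e_i`", call. = FALSE)
  if (any(e_a < 0)) stop("`e_a` must be >= 0", call. = FALSE)
  r <- g_s / g_b
  (e_a / e_i + r) / (1 + r)
}

#' Ball-Berry parameter set
#'
#' Holds the parameters of either the original Ball-Berry model (constant
#' slope `m`) or the soil-water-modified variant in which the slope decays
#' exponentially with the mean root-zone soil water potential:
#' m(psi) = m_i * exp(-beta * psi_s). With the typically fitted beta < 0 the
#' slope shrinks as the soil dries (psi_s more negative).
#'
#' @param slope Ball-Berry slope: `m` for the original variant, the
#'   zero-deficit initial slope `m_i` for the modified variant. Dimensionless,
#'   > 0.
#' @param g0 Residual (dark) stomatal conductance, mol m-2 s-1. May be
#'   negative, as empirical fits sometimes are.
#' @param beta Decay constant linking the slope to soil water potential,
#'   MPa-1. Required for (and only for) the modified variant.
#' @param variant `"original"` or `"modified"`.
#' @return An object of class `bb_params`.
#' @examples
#' bb_params(33.43, 0.019, beta = -1.98)            # modified
#' bb_params(26.85, -0.024, variant = "original")   # original
#' @export
bb_params <- function(slope, g0, beta = NULL,
                      variant = if (is.null(beta)) "original" else "modified") {
  variant <- match.arg(variant, c("original", "modified"))
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(g0), length(g0) == 1L, is.finite(g0))
  if (slope <= 0) stop("`slope` must be > 0", call. = FALSE)
  if (variant == "modified") {
    if (is.null(beta) || !is.finite(beta))
      stop("modified variant requires a finite `beta`", call. = FALSE)
    beta <- as.numeric(beta)
  } else {
    beta <- NULL
  }
  structure(list(variant = variant, slope = as.numeric(slope),
                 g0 = as.numeric(g0), beta = beta),
            class = "bb_params")
}

#' @export
print.bb_params <- function(x, ...) {
  if (x$variant == "original") {
    cat(sprintf("Ball-Berry model (original): m = %.4g, g0 = %.4g\n",
                x$slope, x$g0))
  } else {
    cat(sprintf(
      "Ball-Berry model (modified): m_i = %.4g, g0 = %.4g, beta = %.4g MPa-1\n",
      x$slope, x$g0, x$beta))
  }
  invisible(x)
}

#' Effective Ball-Berry slope at a given soil water potential
#'
#' @param params A [bb_params()] object.
#' @param psi_s Mean root-zone soil water potential, MPa (<= 0). Vectorised.
#' @return The slope used in the conductance equation: constant for the
#'   original variant, `m_i * exp(-beta * psi_s)` for the modified one.
#' @examples
#' effective_slope(bb_params(33.43, 0.019, beta = -1.98), -0.53)
#' @export
effective_slope <- function(params, psi_s) {
  stopifnot(inherits(params, "bb_params"), is.numeric(psi_s))
  if (any(psi_s > 0, na.rm = TRUE))
    stop("`psi_s` must be <= 0 (MPa)", call. = FALSE)
  if (params$variant == "original") {
    rep_len(params$slope, length(psi_s))
  } else {
    params$slope * exp(-params$beta * psi_s)
  }
}

#' Solve the Ball-Berry model for stomatal conductance
#'
#' The Ball-Berry relation g_s = m P_n h_s / C_s + g0 uses the leaf-surface
#' humidity h_s, which itself depends on g_s through the boundary layer.
#' Substituting the humidity balance into the relation yields a quadratic
#' A g_s^2 + B g_s + C = 0 with A = C_s/g_b,
#' B = C_s - g0 C_s/g_b - m P_n/g_b and C = -(g0 C_s + m P_n e_a/e_i);
#' the physically meaningful root is the "+sqrt" one.
#'
#' All driver arguments are vectorised and recycled to a common length.
#'
#' @param params A [bb_params()] object.
#' @param p_n Net photosynthetic rate, umol m-2 s-1.
#' @param c_a Atmospheric CO2, umol mol-1.
#' @param t_leaf Leaf temperature, degrees C.
#' @param e_a Air vapour pressure, hPa.
#' @param psi_s Mean root-zone soil water potential, MPa (<= 0); ignored by
#'   the original variant.
#' @param const A [bb_constants()] object.
#' @param diagnostics If `TRUE` return a data frame with the quadratic
#'   coefficients, discriminant, `c_s`, `e_i`, `h_s` and validity flag
#'   alongside `g_s`; otherwise just the conductance vector.
#' @return Stomatal conductance, mol m-2 s-1, or a diagnostics data frame.
#'   Records where the discriminant is negative or the root is non-positive
#'   are flagged `valid = FALSE` (the root value is still reported; it is
#'   `NA` when no real root exists).
#' @examples
#' p <- bb_params(33.43, 0.019, beta = -1.98)
#' solve_gs(p, p_n = 15.3, c_a = 400, t_leaf = 20, e_a = 14, psi_s = -0.01)
#' @export
solve_gs <- function(params, p_n, c_a, t_leaf, e_a, psi_s = 0,
                     const = bb_constants(), diagnostics = FALSE) {
  stopifnot(inherits(params, "bb_params"))
  const <- as_bb_constants(const)
  n <- max(length(p_n), length(c_a), length(t_leaf), length(e_a),
           length(psi_s))
  p_n <- rep_len(p_n, n); c_a <- rep_len(c_a, n)
  t_leaf <- rep_len(t_leaf, n); e_a <- rep_len(e_a, n)
  psi_s <- rep_len(psi_s, n)

  g_b <- const$g_b
  e_i <- saturation_vapor_pressure(t_leaf)
  if (any(e_a >= e_i))
    stop("supersaturation: `e_a` must be below saturation at leaf temperature",
         call. = FALSE)
  c_s <- leaf_surface_co2(c_a, p_n, g_b)
  m <- effective_slope(params, psi_s)
  g0 <- params$g0

  A <- c_s / g_b
  B <- c_s - g0 * c_s / g_b - m * p_n / g_b
  C <- -(g0 * c_s + m * p_n * e_a / e_i)
  disc <- B^2 - 4 * A * C

  g_s <- rep(NA_real_, n)
  ok <- disc >= 0
  g_s[ok] <- (-B[ok] + sqrt(disc[ok])) / (2 * A[ok])
  valid <- ok & !is.na(g_s) & g_s > 0

  if (!diagnostics) return(g_s)
  h_s <- rep(NA_real_, n)
  h_s[valid] <- leaf_surface_humidity(g_s[valid], e_a[valid], e_i[valid], g_b)
  data.frame(g_s = g_s, valid = valid, A = A, B = B, C = C,
             discriminant = disc, c_s = c_s, e_i = e_i, h_s = h_s)
}

#' Leaf transpiration rate
#'
#' Vapour flux through the stomatal and boundary-layer conductances in
#' series, driven by the leaf-to-air vapour pressure gradient expressed as a
#' mole fraction: T_r = (e_i - e_a) / (P_atm (1/g_s + 1/g_b)), reported in
#' mmol m-2 s-1.
#'
#' @param g_s Stomatal conductance, mol m-2 s-1 (> 0).
#' @param t_leaf Leaf temperature, degrees C.
#' @param e_a Air vapour pressure, hPa.
#' @param const A [bb_constants()] object.
#' @return Transpiration, mmol m-2 s-1.
#' @export
transpiration <- function(g_s, t_leaf, e_a, const = bb_constants()) {
  const <- as_bb_constants(const)
  if (any(g_s <= 0, na.rm = TRUE))
    stop("`g_s` must be > 0 for transpiration", call. = FALSE)
  e_i <- saturation_vapor_pressure(t_leaf)
  if (any(e_a > e_i)) stop("`e_a` must not exceed `e_i`", call. = FALSE)
  1000 * (e_i - e_a) / (const$p_atm * (1 / g_s + 1 / const$g_b))
}

#' Leaf water use efficiency
#'
#' @param p_n Net photosynthetic rate, umol m-2 s-1.
#' @param t_r Transpiration, mmol m-2 s-1 (> 0).
#' @return WUE = P_n / T_r, umol CO2 per mmol H2O.
#' @export
water_use_efficiency <- function(p_n, t_r) {
  if (any(t_r <= 0, na.rm = TRUE))
    stop("`t_r` must be > 0 for WUE", call. = FALSE)
  p_n / t_r
}
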