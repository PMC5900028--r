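#' Van Genuchten soil water retention curve
#'
#' Monotone mapping between volumetric water content theta and soil water
#' potential psi (MPa, <= 0):
#' psi(theta) = -(1/alpha) * (S^(-1/m_vg) - 1)^(1/n_vg) with
#' S = (theta - theta_r)/(theta_s - theta_r) and m_vg = 1 - 1/n_vg.
#' The inverse is closed-form, so theta -> psi -> theta round-trips exactly.
#'
#' @param theta_r,theta_s Residual and saturated volumetric water content,
#'   fraction, 0 <= theta_r < theta_s.
#' @param alpha Inverse air-entry pressure, MPa-1 (> 0).
#' @param n_vg Shape parameter (> 1).
#' @param soil Optional label (`"peat"`, `"sand"`, ...).
#' @return Object of class `retention_curve`.
#' @seealso [retention_preset()] for curves calibrated to the two
#'   experimental substrates.
#' @export
retention_curve <- function(theta_r, theta_s, alpha, n_vg, soil = "custom") {
  stopifnot(theta_r >= 0, theta_s > theta_r, alpha > 0, n_vg > 1)
  structure(list(soil = soil, theta_r = theta_r, theta_s = theta_s,
                 alpha = alpha, n_vg = n_vg),
            class = "retention_curve")
}

#' @export
print.retention_curve <- function(x, ...) {
  cat(sprintf(
    "Retention curve (%s): theta_r = %.3f, theta_s = %.3f, alpha = %.4g MPa-1, n = %.4g\n",
    x$soil, x$theta_r, x$theta_s, x$alpha, x$n_vg))
  invisible(x)
}

#' Soil water potential from water content, and its inverse
#'
#' @param curve A [retention_curve()].
#' @param theta Volumetric water content, fraction in (theta_r, theta_s].
#' @param psi Soil water potential, MPa (<= 0).
#' @return `psi_from_theta()` returns psi in MPa; `theta_from_psi()` returns
#'   theta.
#' @export
psi_from_theta <- function(curve, theta) {
  stopifnot(inherits(curve, "retention_curve"))
  if (any(theta <= curve$theta_r) || any(theta > curve$theta_s))
    stop("`theta` outside (theta_r, theta_s]", call. = FALSE)
  m_vg <- 1 - 1 / curve$n_vg
  S <- (theta - curve$theta_r) / (curve$theta_s - curve$theta_r)
  -(1 / curve$alpha) * (S^(-1 / m_vg) - 1)^(1 / curve$n_vg)
}

#' @rdname psi_from_theta
#' @export
theta_from_psi <- function(curve, psi) {
  stopifnot(inherits(curve, "retention_curve"))
  if (any(psi > 0)) stop("`psi` must be <= 0 (MPa)", call. = FALSE)
  m_vg <- 1 - 1 / curve$n_vg
  S <- (1 + (curve$alpha * abs(psi))^curve$n_vg)^(-m_vg)
  curve$theta_r + S * (curve$theta_s - curve$theta_r)
}

#' Retention-curve presets for the two experimental substrates
#'
#' The peat substrate (1.5 L pots, progressive drying) and the sandy soil
#' (10 L split-root pots) are represented by van Genuchten curves calibrated
#' so that each passes through two (theta, psi) anchor points characteristic
#' of the substrate:
#' \describe{
#'   \item{peat}{theta = 0.50 at psi = -0.01 MPa (wet pot at the start of
#'     drying) and theta = 0.15 at psi = -0.55 MPa (endpoint of a 5-day
#'     dry-down).}
#'   \item{sand}{theta = 0.18 at psi = -0.0008 MPa (the full-irrigation
#'     target water content) and theta = 0.06 at psi = -0.398 MPa (the
#'     partial root-zone drying switch threshold).}
#' }
#' Calibration solves for (alpha, n_vg) by 1-D root finding on the ratio of
#' the two anchor equations; residual/saturated contents are fixed per
#' substrate (peat: 0.10/0.60; sand: 0.045/0.38).
#'
#' @param soil `"peat"` or `"sand"`.
#' @return A [retention_curve()].
#' @examples
#' psi_from_theta(retention_preset("sand"), 0.06) # about -0.398 MPa
#' @export
retention_preset <- function(soil = c("peat", "sand")) {
  soil <- match.arg(soil)
  a <- retention_anchors[[soil]]
  calibrate_retention(theta_anchor = a$theta, psi_anchor = a$psi,
                      theta_r = a$theta_r, theta_s = a$theta_s, soil = soil)
}

# anchor definitions live in data, not code paths
retention_anchors <- list(
  peat = list(theta = c(0.50, 0.15), psi = c(-0.01, -0.55),
              theta_r = 0.10, theta_s = 0.60),
  sand = list(theta = c(0.18, 0.06), psi = c(-0.0008, -0.398),
              theta_r = 0.045, theta_s = 0.38)
)

#' Calibrate a van Genuchten curve through two anchor points
#'
#' Given fixed theta_r/theta_s and two (theta, psi) anchors, finds the
#' (alpha, n_vg) pair whose curve passes through both. The n_vg search uses
#' the alpha-free ratio of the two anchor equations.
#'
#' @param theta_anchor,psi_anchor Length-2 vectors of matching anchors
#'   (psi < 0).
#' @param theta_r,theta_s Fixed residual/saturated contents.
#' @param soil Label for the resulting curve.
#' @return A [retention_curve()].
#' @export
calibrate_retention <- function(theta_anchor, psi_anchor, theta_r, theta_s,
                                soil = "custom") {
  stopifnot(length(theta_anchor) == 2L, length(psi_anchor) == 2L,
            all(psi_anchor < 0), all(theta_anchor > theta_r),
            all(theta_anchor < theta_s))
  S <- (theta_anchor - theta_r) / (theta_s - theta_r)
  target <- log(abs(psi_anchor[1]) / abs(psi_anchor[2]))
  ratio_gap <- function(n_vg) {
    m_vg <- 1 - 1 / n_vg
    f <- (S^(-1 / m_vg) - 1)^(1 / n_vg)
    log(f[1] / f[2]) - target
  }
  n_vg <- stats::uniroot(ratio_gap, c(1.01, 25), tol = 1e-12)$root
  m_vg <- 1 - 1 / n_vg
  alpha <- (S[1]^(-1 / m_vg) - 1)^(1 / n_vg) / abs(psi_anchor[1])
  retention_curve(theta_r, theta_s, alpha, n_vg, soil = soil)
}
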