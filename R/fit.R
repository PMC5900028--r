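#' Fit the Ball-Berry model to observed conductance by nonlinear least squares
#'
#' Minimises the sum of squared differences between observed stomatal
#' conductance and the quadratic forward solution over (m, g0) for the
#' original variant or (m_i, g0, beta) for the modified variant, by
#' Levenberg-Marquardt least squares with a small deterministic multi-start
#' (3 initial points) to guard against local minima. 95% confidence bounds
#' are asymptotic Wald intervals: t-quantile at df = n - p with parameter
#' covariance sigma^2 (J'J)^-1 from a central-difference Jacobian at the
#' optimum.
#'
#' Observations for which the forward model yields no positive real root are
#' excluded from the residual sum; their count is reported in
#' `n_invalid_pred`.
#'
#' @param data Observation table (see [predict_bb()]) with finite positive
#'   `gs_obs_mol_m2_s`; at least 5 rows.
#' @param variant `"original"` or `"modified"`.
#' @param init Optional [bb_params()] giving the starting point; defaults to
#'   m = 10, g0 = 0.01 (and beta = -1 for the modified variant).
#' @param const A [bb_constants()] object.
#' @return An object of class `bb_fit`: list with `params` ([bb_params()]
#'   estimates), `estimate`, `se`, `ci_low`, `ci_high` (named vectors), `n`,
#'   `n_invalid_pred`, `rss`, `sigma`, `converged`, `n_iter`, `variant`.
#' @examples
#' cfg <- drying_config(co2 = 400, gs_noise_sd = 0, pn_cv = 0,
#'                      t_leaf_sd = 0, e_a_sd = 0)
#' dat <- simulate_progressive_drying(cfg)
#' fit_bb(dat, "modified")  # recovers the generating parameters
#' @export
fit_bb <- function(data, variant = c("modified", "original"), init = NULL,
                   const = bb_constants()) {
  variant <- match.arg(variant)
  check_observations(data, require_gs = TRUE)
  const <- as_bb_constants(const)
  n <- nrow(data)
  p <- if (variant == "modified") 3L else 2L
  if (n < 5L) stop("need at least 5 observations", call. = FALSE)
  if (n < p + 1L) stop("need more observations than parameters", call. = FALSE)

  ball_proxy <- data$pn_umol_m2_s / data$co2_ppm
  if (length(unique(round(ball_proxy, 12))) < 2L)
    stop("drivers span a single Ball-index value; slope unidentifiable",
         call. = FALSE)
  if (variant == "modified" &&
      diff(range(data$psi_s_mpa)) < 1e-8)
    stop("rank-deficient fit: psi_s is constant, beta is confounded with m_i",
         call. = FALSE)

  theta_to_params <- function(theta) {
    if (variant == "modified")
      bb_params(theta[1], theta[2], beta = theta[3])
    else bb_params(theta[1], theta[2], variant = "original")
  }
  gs_obs <- data$gs_obs_mol_m2_s
  n_invalid <- 0L
  resid_fn <- function(theta) {
    if (theta[1] <= 0) return(rep(1e6, n))  # keep the slope positive
    pr <- solve_gs(theta_to_params(theta), p_n = data$pn_umol_m2_s,
                   c_a = data$co2_ppm, t_leaf = data$t_leaf_c,
                   e_a = data$e_a_hpa, psi_s = data$psi_s_mpa,
                   const = const, diagnostics = TRUE)
    r <- gs_obs - pr$g_s
    bad <- !pr$valid
    n_invalid <<- sum(bad)
    r[bad] <- 0  # excluded from the residual sum
    r
  }

  starts <- if (is.null(init)) {
    if (variant == "modified")
      list(c(10, 0.01, -1), c(30, 0, -2), c(50, 0.05, -0.2))
    else
      list(c(10, 0.01), c(30, 0), c(50, -0.05))
  } else {
    stopifnot(inherits(init, "bb_params"))
    if (variant == "modified" && is.null(init$beta))
      stop("`init` lacks beta for the modified variant", call. = FALSE)
    list(c(init$slope, init$g0, init$beta)[seq_len(p)])
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimiser starts failed", call. = FALSE)

  theta <- best$par
  rss <- best$deviance
  resid_fn(theta)  # refresh n_invalid at the optimum
  n_used <- n - n_invalid
  df <- n_used - p
  if (df < 1L) stop("too few valid observations for inference", call. = FALSE)

  J <- num_jacobian(function(th) {
    pr <- solve_gs(theta_to_params(th), p_n = data$pn_umol_m2_s,
                   c_a = data$co2_ppm, t_leaf = data$t_leaf_c,
                   e_a = data$e_a_hpa, psi_s = data$psi_s_mpa,
                   const = const)
    pr
  }, theta)
  sv <- svd(J, nu = 0, nv = 0)$d
  if (sv[1] / max(sv[p], .Machine$double.eps) > 1e10)
    stop("rank-deficient fit: singular Jacobian at the optimum",
         call. = FALSE)
  sigma2 <- rss / df
  covm <- sigma2 * solve(crossprod(J))
  se <- sqrt(diag(covm))
  tq <- stats::qt(0.975, df)

  nms <- if (variant == "modified") c("m_i", "g0", "beta") else c("m", "g0")
  est <- stats::setNames(theta, nms)
  se <- stats::setNames(se, nms)

  structure(list(
    params = theta_to_params(theta),
    variant = variant,
    estimate = est, se = se,
    ci_low = est - tq * se, ci_high = est + tq * se,
    n = n, n_invalid_pred = n_invalid,
    rss = rss, sigma = sqrt(sigma2),
    converged = best$info %in% 1:4, n_iter = best$niter
  ), class = "bb_fit")
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf("Ball-Berry %s-model fit (n = %d, RSS = %.5g%s)\n",
              x$variant, x$n, x$rss,
              if (x$converged) "" else ", NOT converged"))
  tab <- data.frame(estimate = x$estimate, se = x$se,
                    `ci 2.5%` = x$ci_low, `ci 97.5%` = x$ci_high,
                    check.names = FALSE)
  print(round(tab, 4))
  if (x$n_invalid_pred > 0)
    cat(x$n_invalid_pred, "observation(s) had no valid predicted g_s",
        "and were excluded from the residual sum\n")
  invisible(x)
}

# central-difference Jacobian of vector-valued f at theta
num_jacobian <- function(f, theta, eps = 1e-6) {
  f0 <- f(theta)
  J <- matrix(NA_real_, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (f(tp) - f(tm)) / (2 * h)
  }
  J[!is.finite(J)] <- 0
  J
}

#' Goodness-of-fit metrics for observed versus predicted values
#'
#' @param observed,predicted Numeric vectors of equal length; pairs with a
#'   non-finite member are dropped (the count is reported).
#' @return List of class `bb_metrics`: `r2` (squared Pearson correlation),
#'   `mae`, `rmse`, `n` (finite pairs used), `n_dropped`.
#' @examples
#' goodness(c(1, 2, 3), c(1, 2, 4))
#' @export
goodness <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 3L)
    stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(o) == 0 || stats::sd(p) == 0)
    stop("zero variance: r2 undefined", call. = FALSE)
  structure(list(
    r2 = stats::cor(o, p)^2,
    mae = mean(abs(o - p)),
    rmse = sqrt(mean((o - p)^2)),
    n = length(o),
    n_dropped = sum(!ok)
  ), class = "bb_metrics")
}

#' @export
print.bb_metrics <- function(x, ...) {
  cat(sprintf("r2 = %.3f, MAE = %.4g, RMSE = %.4g (n = %d%s)\n",
              x$r2, x$mae, x$rmse, x$n,
              if (x$n_dropped) paste0(", ", x$n_dropped, " dropped") else ""))
  invisible(x)
}
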