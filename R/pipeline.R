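#' Validate fitted parameters against an observation set
#'
#' Thin wrapper chaining [predict_bb()] and [goodness()]: predicts
#' conductance (and transpiration/WUE) for every observation and scores the
#' predictions against the observed conductance.
#'
#' @param params A [bb_params()] object (typically from [fit_bb()]).
#' @param data Observation table with `gs_obs_mol_m2_s`.
#' @param const A [bb_constants()] object.
#' @return List with `predictions` (the [predict_bb()] frame) and `metrics`
#'   (a `bb_metrics` object for observed vs predicted g_s).
#' @export
validate_bb <- function(params, data, const = bb_constants()) {
  check_observations(data, require_gs = TRUE)
  pred <- predict_bb(params, data, const)
  list(predictions = pred,
       metrics = goodness(data$gs_obs_mol_m2_s, pred$gs_pred))
}

#' Parameterisation summary table
#'
#' Collects one or more [fit_bb()] results into a table mirroring the usual
#' report layout: one row per CO2 level and model variant, estimates with
#' 95% confidence bounds.
#'
#' @param fits Named list of `bb_fit` objects; names label the rows (e.g.
#'   `"400 ppm original"`).
#' @return Data frame with columns `label, variant, slope, slope_lo,
#'   slope_hi, g0, g0_lo, g0_hi, beta, beta_lo, beta_hi, rss, n`.
#' @export
parameterization_table <- function(fits) {
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, logical(1),
                                         "bb_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    slope_name <- if (f$variant == "modified") "m_i" else "m"
    has_beta <- f$variant == "modified"
    data.frame(
      label = nm, variant = f$variant,
      slope = f$estimate[[slope_name]],
      slope_lo = f$ci_low[[slope_name]], slope_hi = f$ci_high[[slope_name]],
      g0 = f$estimate[["g0"]],
      g0_lo = f$ci_low[["g0"]], g0_hi = f$ci_high[["g0"]],
      beta = if (has_beta) f$estimate[["beta"]] else NA_real_,
      beta_lo = if (has_beta) f$ci_low[["beta"]] else NA_real_,
      beta_hi = if (has_beta) f$ci_high[["beta"]] else NA_real_,
      rss = f$rss, n = f$n)
  }))
}

#' Run the full simulation-parameterisation-validation workflow
#'
#' End-to-end convenience driver at one CO2 level: simulate a progressive
#' drying experiment, fit both model variants to it, simulate the three
#' split-root irrigation regimes, and score both fitted variants on each
#' regime. All randomness derives from `seed`.
#'
#' @param co2 400 or 800.
#' @param seed Integer seed; the drying run uses `seed`, the split-root
#'   regimes `seed + 1:3`.
#' @param drying_args,split_args Extra arguments passed to
#'   [drying_config()] / [split_root_config()].
#' @return List with `exp1` (drying data), `fits` (original and modified
#'   `bb_fit`), `exp2` (named list of FI/DI/PRI data frames), `validation`
#'   (per regime and variant, [validate_bb()] results).
#' @export
run_bb_workflow <- function(co2 = 400, seed = 1L,
                            drying_args = list(), split_args = list()) {
  cfg1 <- do.call(drying_config,
                  c(list(co2 = co2, seed = seed), drying_args))
  exp1 <- simulate_progressive_drying(cfg1)
  fits <- list(original = fit_bb(exp1, "original"),
               modified = fit_bb(exp1, "modified"))

  regimes <- c("FI", "DI", "PRI")
  exp2 <- stats::setNames(lapply(seq_along(regimes), function(i) {
    cfg <- do.call(split_root_config,
                   c(list(co2 = co2, treatment = regimes[i],
                          seed = seed + i), split_args))
    simulate_split_root(cfg)
  }), regimes)

  validation <- lapply(exp2, function(dat) {
    list(original = validate_bb(fits$original$params, dat),
         modified = validate_bb(fits$modified$params, dat))
  })

  list(co2 = co2, seed = seed, exp1 = exp1, fits = fits, exp2 = exp2,
       validation = validation)
}
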