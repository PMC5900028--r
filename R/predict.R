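#' Column schema of a gas-exchange observation table
#'
#' @keywords internal
obs_columns <- c("day", "unit_id", "treatment", "co2_ppm", "t_leaf_c",
                 "e_a_hpa", "psi_s_mpa", "pn_umol_m2_s", "gs_obs_mol_m2_s")

check_observations <- function(data, require_gs = FALSE) {
  need <- setdiff(obs_columns, if (require_gs) character() else
                  "gs_obs_mol_m2_s")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("observation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0L) stop("observation table is empty", call. = FALSE)
  with(data, {
    if (any(psi_s_mpa > 0, na.rm = TRUE))
      stop("psi_s_mpa must be <= 0", call. = FALSE)
    if (any(co2_ppm <= 0, na.rm = TRUE))
      stop("co2_ppm must be > 0", call. = FALSE)
    if (any(e_a_hpa < 0, na.rm = TRUE))
      stop("e_a_hpa must be >= 0", call. = FALSE)
    e_i <- saturation_vapor_pressure(t_leaf_c)
    if (any(e_a_hpa >= e_i, na.rm = TRUE))
      stop("e_a_hpa must be below saturation at leaf temperature",
           call. = FALSE)
  })
  if (require_gs) {
    gs <- data$gs_obs_mol_m2_s
    if (any(!is.finite(gs)) || any(gs <= 0))
      stop("gs_obs_mol_m2_s must be finite and > 0", call. = FALSE)
  }
  invisible(data)
}

#' Predict conductance, transpiration and WUE for a dataset
#'
#' Applies the full forward chain to every row of an observation table:
#' leaf-surface CO2, the quadratic conductance solution, leaf-surface
#' humidity, transpiration, water use efficiency, and the vapour pressure
#' deficit at leaf-temperature basis (VPD = (e_i - e_a)/10 kPa).
#'
#' Rows where the quadratic has no positive real root are flagged
#' `valid = FALSE` and their transpiration/WUE set to `NA`; they are never
#' dropped, so the output always has one row per input row, in order.
#'
#' @param params A [bb_params()] object.
#' @param data Data frame with columns `day, unit_id, treatment, co2_ppm,
#'   t_leaf_c, e_a_hpa, psi_s_mpa, pn_umol_m2_s` (and optionally
#'   `gs_obs_mol_m2_s`).
#' @param const A [bb_constants()] object.
#' @return The input data frame with columns `cs_ppm, hs, gs_pred,
#'   tr_mmol_m2_s, wue_umol_mmol, vpd_kpa, valid` appended.
#' @examples
#' obs <- data.frame(day = 1, unit_id = "p1", treatment = "drying",
#'                   co2_ppm = 400, t_leaf_c = 20, e_a_hpa = 14,
#'                   psi_s_mpa = -0.01, pn_umol_m2_s = 15.3)
#' predict_bb(bb_params(33.43, 0.019, beta = -1.98), obs)
#' @export
predict_bb <- function(params, data, const = bb_constants()) {
  check_observations(data)
  const <- as_bb_constants(const)
  d <- solve_gs(params, p_n = data$pn_umol_m2_s, c_a = data$co2_ppm,
                t_leaf = data$t_leaf_c, e_a = data$e_a_hpa,
                psi_s = data$psi_s_mpa, const = const, diagnostics = TRUE)
  out <- data
  out$cs_ppm <- d$c_s
  out$hs <- d$h_s
  out$gs_pred <- d$g_s
  out$tr_mmol_m2_s <- NA_real_
  out$wue_umol_mmol <- NA_real_
  ok <- d$valid
  if (any(ok)) {
    tr <- transpiration(d$g_s[ok], data$t_leaf_c[ok], data$e_a_hpa[ok], const)
    out$tr_mmol_m2_s[ok] <- tr
    out$wue_umol_mmol[ok] <- water_use_efficiency(data$pn_umol_m2_s[ok], tr)
  }
  out$vpd_kpa <- (d$e_i - data$e_a_hpa) / 10
  out$valid <- ok
  out
}

#' Read / write gas-exchange observation tables
#'
#' Flat CSV with the canonical column schema; `write_gas_exchange()` refuses
#' tables that violate the observation invariants so generated data are
#' validated on write.
#'
#' @param path File path.
#' @param data Observation (or prediction) data frame.
#' @return `read_gas_exchange()` returns a data frame;
#'   `write_gas_exchange()` returns `path` invisibly.
#' @export
read_gas_exchange <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_observations(data)
  data
}

#' @rdname read_gas_exchange
#' @export
write_gas_exchange <- function(data, path) {
  check_observations(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
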