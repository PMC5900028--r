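#' Physical constants of the leaf gas-exchange setup
#'
#' Bundles the two measurement-system constants the forward model needs: the
#' boundary-layer conductance of the leaf chamber and the air pressure.
#'
#' @param g_b Boundary-layer conductance to water vapour between the leaf
#'   surface and the bulk air, mol m-2 s-1. The default is the value for the
#'   LiCor 6400 leaf chamber.
#' @param p_atm Air pressure, hPa.
#'
#' @return An object of class `bb_constants`: a list with elements `g_b` and
#'   `p_atm`.
#' @examples
#' bb_constants()
#' bb_constants(g_b = 1.4) # free-leaf boundary layer, outdoors
#' @export
bb_constants <- function(g_b = 9.29, p_atm = 1013) {
  stopifnot(is.numeric(g_b), length(g_b) == 1L, is.finite(g_b),
            is.numeric(p_atm), length(p_atm) == 1L, is.finite(p_atm))
  if (g_b <= 0) stop("`g_b` must be > 0", call. = FALSE)
  if (p_atm <= 0) stop("`p_atm` must be > 0", call. = FALSE)
  structure(list(g_b = g_b, p_atm = p_atm), class = "bb_constants")
}

#' @export
print.bb_constants <- function(x, ...) {
  cat("Gas-exchange constants: g_b =", x$g_b, "mol m-2 s-1, P_atm =",
      x$p_atm, "hPa\n")
  invisible(x)
}

as_bb_constants <- function(x) {
  if (inherits(x, "bb_constants")) return(x)
  if (is.null(x)) return(bb_constants())
  do.call(bb_constants, as.list(x))
}
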