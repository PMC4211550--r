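#' Michaelis-Menten flux
#'
#' V * S / (Km + S), the saturating flux of enzymatic decay and transporter
#' uptake. Zero at S = 0 (including the Km + S = 0 limit), approaches V as S
#' grows. Vectorized and monotone non-decreasing in both V and S.
#'
#' @param V maximum flux (capacity).
#' @param S substrate concentration (mg cm^-3), >= 0.
#' @param Km half-saturation constant (mg cm^-3), >= 0.
#' @return Flux, same units as \code{V}.
#' @export
mm_flux <- function(V, S, Km) {
  stopifnot(all(S >= 0), all(Km >= 0))
  denom <- Km + S
  out <- ifelse(denom > 0, V * S / denom, 0)
  out
}

#' Arrhenius temperature adjustment of Michaelis-Menten parameters
#'
#' Both Vmax and Km follow the Arrhenius relationship with temperature, each
#' with its own activation energy (a single Km activation energy is shared by
#' enzymatic and uptake kinetics). At \code{T == T_ref} the inputs are
#' returned unchanged.
#'
#' @param Vmax maximum rate at the reference temperature.
#' @param Km half-saturation constant at the reference temperature.
#' @param T_c temperature (degrees C).
#' @param Ea_V activation energy for Vmax (kJ mol^-1).
#' @param Ea_K activation energy for Km (kJ mol^-1).
#' @param T_ref reference temperature (degrees C).
#' @return list with elements \code{Vmax} and \code{Km} at temperature T.
#' @export
temperature_adjust <- function(Vmax, Km, T_c, Ea_V, Ea_K = 20, T_ref = 20) {
  list(Vmax = Vmax * arrhenius_factor(T_c, T_ref, Ea_V),
       Km   = Km * arrhenius_factor(T_c, T_ref, Ea_K))
}

#' Lignocellulose decay penalty
#'
#' Lignin shields cellulose from enzymatic attack. The lignocellulose index
#' LCI = lignin C / (lignin C + cellulose C) reduces cellulose decay by the
#' multiplier max(0, 1 + lambda_slope * LCI). When both pools are empty the
#' multiplier is 1 (there is nothing to decay anyway).
#'
#' @param lignin_C lignin carbon (mg cm^-3), >= 0; vectorized.
#' @param cellulose_C cellulose carbon (mg cm^-3), >= 0.
#' @param lambda_slope fractional change in cellulose decay per unit LCI
#'   (negative).
#' @return Dimensionless multiplier in [0, 1] (for lambda_slope in [-1, 0]).
#' @export
lignocellulose_multiplier <- function(lignin_C, cellulose_C,
                                      lambda_slope = -0.8) {
  stopifnot(all(lignin_C >= 0), all(cellulose_C >= 0))
  tot <- lignin_C + cellulose_C
  lci <- ifelse(tot > 0, lignin_C / tot, 0)
  pmax(0, 1 + lambda_slope * lci)
}
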