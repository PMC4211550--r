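#' Parameters of the analytical rate-yield model
#'
#' The analytical model describes a spatially and taxonomically homogeneous
#' community whose growth G = U * eps is the product of an Arrhenius-scaled
#' uptake rate U and carbon use efficiency eps. Intrinsic CUE (the CUE at the
#' reference temperature) declines linearly with reference uptake investment
#' (slope \code{m_U}, the rate-yield tradeoff) and realized CUE declines
#' linearly with temperature (slope \code{m_T}).
#'
#' @param eps0 CUE intercept at zero uptake investment (mg mg^-1), in (0, 1].
#' @param m_T CUE temperature slope (mg mg^-1 per degree C).
#' @param m_U CUE-uptake tradeoff slope (must be negative for an interior
#'   optimum; the high and low tradeoff scenarios use -0.4 and -0.2).
#' @param Ea activation energy for uptake (kJ mol^-1).
#' @param T_ref reference temperature (degrees C).
#' @return A named list of class \code{analytical_params}.
#' @export
analytical_params <- function(eps0 = 0.5, m_T = -0.016, m_U = -0.4,
                              Ea = 35, T_ref = 20) {
  stopifnot(is.finite(eps0), eps0 > 0, eps0 <= 1,
            is.finite(m_T), is.finite(m_U), is.finite(Ea), is.finite(T_ref))
  structure(list(eps0 = eps0, m_T = m_T, m_U = m_U, Ea = Ea,
                 R = 8.314, T_ref = T_ref),
            class = "analytical_params")
}

#' Arrhenius temperature factor
#'
#' Dimensionless multiplier exp[(-Ea/R) (1/(T+273) - 1/(T_ref+273))] applied
#' to rates at the reference temperature. \code{Ea} is supplied in kJ mol^-1
#' and converted to J mol^-1 internally to match R = 8.314 J mol^-1 K^-1.
#' Strictly increasing in \code{T} for positive \code{Ea}; equals 1 at
#' \code{T == T_ref}.
#'
#' @param T_c temperature (degrees C); vectorized.
#' @param T_ref reference temperature (degrees C).
#' @param Ea activation energy (kJ mol^-1).
#' @return Dimensionless multiplier(s).
#' @examples
#' arrhenius_factor(25, 20, 35) # about 1.27
#' @export
arrhenius_factor <- function(T_c, T_ref = 20, Ea = 35) {
  if (!all(is.finite(T_c)) || !all(is.finite(T_ref)) || !all(is.finite(Ea)))
    stop("arrhenius_factor: non-finite input")
  if (any(T_c <= -273) || any(T_ref <= -273))
    stop("arrhenius_factor: temperature at or below absolute zero")
  exp((-Ea * 1000 / 8.314) * (1 / (T_c + 273) - 1 / (T_ref + 273)))
}

#' Growth rate at a given uptake investment and temperature
#'
#' G = U_ref * arr(T) * (eps0 + m_U * U_ref + m_T * (T - T_ref)). The bracket
#' is the realized CUE implied by the investment U_ref; growth can be negative
#' when realized CUE is negative (the caller decides how to treat that).
#'
#' @param U_ref reference uptake rate (uptake at T_ref); must be >= 0.
#' @param T_c temperature (degrees C).
#' @param p an \code{\link{analytical_params}} object.
#' @return Growth rate, same units as \code{U_ref}.
#' @export
growth_rate <- function(U_ref, T_c, p = analytical_params()) {
  stopifnot(all(is.finite(U_ref)), all(U_ref >= 0))
  arr <- arrhenius_factor(T_c, p$T_ref, p$Ea)
  eps <- p$eps0 + p$m_U * U_ref + p$m_T * (T_c - p$T_ref)
  U_ref * arr * eps
}

#' Growth-maximizing reference uptake rate
#'
#' Closed-form maximizer of \code{\link{growth_rate}} in \code{U_ref}:
#' U_ref* = -(eps0 + m_T (T - T_ref)) / (2 m_U). Linear and decreasing in T
#' when \code{m_T < 0}. With no tradeoff (m_U = 0) growth is maximized at
#' infinite uptake investment, so that case is an error.
#'
#' @inheritParams growth_rate
#' @return Optimal U_ref.
#' @export
optimal_uref <- function(T_c, p = analytical_params()) {
  if (p$m_U >= 0)
    stop("optimal_uref: requires m_U < 0 (no interior optimum otherwise)")
  -(p$eps0 + p$m_T * (T_c - p$T_ref)) / (2 * p$m_U)
}

#' Growth-maximizing intrinsic CUE
#'
#' Substituting the optimal uptake investment into the CUE-investment line
#' gives eps_int* = (eps0 - m_T (T - T_ref)) / 2. The optimum is independent
#' of the tradeoff slope m_U, so the magnitude of CUE adaptation under warming
#' does not depend on how steep the tradeoff is, and
#' eps_int*(T) - eps_int*(T_ref) = -m_T (T - T_ref) / 2: adaptation offsets
#' exactly half of the temperature-forced CUE change.
#'
#' @inheritParams growth_rate
#' @return Optimal intrinsic CUE (mg mg^-1).
#' @examples
#' p <- analytical_params()
#' optimal_eps_int(20, p) - optimal_eps_int(15, p) # 0.04
#' @export
optimal_eps_int <- function(T_c, p = analytical_params()) {
  if (p$m_U >= 0)
    stop("optimal_eps_int: requires m_U < 0 (no interior optimum otherwise)")
  (p$eps0 - p$m_T * (T_c - p$T_ref)) / 2
}

#' Temperature sweep of the analytical optimum
#'
#' @param T_c vector of temperatures (degrees C).
#' @param p an \code{\link{analytical_params}} object.
#' @return data.frame with columns \code{T}, \code{optimal_uref},
#'   \code{optimal_eps_int}, \code{max_growth}.
#' @export
analytical_sweep <- function(T_c = seq(10, 30, by = 1), p = analytical_params()) {
  u <- optimal_uref(T_c, p)
  data.frame(
    T = T_c,
    optimal_uref = u,
    optimal_eps_int = optimal_eps_int(T_c, p),
    max_growth = growth_rate(u, T_c, p)
  )
}

#' Growth as a function of intrinsic CUE
#'
#' Sweeps uptake investment, reporting the implied intrinsic CUE
#' (eps0 + m_U U_ref) and growth at each point for one or more temperatures —
#' the growth-versus-intrinsic-CUE curves whose peaks shift toward higher
#' intrinsic CUE as temperature rises.
#'
#' @param T_c vector of temperatures (degrees C).
#' @param p an \code{\link{analytical_params}} object.
#' @param n number of uptake grid points per temperature.
#' @return data.frame with columns \code{T}, \code{U_ref}, \code{eps_int},
#'   \code{growth}.
#' @export
growth_cue_sweep <- function(T_c = c(15, 20, 25), p = analytical_params(),
                             n = 201) {
  u_max <- max(optimal_uref(T_c, p)) * 2
  u <- seq(0, u_max, length.out = n)
  out <- lapply(T_c, function(tt) {
    data.frame(T = tt, U_ref = u, eps_int = p$eps0 + p$m_U * u,
               growth = growth_rate(u, tt, p))
  })
  do.call(rbind, out)
}
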