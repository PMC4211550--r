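#' Default simulation parameters
#'
#' Returns the full parameter set of the decomposition simulator: community
#' composition, kinetic constants, CUE tradeoff slopes, stoichiometric targets
#' and tolerances, demographic rates, and lattice geometry. Values are the
#' model's standard litter-decomposition configuration; any subset can be
#' overridden through \code{...}.
#'
#' Units: concentrations are mg cm^-3 (one lattice point is nominally 1 cm^3,
#' so per-cell quotas are in mg), rates are day^-1, activation energies are
#' kJ mol^-1, temperatures are degrees Celsius.
#'
#' @param ... named overrides of any default value.
#' @return A named list of class \code{dement_params}.
#' @examples
#' p <- dement_params(x = 20, y = 20, days = 500)
#' p$V_E
#' @export
dement_params <- function(...) {
  p <- list(
    ## scale
    days = 5000,          # iterations (1 day each)
    x    = 100,           # lattice length
    y    = 100,           # lattice width
    ## community size
    n_enzymes      = 50,  # N_E: enzymes in the community pool
    n_substrates   = 12,  # N_S: organic substrates
    n_transporters = 14,  # N_U: uptake transporters in the pool
    n_taxa         = 100, # number of virtual taxa
    fungal_fraction = 0.5,
    ## kinetics
    Ea_uptake   = 35,     # E_a: activation energy for uptake (kJ mol^-1)
    Ea_Km       = 20,     # E_aK: activation energy for Km (enzymes and uptake)
    km_E_slope  = 10,     # Km = slope * Vmax + intercept (enzymes)
    km_E_int    = 0,
    km_U_slope  = 0.2,    # Km = slope * Vmax + intercept (uptake)
    km_U_int    = 0,
    V_E         = 100,    # enzyme Vmax at T_ref (mg substrate mg^-1 enzyme d^-1)
    V_U         = 5,      # uptake Vmax at T_ref (mg substrate mg^-1 biomass d^-1)
    lambda_slope = -0.8,  # fractional change in cellulose decay per unit LCI
    lci_hemicellulose = FALSE, # also penalize hemicellulose decay by LCI
    E_S         = 1,      # minimum enzymes able to degrade each substrate
    U_M         = 1,      # minimum transporters able to take up each monomer
    E_max       = 40,     # maximum enzyme genes per taxon
    theta       = 1,      # strength of the specificity-efficiency tradeoff
    ## CUE model
    eps0 = 0.5,           # CUE intercept (mg mg^-1)
    m_T  = -0.016,        # CUE temperature slope (mg mg^-1 degC^-1)
    m_E  = -0.2,          # CUE change with full enzyme investment
    m_U  = -0.2,          # CUE change with full uptake investment
    ## enzyme production costs
    Z_EC    = 5e-5,       # inducible C cost per enzyme, fraction of uptake C
    beta_EC = 5e-5,       # constitutive C cost per enzyme, fraction of biomass C d^-1
    Z_EN    = 0.3,        # enzyme N cost as a fraction of C cost
    ## losses
    leaching = 0.1,       # L: fraction of dissolved pools leached per day
    tau_E    = 0.04,      # enzyme turnover rate
    tau_B    = 0.02,      # bacterial random death rate
    tau_F    = 0.01,      # fungal random death rate
    ## initialization
    F_MS = 0.045,         # initial monomer as fraction of initial substrate
    D_B  = 0.1,           # initial bacterial cells per lattice point (mean)
    D_F  = 0.004,         # initial fungal cells per lattice point (mean)
    F_B  = 0.5,           # initial fungal share of biomass (via 25x cell size)
    ## biomass stoichiometry (mass fractions) and tolerances
    frac_C_bact = 0.825, frac_N_bact = 0.160, frac_P_bact = 0.015,
    frac_C_fungi = 0.900, frac_N_fungi = 0.090, frac_P_fungi = 0.010,
    tol_C = 0.090, tol_N = 0.040, tol_P = 0.005,
    ## death thresholds and division thresholds (mg per cell)
    C_min = 0.086, N_min = 0.012, P_min = 0.002,
    C_max_bact = 2, C_max_fungi = 50,
    ## dispersal
    rho_y = 0.05,         # fungal probability of moving +-1 in y at division
    delta = 1,            # maximum dispersal distance (lattice points)
    fungal_x_disperse = FALSE, # alternative: lateral x-move instead of staying
    ## temperature
    T_ref = 20,
    R_gas = 8.314         # J mol^-1 K^-1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$E_max <= p$n_enzymes || p$E_max >= 0)
  structure(p, class = "dement_params")
}

#' Tradeoff slopes for the named warming scenario
#'
#' The simulator is run under a high tradeoff scenario (m_E = m_U = -0.2) and
#' a low tradeoff scenario (m_E = m_U = -0.1). For the analytical model the
#' corresponding uptake-tradeoff slopes are m_U = -0.4 (high) and -0.2 (low).
#'
#' @param scenario \code{"high"} or \code{"low"}.
#' @return Named list with \code{m_E} and \code{m_U}.
#' @export
scenario_slopes <- function(scenario = c("high", "low")) {
  scenario <- match.arg(scenario)
  s <- if (scenario == "high") -0.2 else -0.1
  list(m_E = s, m_U = s)
}

#' Litter substrate chemistry table
#'
#' Initial pool sizes (mg cm^-3, split into C, N and P), daily external input
#' rates (expressed as C; N and P inputs follow each compound's fixed
#' stoichiometry) for the polymeric substrate and its corresponding monomer,
#' and the activation energy for enzymatic decay of each substrate. The
#' chemistry reflects grassland plant litter plus the two internally generated
#' pools (dead microbial biomass and dead enzymes), which start empty and
#' receive no external input.
#'
#' @return A data.frame with one row per substrate, columns \code{substrate},
#'   \code{C0}, \code{N0}, \code{P0}, \code{input_sub} (substrate C input,
#'   mg cm^-3 day^-1), \code{input_mon} (monomer C input), \code{Ea}
#'   (kJ mol^-1).
#' @export
substrate_table <- function() {
  data.frame(
    substrate = c("dead_microbe", "dead_enzyme", "cellulose", "hemicellulose",
                  "starch", "chitin", "lignin", "protein_1", "protein_2",
                  "protein_3", "organic_P1", "organic_P2"),
    C0 = c(0, 0, 146.89, 85.86, 12.21, 5.00, 48.51, 10.60, 10.60, 10.60,
           12.48, 1.82),
    N0 = c(0, 0, 0, 0, 0, 0.8325, 0.4043, 2.0970, 2.0970, 2.0970, 0, 0.7975),
    P0 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.4785, 0.4785),
    input_sub = c(0, 0, 0.4024, 0.2352, 0.0335, 0.0137, 0.1329, 0.0290,
                  0.0290, 0.0290, 0.0342, 0.0050),
    input_mon = c(0, 0, 0.01811, 0.01058, 0.00151, 0.00062, 0.00598, 0.00131,
                  0.00131, 0.00131, 0.00154, 0.00022),
    Ea = c(37, 35, 36, 35, 35, 37, 39, 35, 35, 35, 36, 34),
    stringsAsFactors = FALSE
  )
}

# substrate indices used by the lignocellulose penalty
SUB_DEAD_MICROBE <- 1L
SUB_DEAD_ENZYME  <- 2L
SUB_CELLULOSE    <- 3L
SUB_HEMICELLULOSE <- 4L
SUB_LIGNIN       <- 7L

# uptake target indices: monomers 1..12 mirror the substrates, then inorganic
# N (13) and inorganic P (14)
MON_INORG_N <- 13L
MON_INORG_P <- 14L

#' @export
print.dement_params <- function(x, ...) {
  cat("<dement_params> ", x$n_taxa, " taxa, ", x$n_enzymes, " enzymes, ",
      x$n_substrates, " substrates, lattice ", x$x, "x", x$y,
      ", ", x$days, " days\n", sep = "")
  cat("  tradeoff slopes m_E = ", x$m_E, ", m_U = ", x$m_U,
      "; eps0 = ", x$eps0, ", m_T = ", x$m_T, "\n", sep = "")
  invisible(x)
}
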