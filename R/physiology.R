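#' Precompute temperature-adjusted run context
#'
#' Applies the Arrhenius adjustment once per run: enzyme Vmax uses each
#' substrate's decay activation energy, uptake Vmax uses the uptake activation
#' energy, and both Km sets share the single Km activation energy. Also caches
#' per-taxon realized CUE, reachable-monomer sets, guild flags and demographic
#' constants used in the daily step.
#'
#' @param community a \code{dement_community}.
#' @param params a \code{\link{dement_params}} list.
#' @param T_c run temperature (degrees C).
#' @return list used by \code{\link{step_day}}.
#' @export
run_context <- function(community, params = community$params,
                        T_c = params$T_ref) {
  enz <- community$enzymes
  trn <- community$transporters
  tax <- community$taxa
  arr_K <- arrhenius_factor(T_c, params$T_ref, enz$Ea_K)
  VmaxT <- sweep(enz$Vmax, 2, arrhenius_factor(T_c, params$T_ref, enz$Ea), `*`)
  KmT <- enz$Km * arr_K
  fung <- tax$guild == "fungal"
  list(
    T_c = T_c,
    VmaxT = VmaxT, KmT = KmT,
    VU_T = trn$Vmax_U * arrhenius_factor(T_c, params$T_ref, trn$Ea_U),
    KmU_T = trn$Km_U * arr_K,
    eps = realized_cue(tax$eps_int, T_c, params),
    reach = tax$reach * 1,
    n_reach = pmax(1L, rowSums(tax$reach)),
    GE = tax$GE * 1,
    n_enz_genes = tax$n_enz_genes,
    fungal = fung,
    tau = ifelse(fung, params$tau_F, params$tau_B),
    C_div = ifelse(fung, params$C_max_fungi, params$C_max_bact),
    fC_up = ifelse(fung, params$frac_C_fungi, params$frac_C_bact) + params$tol_C,
    fN_up = ifelse(fung, params$frac_N_fungi, params$frac_N_bact) + params$tol_N,
    fP_up = ifelse(fung, params$frac_P_fungi, params$frac_P_bact) + params$tol_P
  )
}

#' Realized carbon use efficiency at temperature T
#'
#' eps = eps_int + m_T (T - T_ref), clamped at 0 below (negative growth is
#' expressed through starvation mortality rather than negative CUE).
#'
#' @param eps_int intrinsic CUE (vectorized over taxa).
#' @param T_c temperature (degrees C).
#' @param params a \code{\link{dement_params}} list.
#' @return Realized CUE in [0, 1].
#' @export
realized_cue <- function(eps_int, T_c, params = dement_params()) {
  pmin(1, pmax(0, eps_int + params$m_T * (T_c - params$T_ref)))
}

#' Enzymatic substrate degradation
#'
#' Per point and substrate, decay is the sum over enzyme pools of
#' Michaelis-Menten fluxes with capacity Vmax_T * enzyme concentration,
#' multiplied by the lignocellulose penalty for cellulose (and optionally
#' hemicellulose) and capped at the standing pool. Substrate concentration is
#' the compound's total mass (C + N + P); decayed mass moves to the matching
#' monomer pool preserving the pool's stoichiometry.
#'
#' @param w a \code{dement_world}.
#' @param community a \code{dement_community}.
#' @param params a \code{\link{dement_params}} list.
#' @param ctx optional precomputed \code{\link{run_context}}.
#' @return The updated world.
#' @export
degrade_substrates <- function(w, community, params = community$params,
                               ctx = run_context(community, params, w$T)) {
  targets <- community$enzymes$targets
  nS <- params$n_substrates
  lci_mult <- NULL
  for (s in seq_len(nS)) {
    es <- which(targets[, s])
    if (!length(es)) next
    S_tot <- w$subC[, s] + w$subN[, s] + w$subP[, s]
    if (all(S_tot <= 0)) next
    denom <- outer(S_tot, ctx$KmT[es, s], `+`)
    sat <- S_tot / (denom + (denom == 0))
    ## decay = sum_e VmaxT[e,s] * enz[,e] * sat[,e], as a matrix-vector product
    decay <- drop((w$enz[, es, drop = FALSE] * sat) %*% ctx$VmaxT[es, s])
    if (s == SUB_CELLULOSE ||
        (s == SUB_HEMICELLULOSE && isTRUE(params$lci_hemicellulose))) {
      if (is.null(lci_mult))
        lci_mult <- lignocellulose_multiplier(
          w$subC[, SUB_LIGNIN], w$subC[, SUB_CELLULOSE], params$lambda_slope)
      decay <- decay * lci_mult
    }
    decay <- pmin(decay, S_tot)
    f <- decay / (S_tot + (S_tot == 0))
    dC <- f * w$subC[, s]; dN <- f * w$subN[, s]; dP <- f * w$subP[, s]
    w$subC[, s] <- w$subC[, s] - dC
    w$subN[, s] <- w$subN[, s] - dN
    w$subP[, s] <- w$subP[, s] - dP
    w$monC[, s] <- w$monC[, s] + dC
    w$monN[, s] <- w$monN[, s] + dN
    w$monP[, s] <- w$monP[, s] + dP
    if (any(w$subC[, s] < 0)) stop("degrade_substrates: negative pool")
  }
  w
}

#' Monomer uptake by cells
#'
#' Each cell's uptake capacity is V_U_T times its C quota, split equally
#' across the monomers its transporters reach; per-monomer demand follows
#' Michaelis-Menten saturation in the local pool (total monomer mass). When
#' the summed demands at a point exceed a pool, all takers are scaled down
#' proportionally. Organic monomers deliver C, N and P in the local pool's
#' stoichiometry; inorganic N and P deliver a single element.
#'
#' @inheritParams degrade_substrates
#' @param grouping optional precomputed point grouping of the cells (internal
#'   fast path shared across the day's sub-steps).
#' @return list(world, uptC, uptN, uptP) with per-cell assimilated masses.
#' @export
take_up <- function(w, community, params = community$params,
                    ctx = run_context(community, params, w$T),
                    grouping = NULL) {
  nc <- n_cells(w)
  if (nc == 0)
    return(list(world = w, uptC = numeric(0), uptN = numeric(0),
                uptP = numeric(0)))
  nS <- params$n_substrates
  cpt <- w$cells$pt
  ct <- w$cells$taxon

  Smat <- cbind(w$monC + w$monN + w$monP, w$inorgN, w$inorgP)
  denom <- ctx$KmU_T + Smat
  sat <- Smat / (denom + (denom == 0))

  cap <- ctx$VU_T * w$cells$C / ctx$n_reach[ct]
  demand <- cap * ctx$reach[ct, , drop = FALSE] * sat[cpt, , drop = FALSE]

  if (is.null(grouping)) grouping <- pt_group(cpt)
  grp <- grouping$grp
  upts <- grouping$upts
  demand_pt <- rowsum(demand, grp)
  avail <- Smat[upts, , drop = FALSE]
  scale <- avail / (demand_pt + (demand_pt == 0))
  scale[scale > 1] <- 1
  take <- demand * scale[as.integer(grp), , drop = FALSE]
  removed <- rowsum(take, grp)

  ## element composition of each organic monomer pool (before removal)
  mass_org <- Smat[, seq_len(nS), drop = FALSE]
  mass_safe <- mass_org + (mass_org == 0)
  fC <- w$monC / mass_safe
  fN <- w$monN / mass_safe
  fP <- w$monP / mass_safe

  take_org <- take[, seq_len(nS), drop = FALSE]
  uptC <- unname(rowSums(take_org * fC[cpt, , drop = FALSE]))
  uptN <- unname(rowSums(take_org * fN[cpt, , drop = FALSE]) +
                   take[, MON_INORG_N])
  uptP <- unname(rowSums(take_org * fP[cpt, , drop = FALSE]) +
                   take[, MON_INORG_P])

  rem_org <- removed[, seq_len(nS), drop = FALSE]
  fr <- matrix(0, w$npts, nS)
  fr[upts, ] <- rem_org / mass_safe[upts, , drop = FALSE]
  w$monC <- w$monC * (1 - fr)
  w$monN <- w$monN * (1 - fr)
  w$monP <- w$monP * (1 - fr)
  w$inorgN[upts] <- w$inorgN[upts] - removed[, MON_INORG_N]
  w$inorgP[upts] <- w$inorgP[upts] - removed[, MON_INORG_P]

  list(world = w, uptC = uptC, uptN = uptN, uptP = uptP)
}

#' CUE-partitioned growth and stoichiometric homeostasis
#'
#' Of the assimilated C, the fraction eps is retained as growth and (1 - eps)
#' is respired (growth respiration). Assimilated N and P enter the quotas in
#' full. Homeostasis then enforces the guild's element-fraction tolerance
#' bands: C above the upper C-fraction band is respired as overflow (ledgered
#' separately from growth respiration and excluded from intrinsic-CUE
#' accounting), and N or P above their bands are mineralized to the local
#' inorganic pools. Each excess is resolved by the exact one-unknown balance
#' that places the offending fraction on its band boundary; the three
#' elements are relaxed sequentially and iterated to convergence.
#'
#' @param C,N,P per-cell quota vectors (mg).
#' @param uptC,uptN,uptP per-cell assimilated masses (mg).
#' @param eps per-cell realized CUE in [0, 1].
#' @param fC_up,fN_up,fP_up per-cell upper element-fraction bounds.
#' @return list(C, N, P, growth_resp, overflow, minN, minP) per cell.
#' @export
grow_and_balance <- function(C, N, P, uptC, uptN, uptP, eps,
                             fC_up, fN_up, fP_up) {
  stopifnot(all(eps >= 0), all(eps <= 1))
  growth_resp <- (1 - eps) * uptC
  C <- C + eps * uptC
  N <- N + uptN
  P <- P + uptP
  bal <- homeostasis(C, N, P, fC_up, fN_up, fP_up)
  c(list(growth_resp = growth_resp), bal)
}

## sequential relaxation onto the element-fraction bands; exact boundary
## solve per element, iterated because fixing one fraction shifts the others
homeostasis <- function(C, N, P, fC_up, fN_up, fP_up, iters = 8L) {
  n <- length(C)
  fC_up <- rep_len(fC_up, n); fN_up <- rep_len(fN_up, n)
  fP_up <- rep_len(fP_up, n)
  overflow <- numeric(n); minN <- numeric(n); minP <- numeric(n)
  tot <- C + N + P
  act <- which(tot > 0 & (C > fC_up * tot | N > fN_up * tot |
                          P > fP_up * tot))
  if (!length(act))
    return(list(C = C, N = N, P = P, overflow = overflow,
                minN = minN, minP = minP))
  res <- homeostasis_core(C[act], N[act], P[act], fC_up[act], fN_up[act],
                          fP_up[act], iters)
  C[act] <- res$C; N[act] <- res$N; P[act] <- res$P
  overflow[act] <- res$overflow; minN[act] <- res$minN; minP[act] <- res$minP
  list(C = C, N = N, P = P, overflow = overflow, minN = minN, minP = minP)
}

homeostasis_core <- function(C, N, P, fC_up, fN_up, fP_up, iters = 8L) {
  overflow <- numeric(length(C))
  minN <- numeric(length(C))
  minP <- numeric(length(C))
  tol <- 1 + 1e-12
  for (i in seq_len(iters)) {
    tot <- C + N + P
    exc <- tot > 0 & C > fC_up * tot
    if (any(exc)) {
      Cnew <- fC_up[exc] * (N[exc] + P[exc]) / (1 - fC_up[exc])
      overflow[exc] <- overflow[exc] + C[exc] - Cnew
      C[exc] <- Cnew
    }
    tot <- C + N + P
    exc <- tot > 0 & N > fN_up * tot
    if (any(exc)) {
      Nnew <- fN_up[exc] * (C[exc] + P[exc]) / (1 - fN_up[exc])
      minN[exc] <- minN[exc] + N[exc] - Nnew
      N[exc] <- Nnew
    }
    tot <- C + N + P
    exc <- tot > 0 & P > fP_up * tot
    if (any(exc)) {
      Pnew <- fP_up[exc] * (C[exc] + N[exc]) / (1 - fP_up[exc])
      minP[exc] <- minP[exc] + P[exc] - Pnew
      P[exc] <- Pnew
    }
    tot <- C + N + P
    ok <- !any(tot > 0 & (C > fC_up * tot * tol | N > fN_up * tot * tol |
                          P > fP_up * tot * tol))
    if (ok) break
  }
  list(C = C, N = N, P = P, overflow = overflow, minN = minN, minP = minP)
}

#' Extracellular enzyme production
#'
#' Per possessed enzyme gene, production has a constitutive component
#' (beta_EC times the cell's C quota per day) and an inducible component
#' (Z_EC times the day's gross C uptake). The C cost and an N cost of Z_EN
#' times the C cost are paid from the cell's quotas; production is pro-rated
#' if either quota would fall below its death threshold. Produced enzyme mass
#' is added to the cell's lattice point, split across the taxon's enzymes.
#'
#' @param w a \code{dement_world}.
#' @param uptC per-cell gross C uptake for the day (mg).
#' @param community a \code{dement_community}.
#' @param params a \code{\link{dement_params}} list.
#' @param ctx optional precomputed \code{\link{run_context}}.
#' @return list(world, prodC, prodN) with total production for the ledger.
#' @export
produce_enzymes <- function(w, uptC, community, params = community$params,
                            ctx = run_context(community, params, w$T)) {
  nc <- n_cells(w)
  if (nc == 0) return(list(world = w, prodC = 0, prodN = 0))
  ct <- w$cells$taxon
  ng <- ctx$n_enz_genes[ct]
  per_enz <- params$beta_EC * w$cells$C + params$Z_EC * uptC
  costC <- ng * per_enz
  costN <- params$Z_EN * costC
  fC <- pmax(0, w$cells$C - params$C_min) / (costC + (costC == 0))
  fN <- pmax(0, w$cells$N - params$N_min) / (costN + (costN == 0))
  f <- pmin(1, fC, fN)
  f[costC == 0] <- 1
  produced <- which(f > 0 & ng > 0 & per_enz > 0)
  if (length(produced)) {
    add <- (f * per_enz)[produced] * ctx$GE[ct[produced], , drop = FALSE]
    g <- pt_group(w$cells$pt[produced])
    add_pt <- rowsum(add, g$grp)
    w$enz[g$upts, ] <- w$enz[g$upts, ] + add_pt
  }
  w$cells$C <- w$cells$C - f * costC
  w$cells$N <- w$cells$N - f * costN
  list(world = w, prodC = sum(f * costC), prodN = sum(f * costN))
}
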