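#' Mortality: starvation and random death
#'
#' A cell dies deterministically when any quota falls below its minimum
#' (starvation), and randomly as a first-order process with the guild's
#' turnover rate. Dead quotas transfer to the dead-microbe substrate pool at
#' the cell's lattice point; that pool's stoichiometry is unconstrained, so
#' whatever composition the cell had is what the pool receives.
#'
#' @param w a \code{dement_world}.
#' @param community a \code{dement_community}.
#' @param params a \code{\link{dement_params}} list.
#' @param ctx optional precomputed \code{\link{run_context}}.
#' @return list(world, n_died, dead = c(C, N, P)).
#' @export
mortality <- function(w, community, params = community$params,
                      ctx = run_context(community, params, w$T)) {
  nc <- n_cells(w)
  if (nc == 0) return(list(world = w, n_died = 0L, dead = c(C = 0, N = 0, P = 0)))
  cs <- w$cells
  starved <- cs$C < params$C_min | cs$N < params$N_min | cs$P < params$P_min
  dead <- starved | stats::runif(nc) < ctx$tau[cs$taxon]
  tot <- c(C = 0, N = 0, P = 0)
  if (any(dead)) {
    g <- pt_group(cs$pt[dead])
    upts <- g$upts
    w$subC[upts, SUB_DEAD_MICROBE] <- w$subC[upts, SUB_DEAD_MICROBE] +
      rowsum(cs$C[dead], g$grp)[, 1]
    w$subN[upts, SUB_DEAD_MICROBE] <- w$subN[upts, SUB_DEAD_MICROBE] +
      rowsum(cs$N[dead], g$grp)[, 1]
    w$subP[upts, SUB_DEAD_MICROBE] <- w$subP[upts, SUB_DEAD_MICROBE] +
      rowsum(cs$P[dead], g$grp)[, 1]
    tot <- c(C = sum(cs$C[dead]), N = sum(cs$N[dead]), P = sum(cs$P[dead]))
    keep <- !dead
    w$cells <- list(pt = cs$pt[keep], taxon = cs$taxon[keep],
                    C = cs$C[keep], N = cs$N[keep], P = cs$P[keep])
  }
  list(world = w, n_died = sum(dead), dead = tot)
}

#' First-order enzyme turnover
#'
#' Each enzyme pool decays by the fraction tau_E per day. Decayed enzyme C,
#' with its bound N (Z_EN times C), enters the dead-enzyme substrate pool at
#' the same point.
#'
#' @inheritParams mortality
#' @return list(world, decayed_C).
#' @export
enzyme_turnover <- function(w, params = dement_params()) {
  loss <- params$tau_E * w$enz
  w$enz <- w$enz - loss
  per_pt <- rowSums(loss)
  w$subC[, SUB_DEAD_ENZYME] <- w$subC[, SUB_DEAD_ENZYME] + per_pt
  w$subN[, SUB_DEAD_ENZYME] <- w$subN[, SUB_DEAD_ENZYME] + params$Z_EN * per_pt
  list(world = w, decayed_C = sum(per_pt))
}

#' Division and dispersal
#'
#' A cell whose C quota reaches its guild's division threshold splits all
#' quotas 50/50. Bacterial offspring are placed uniformly at random among the
#' 8 wrap-around neighbors within distance delta = 1, producing globular
#' colonies. Fungal offspring move one point up or down the y axis with total
#' probability rho_y (split evenly between the two directions) and otherwise
#' stay on the parent's point (or, with \code{fungal_x_disperse}, make a
#' lateral x move instead), producing hypha-like columns. Offspring may stack
#' on occupied points; there is no crowding limit.
#'
#' @inheritParams mortality
#' @return The updated world.
#' @export
divide_and_disperse <- function(w, community, params = community$params,
                                ctx = run_context(community, params, w$T)) {
  nc <- n_cells(w)
  if (nc == 0) return(w)
  cs <- w$cells
  thr <- ctx$C_div[cs$taxon]
  div <- which(cs$C >= thr)
  if (!length(div)) return(w)

  ## halve parent quotas; offspring get the other half
  cs$C[div] <- cs$C[div] / 2
  cs$N[div] <- cs$N[div] / 2
  cs$P[div] <- cs$P[div] / 2
  off_taxon <- cs$taxon[div]
  off_C <- cs$C[div]; off_N <- cs$N[div]; off_P <- cs$P[div]

  fungal <- ctx$fungal[off_taxon]
  n_off <- length(div)
  dx <- integer(n_off); dy <- integer(n_off)

  nb <- which(!fungal)
  if (length(nb)) {
    moves <- expand.grid(dx = -params$delta:params$delta,
                         dy = -params$delta:params$delta)
    moves <- moves[!(moves$dx == 0 & moves$dy == 0), ]
    k <- sample.int(nrow(moves), length(nb), replace = TRUE)
    dx[nb] <- moves$dx[k]
    dy[nb] <- moves$dy[k]
  }
  nf <- which(fungal)
  if (length(nf)) {
    u <- stats::runif(length(nf))
    go <- u < params$rho_y
    dy[nf[go & u < params$rho_y / 2]] <- -1L
    dy[nf[go & u >= params$rho_y / 2]] <- 1L
    if (isTRUE(params$fungal_x_disperse) && any(!go))
      dx[nf[!go]] <- sample(c(-1L, 1L), sum(!go), replace = TRUE)
  }
  off_pt <- offset_pt(cs$pt[div], dx, dy, w$nx, w$ny)

  w$cells <- list(pt = c(cs$pt, off_pt), taxon = c(cs$taxon, off_taxon),
                  C = c(cs$C, off_C), N = c(cs$N, off_N),
                  P = c(cs$P, off_P))
  w
}

#' Fungal nutrient translocation
#'
#' At the start of each model iteration, every cell of a fungal taxon has its
#' C, N and P quotas set to that taxon's lattice-wide mean, mixing nutrients
#' across the whole mycelium. Totals are conserved; bacterial cells are
#' untouched.
#'
#' @inheritParams mortality
#' @return The updated world.
#' @export
translocate <- function(w, community, ctx = NULL) {
  nc <- n_cells(w)
  if (nc == 0) return(w)
  fungal <- if (is.null(ctx)) community$taxa$guild == "fungal" else ctx$fungal
  idx <- which(fungal[w$cells$taxon])
  if (length(idx) < 2) return(w)
  tx <- w$cells$taxon[idx]
  w$cells$C[idx] <- stats::ave(w$cells$C[idx], tx)
  w$cells$N[idx] <- stats::ave(w$cells$N[idx], tx)
  w$cells$P[idx] <- stats::ave(w$cells$P[idx], tx)
  w
}
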