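#' @title Lattice world state
#' @description Internal representation: per-point pools are matrices with one
#'   row per lattice point (row-major over x, then y), one column per
#'   substrate/monomer/enzyme. Cells are a list of parallel vectors (point
#'   index, taxon index, C/N/P quotas in mg). Each lattice point is nominally
#'   1 cm^3, so mg cm^-3 pool values are per-point masses in mg.
#' @name world
#' @keywords internal
NULL

## point index <-> coordinates: pt = (ix - 1) * ny + iy
pt_index <- function(ix, iy, ny) (ix - 1L) * ny + iy

pt_coords <- function(pt, ny) {
  iy <- ((pt - 1L) %% ny) + 1L
  ix <- ((pt - 1L) %/% ny) + 1L
  cbind(ix = ix, iy = iy)
}

#' Displace lattice points with wrap-around boundaries
#'
#' @param pt integer point indices.
#' @param dx,dy displacement (vectors recycled against \code{pt}).
#' @param nx,ny lattice dimensions.
#' @return Displaced point indices.
#' @export
offset_pt <- function(pt, dx, dy, nx, ny) {
  co <- pt_coords(pt, ny)
  ix <- ((co[, "ix"] - 1L + dx) %% nx) + 1L
  iy <- ((co[, "iy"] - 1L + dy) %% ny) + 1L
  pt_index(ix, iy, ny)
}

#' The 8 wrap-around neighbors of a lattice point
#'
#' @param pt a single point index.
#' @param nx,ny lattice dimensions.
#' @return Integer vector of 8 neighboring point indices (with wrap-around;
#'   on degenerate lattices neighbors may repeat).
#' @export
neighbor_points <- function(pt, nx, ny) {
  d <- expand.grid(dx = -1:1, dy = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0), ]
  offset_pt(rep(pt, nrow(d)), d$dx, d$dy, nx, ny)
}

## cheap integer-code factor over sorted unique points (avoids factor()'s
## character conversion in rowsum grouping on the hot path)
pt_group <- function(pt) {
  upts <- sort(unique(pt))
  list(grp = structure(match(pt, upts), levels = as.character(upts),
                       class = "factor"),
       upts = upts)
}

empty_cells <- function() {
  list(pt = integer(0), taxon = integer(0),
       C = numeric(0), N = numeric(0), P = numeric(0))
}

n_cells <- function(w) length(w$cells$pt)

#' Construct a world with explicit pools and cells
#'
#' Low-level constructor used by \code{\link{initialize_world}} and by tests
#' that need full control over the initial state. Substrate pools start at the
#' chemistry table's initial values (uniform across points) and monomers at
#' \code{F_MS} times their substrate, unless overridden.
#'
#' @param community a \code{dement_community}.
#' @param params a \code{\link{dement_params}} list.
#' @param T_c run temperature (degrees C).
#' @param cells optional cell list (parallel vectors \code{pt}, \code{taxon},
#'   \code{C}, \code{N}, \code{P}); defaults to an empty world.
#' @param subC,subN,subP,monC,monN,monP optional pool matrix overrides.
#' @return A \code{dement_world} list.
#' @export
make_world <- function(community, params = community$params,
                       T_c = params$T_ref, cells = empty_cells(),
                       subC = NULL, subN = NULL, subP = NULL,
                       monC = NULL, monN = NULL, monP = NULL) {
  nx <- params$x; ny <- params$y
  npts <- nx * ny
  nS <- params$n_substrates
  st <- substrate_table()
  fill <- function(v) matrix(rep(v, each = npts), npts, nS)
  w <- list(
    nx = nx, ny = ny, npts = npts,
    subC = if (is.null(subC)) fill(st$C0) else subC,
    subN = if (is.null(subN)) fill(st$N0) else subN,
    subP = if (is.null(subP)) fill(st$P0) else subP,
    monC = if (is.null(monC)) fill(params$F_MS * st$C0) else monC,
    monN = if (is.null(monN)) fill(params$F_MS * st$N0) else monN,
    monP = if (is.null(monP)) fill(params$F_MS * st$P0) else monP,
    inorgN = numeric(npts), inorgP = numeric(npts),
    enz = matrix(0, npts, params$n_enzymes),
    cells = cells,
    T = T_c, day = 0L
  )
  class(w) <- "dement_world"
  w
}

## initial quota vector for a guild: cells start at half the division
## threshold, with composition at the guild's reference element fractions
initial_quota <- function(guild, params) {
  if (guild == "bacterial") {
    C <- params$C_max_bact / 2
    M <- C / params$frac_C_bact
    c(C = C, N = M * params$frac_N_bact, P = M * params$frac_P_bact)
  } else {
    C <- params$C_max_fungi / 2
    M <- C / params$frac_C_fungi
    c(C = C, N = M * params$frac_N_fungi, P = M * params$frac_P_fungi)
  }
}

#' Initialize the lattice world
#'
#' Substrate pools are spread uniformly across points at the chemistry table's
#' initial values, monomers at \code{F_MS} times their substrate. Cells are
#' placed by independent per-point Poisson draws at mean densities \code{D_B}
#' (bacteria) and \code{D_F} (fungi); each placed cell is assigned a uniformly
#' drawn taxon of its guild and starts at half its guild's division threshold
#' with reference stoichiometry. Fungal cells are 25 times larger than
#' bacterial cells, which at the default densities makes the initial fungal
#' biomass share \code{F_B} = 0.5.
#'
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @param community a \code{dement_community}.
#' @param params a \code{\link{dement_params}} list.
#' @param T_c run temperature (degrees C).
#' @return A \code{dement_world}.
#' @export
initialize_world <- function(seed = NULL, community,
                             params = community$params,
                             T_c = params$T_ref) {
  if (!is.null(seed)) set.seed(seed)
  npts <- params$x * params$y
  guild <- community$taxa$guild
  bact <- which(guild == "bacterial")
  fung <- which(guild == "fungal")

  place_guild <- function(density, taxa_ids, quota) {
    counts <- stats::rpois(npts, density)
    pts <- rep(seq_len(npts), counts)
    n <- length(pts)
    taxon <- if (n > 0 && length(taxa_ids) > 0)
      taxa_ids[sample.int(length(taxa_ids), n, replace = TRUE)]
    else integer(0)
    list(pt = pts, taxon = taxon,
         C = rep(quota["C"], n), N = rep(quota["N"], n),
         P = rep(quota["P"], n))
  }
  cb <- if (length(bact)) place_guild(params$D_B, bact,
                                      initial_quota("bacterial", params))
        else empty_cells()
  cf <- if (length(fung)) place_guild(params$D_F, fung,
                                      initial_quota("fungal", params))
        else empty_cells()
  cells <- list(pt = c(cb$pt, cf$pt), taxon = c(cb$taxon, cf$taxon),
                C = unname(c(cb$C, cf$C)), N = unname(c(cb$N, cf$N)),
                P = unname(c(cb$P, cf$P)))
  make_world(community, params, T_c, cells)
}

#' Daily external inputs
#'
#' Adds the chemistry table's substrate and monomer inputs uniformly across
#' lattice points. Input rates are expressed as C; N and P are added in each
#' compound's fixed initial-pool stoichiometry, so inputs preserve substrate
#' stoichiometry. Dead-microbe and dead-enzyme pools receive no external
#' input (only mortality and enzyme decay feed them).
#'
#' @param w a \code{dement_world}.
#' @param params a \code{\link{dement_params}} list.
#' @return The updated world.
#' @export
apply_inputs <- function(w, params = dement_params()) {
  st <- substrate_table()
  rN <- ifelse(st$C0 > 0, st$N0 / st$C0, 0)
  rP <- ifelse(st$C0 > 0, st$P0 / st$C0, 0)
  w$subC <- sweep(w$subC, 2, st$input_sub, `+`)
  w$subN <- sweep(w$subN, 2, st$input_sub * rN, `+`)
  w$subP <- sweep(w$subP, 2, st$input_sub * rP, `+`)
  w$monC <- sweep(w$monC, 2, st$input_mon, `+`)
  w$monN <- sweep(w$monN, 2, st$input_mon * rN, `+`)
  w$monP <- sweep(w$monP, 2, st$input_mon * rP, `+`)
  w
}

#' Per-point daily input rates by element
#'
#' Totals of the chemistry table's substrate plus monomer inputs, used by the
#' daily mass-balance ledger.
#'
#' @param params a \code{\link{dement_params}} list.
#' @return Named vector c(C, N, P), mg cm^-3 day^-1 per lattice point.
#' @export
input_rates <- function(params = dement_params()) {
  st <- substrate_table()
  rN <- ifelse(st$C0 > 0, st$N0 / st$C0, 0)
  rP <- ifelse(st$C0 > 0, st$P0 / st$C0, 0)
  tot <- st$input_sub + st$input_mon
  c(C = sum(tot), N = sum(tot * rN), P = sum(tot * rP))
}

#' Daily leaching of dissolved pools
#'
#' Monomers and inorganic N/P are reduced by the fraction \code{leaching} per
#' day; polymeric substrates, enzymes and cells do not leach. Returns the
#' leached masses for the mass-balance ledger.
#'
#' @param w a \code{dement_world}.
#' @param params a \code{\link{dement_params}} list.
#' @return list(world, leached = c(C, N, P)).
#' @export
apply_leaching <- function(w, params = dement_params()) {
  L <- params$leaching
  leached <- c(
    C = L * sum(w$monC),
    N = L * (sum(w$monN) + sum(w$inorgN)),
    P = L * (sum(w$monP) + sum(w$inorgP))
  )
  w$monC <- w$monC * (1 - L)
  w$monN <- w$monN * (1 - L)
  w$monP <- w$monP * (1 - L)
  w$inorgN <- w$inorgN * (1 - L)
  w$inorgP <- w$inorgP * (1 - L)
  list(world = w, leached = leached)
}

#' Total element masses in the world
#'
#' Sums substrates, monomers, inorganic pools, enzymes and cell quotas.
#' Enzymes carry bound N at \code{Z_EN} times their C.
#'
#' @param w a \code{dement_world}.
#' @param params a \code{\link{dement_params}} list.
#' @return Named vector c(C, N, P) in mg.
#' @export
world_totals <- function(w, params = dement_params()) {
  enzC <- sum(w$enz)
  c(C = sum(w$subC) + sum(w$monC) + enzC + sum(w$cells$C),
    N = sum(w$subN) + sum(w$monN) + sum(w$inorgN) + params$Z_EN * enzC +
      sum(w$cells$N),
    P = sum(w$subP) + sum(w$monP) + sum(w$inorgP) + sum(w$cells$P))
}

#' Export per-point pools as a tidy table
#'
#' @param w a \code{dement_world}.
#' @return data.frame(point, pool, element, value) for substrates, monomers,
#'   inorganic nutrients and enzymes (total C).
#' @export
world_snapshot <- function(w) {
  st <- substrate_table()$substrate
  npts <- w$npts
  tidy <- function(m, pool, el)
    data.frame(point = rep(seq_len(npts), ncol(m)),
               pool = rep(pool, each = npts),
               element = el, value = as.vector(m))
  rbind(
    tidy(w$subC, paste0("substrate:", st), "C"),
    tidy(w$subN, paste0("substrate:", st), "N"),
    tidy(w$subP, paste0("substrate:", st), "P"),
    tidy(w$monC, paste0("monomer:", st), "C"),
    tidy(w$monN, paste0("monomer:", st), "N"),
    tidy(w$monP, paste0("monomer:", st), "P"),
    data.frame(point = seq_len(npts), pool = "inorganic_N", element = "N",
               value = w$inorgN),
    data.frame(point = seq_len(npts), pool = "inorganic_P", element = "P",
               value = w$inorgP),
    data.frame(point = seq_len(npts), pool = "enzymes", element = "C",
               value = rowSums(w$enz))
  )
}

#' @export
print.dement_world <- function(x, ...) {
  cat("<dement_world> ", x$nx, "x", x$ny, " lattice, day ", x$day,
      ", T = ", x$T, " C, ", n_cells(x), " cells\n", sep = "")
  cat("  substrate C ", round(sum(x$subC) / x$npts, 2),
      ", monomer C ", round(sum(x$monC) / x$npts, 3),
      ", biomass C ", round(sum(x$cells$C) / x$npts, 3),
      " mg cm^-3 (per-point means)\n", sep = "")
  invisible(x)
}
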