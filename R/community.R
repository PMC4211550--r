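#' Build the community enzyme pool
#'
#' Creates \code{n_enzymes} extracellular enzyme definitions. Each enzyme is
#' assigned a uniformly drawn number of target substrates (at least 1 of the
#' \code{n_substrates} organic substrates) and the specific targets are drawn
#' uniformly without replacement. Community-wide coverage is then repaired so
#' every substrate is degradable by at least \code{E_S} enzymes, by adding
#' each under-covered substrate to randomly chosen enzymes.
#'
#' A specificity-efficiency tradeoff reduces the per-substrate Vmax of
#' generalist enzymes: Vmax = V_E * n_targets^(-theta), so theta = 1 splits a
#' fixed total capacity across targets and theta = 0 disables the tradeoff.
#' Km is tied linearly to Vmax (Km = km_E_slope * Vmax + km_E_int).
#'
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @param params a \code{\link{dement_params}} list.
#' @return list of class \code{enzyme_pool}: \code{targets} (n_enzymes x
#'   n_substrates logical), \code{Vmax} and \code{Km} (same shape, 0 off
#'   target), \code{Ea} (per-substrate decay activation energies, kJ mol^-1),
#'   \code{Ea_K}.
#' @export
build_enzyme_pool <- function(seed = NULL, params = dement_params()) {
  if (!is.null(seed)) set.seed(seed)
  nE <- params$n_enzymes
  nS <- params$n_substrates
  if (nE < 1 || nE * nS < nS * params$E_S || nE < params$E_S)
    stop("build_enzyme_pool: cannot cover ", nS, " substrates with ",
         nE, " enzymes at E_S = ", params$E_S)
  targets <- matrix(FALSE, nE, nS)
  for (e in seq_len(nE)) {
    k <- sample.int(nS, 1L)
    targets[e, sample.int(nS, k)] <- TRUE
  }
  ## coverage repair: every substrate degradable by >= E_S enzymes
  for (s in seq_len(nS)) {
    short <- params$E_S - sum(targets[, s])
    if (short > 0) {
      cand <- which(!targets[, s])
      targets[cand[sample.int(length(cand), short)], s] <- TRUE
    }
  }
  n_t <- rowSums(targets)
  vmax_row <- params$V_E * n_t^(-params$theta)
  Vmax <- sweep(targets * 1, 1, vmax_row, `*`)
  Km <- (params$km_E_slope * Vmax + params$km_E_int) * targets
  st <- substrate_table()
  structure(list(targets = targets, Vmax = Vmax, Km = Km,
                 Ea = st$Ea[seq_len(nS)], Ea_K = params$Ea_Km),
            class = "enzyme_pool")
}

#' Build the community uptake transporter pool
#'
#' Creates \code{n_transporters} transporter definitions over the 14 uptake
#' targets: the 12 substrate-derived organic monomers plus inorganic N and
#' inorganic P released through mineralization. Target sets are drawn like
#' enzyme target sets and coverage is repaired so every uptake target is
#' reachable by at least \code{U_M} transporters. Vmax is constant across
#' transporters (no specificity tradeoff for uptake) and Km is tied linearly
#' to Vmax; at default parameters Km_U = 0.2 * 5 = 1 mg cm^-3.
#'
#' @inheritParams build_enzyme_pool
#' @return list of class \code{transporter_pool}: \code{targets}
#'   (n_transporters x 14 logical), \code{Vmax_U}, \code{Km_U}, \code{Ea_U},
#'   \code{Ea_K}.
#' @export
build_transporter_pool <- function(seed = NULL, params = dement_params()) {
  if (!is.null(seed)) set.seed(seed)
  nU <- params$n_transporters
  nM <- params$n_substrates + 2L   # organic monomers + inorganic N + P
  if (nU < 1 || nU < params$U_M)
    stop("build_transporter_pool: cannot cover ", nM, " targets with ",
         nU, " transporters at U_M = ", params$U_M)
  targets <- matrix(FALSE, nU, nM)
  for (u in seq_len(nU)) {
    k <- sample.int(nM, 1L)
    targets[u, sample.int(nM, k)] <- TRUE
  }
  for (m in seq_len(nM)) {
    short <- params$U_M - sum(targets[, m])
    if (short > 0) {
      cand <- which(!targets[, m])
      targets[cand[sample.int(length(cand), short)], m] <- TRUE
    }
  }
  structure(list(targets = targets,
                 Vmax_U = params$V_U,
                 Km_U = params$km_U_slope * params$V_U + params$km_U_int,
                 Ea_U = params$Ea_uptake, Ea_K = params$Ea_Km),
            class = "transporter_pool")
}

#' Generate virtual taxa with trait-linked intrinsic CUE
#'
#' Assigns each taxon a guild (bacterial or fungal, split by
#' \code{fungal_fraction}), an enzyme gene set of uniformly drawn size
#' (0..E_max enzymes sampled from the pool) and an uptake gene set of
#' uniformly drawn size (1..n_transporters). Gene sets are then repaired to
#' satisfy the uptake-coverage rule: every taxon must be able to take up at
#' least one organic monomer and every monomer released by the enzymes it
#' carries; missing coverage is fixed by adding randomly chosen transporters
#' that reach an uncovered monomer.
#'
#' Investment fractions are computed from the final gene sets, f_E =
#' n_enzyme_genes / E_max and f_U = n_uptake_genes / n_transporters, and the
#' rate-yield tradeoff sets intrinsic CUE as
#' eps_int = eps0 + f_E * m_E + f_U * m_U.
#'
#' @inheritParams build_enzyme_pool
#' @param enzymes an \code{enzyme_pool}.
#' @param transporters a \code{transporter_pool}.
#' @param n_taxa number of taxa.
#' @return list of class \code{taxa_set}: \code{guild} (character vector),
#'   \code{GE} (n_taxa x n_enzymes logical), \code{GU} (n_taxa x
#'   n_transporters logical), \code{f_E}, \code{f_U}, \code{eps_int},
#'   \code{n_enz_genes}, \code{n_upt_genes}, \code{reach} (n_taxa x 14
#'   logical union of transporter targets).
#' @export
generate_taxa <- function(seed = NULL, params = dement_params(),
                          enzymes, transporters,
                          n_taxa = params$n_taxa) {
  if (!is.null(seed)) set.seed(seed)
  nE <- params$n_enzymes
  nU <- params$n_transporters
  nS <- params$n_substrates
  nM <- nS + 2L
  n_f <- round(n_taxa * params$fungal_fraction)
  guild <- c(rep("bacterial", n_taxa - n_f), rep("fungal", n_f))

  GE <- matrix(FALSE, n_taxa, nE)
  GU <- matrix(FALSE, n_taxa, nU)
  for (i in seq_len(n_taxa)) {
    ke <- sample.int(params$E_max + 1L, 1L) - 1L  # uniform on 0..E_max
    if (ke > 0) GE[i, sample.int(nE, ke)] <- TRUE
    ku <- sample.int(nU, 1L)                      # uniform on 1..nU
    GU[i, sample.int(nU, ku)] <- TRUE
  }

  ## repair uptake coverage per taxon
  for (i in seq_len(n_taxa)) {
    repeat {
      reach <- colSums(transporters$targets[GU[i, ], , drop = FALSE]) > 0
      required <- colSums(enzymes$targets[GE[i, ], , drop = FALSE]) > 0
      missing <- which(required & !reach[seq_len(nS)])
      if (!length(missing) && any(reach[seq_len(nS)])) break
      m <- if (length(missing)) missing[1L] else sample.int(nS, 1L)
      cand <- which(transporters$targets[, m] & !GU[i, ])
      if (!length(cand))
        stop("generate_taxa: no transporter available for monomer ", m)
      GU[i, cand[sample.int(length(cand), 1L)]] <- TRUE
    }
  }

  n_enz <- rowSums(GE)
  n_upt <- rowSums(GU)
  f_E <- n_enz / params$E_max
  f_U <- n_upt / nU
  eps_int <- params$eps0 + f_E * params$m_E + f_U * params$m_U
  reach <- (GU %*% transporters$targets) > 0
  structure(list(guild = guild, GE = GE, GU = GU,
                 f_E = f_E, f_U = f_U, eps_int = eps_int,
                 n_enz_genes = n_enz, n_upt_genes = n_upt, reach = reach),
            class = "taxa_set")
}

#' Generate a full community (enzyme pool, transporter pool, taxa)
#'
#' Seeds the RNG once and draws the three components in a fixed order, so a
#' given seed always reproduces the identical community.
#'
#' @param seed integer seed.
#' @param params a \code{\link{dement_params}} list.
#' @return list of class \code{dement_community} with elements
#'   \code{enzymes}, \code{transporters}, \code{taxa}, \code{params}.
#' @export
generate_community <- function(seed, params = dement_params()) {
  set.seed(seed)
  enz <- build_enzyme_pool(NULL, params)
  trn <- build_transporter_pool(NULL, params)
  tax <- generate_taxa(NULL, params, enz, trn)
  structure(list(enzymes = enz, transporters = trn, taxa = tax,
                 params = params, seed = seed),
            class = "dement_community")
}

#' @export
print.dement_community <- function(x, ...) {
  tx <- x$taxa
  cat("<dement_community> ", length(tx$guild), " taxa (",
      sum(tx$guild == "bacterial"), " bacterial, ",
      sum(tx$guild == "fungal"), " fungal), ",
      nrow(x$enzymes$targets), " enzymes, ",
      nrow(x$transporters$targets), " transporters\n", sep = "")
  cat("  eps_int range [", round(min(tx$eps_int), 3), ", ",
      round(max(tx$eps_int), 3), "], mean enzyme genes ",
      round(mean(tx$n_enz_genes), 1), "\n", sep = "")
  invisible(x)
}

#' Serialize taxa to a tab-delimited table
#'
#' One row per taxon (guild, gene sets as `;`-delimited ID lists, investment
#' fractions, intrinsic CUE), so paired runs or external analyses can share
#' identical communities.
#'
#' @param community a \code{dement_community}.
#' @param path output file path.
#' @return The written data.frame, invisibly.
#' @export
write_community <- function(community, path) {
  tx <- community$taxa
  df <- data.frame(
    taxon_id = seq_along(tx$guild),
    guild = tx$guild,
    enzyme_genes = vapply(seq_along(tx$guild), function(i)
      paste(which(tx$GE[i, ]), collapse = ";"), character(1)),
    uptake_genes = vapply(seq_along(tx$guild), function(i)
      paste(which(tx$GU[i, ]), collapse = ";"), character(1)),
    f_E = tx$f_E, f_U = tx$f_U, eps_int = tx$eps_int,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a taxa table written by \code{\link{write_community}}
#'
#' @param path file path.
#' @return data.frame with one row per taxon.
#' @export
read_community <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
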