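# Small-scale fixtures built in code.

tiny_params <- function(...) {
  dement_params(x = 6, y = 6, days = 20, n_taxa = 12, ...)
}

# Hand-built community for oracle tests: explicit enzyme/transporter target
# matrices and per-taxon gene matrices, bypassing the random generators.
manual_community <- function(params, enz_targets, trn_targets, guild,
                             GE, GU) {
  nS <- params$n_substrates
  st <- substrate_table()
  n_t <- rowSums(enz_targets)
  vmax_row <- ifelse(n_t > 0, params$V_E * n_t^(-params$theta), 0)
  Vmax <- sweep(enz_targets * 1, 1, vmax_row, `*`)
  enz <- structure(list(
    targets = enz_targets, Vmax = Vmax,
    Km = (params$km_E_slope * Vmax + params$km_E_int) * enz_targets,
    Ea = st$Ea[seq_len(nS)], Ea_K = params$Ea_Km), class = "enzyme_pool")
  trn <- structure(list(
    targets = trn_targets, Vmax_U = params$V_U,
    Km_U = params$km_U_slope * params$V_U + params$km_U_int,
    Ea_U = params$Ea_uptake, Ea_K = params$Ea_Km),
    class = "transporter_pool")
  f_E <- rowSums(GE) / params$E_max
  f_U <- rowSums(GU) / params$n_transporters
  tax <- structure(list(
    guild = guild, GE = GE, GU = GU, f_E = f_E, f_U = f_U,
    eps_int = params$eps0 + f_E * params$m_E + f_U * params$m_U,
    n_enz_genes = rowSums(GE), n_upt_genes = rowSums(GU),
    reach = (GU %*% trn_targets) > 0), class = "taxa_set")
  structure(list(enzymes = enz, transporters = trn, taxa = tax,
                 params = params, seed = NA),
            class = "dement_community")
}

# one bacterial taxon, one enzyme targeting cellulose, one transporter for
# the cellulose monomer; used by the scalar-oracle and conservation tests
single_taxon_community <- function(params) {
  nS <- params$n_substrates
  et <- matrix(FALSE, 1, nS); et[1, 3] <- TRUE            # cellulose
  tt <- matrix(FALSE, 1, nS + 2); tt[1, 3] <- TRUE        # its monomer
  manual_community(params, et, tt, guild = "bacterial",
                   GE = matrix(TRUE, 1, 1), GU = matrix(TRUE, 1, 1))
}

# cells list helper
cells_at <- function(pt, taxon, C, N, P) {
  n <- length(pt)
  list(pt = as.integer(pt), taxon = as.integer(rep_len(taxon, n)),
       C = rep_len(C, n), N = rep_len(N, n), P = rep_len(P, n))
}
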