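#' Advance the world by one day
#'
#' Applies, in order: fungal translocation, enzymatic substrate degradation,
#' monomer uptake, CUE-partitioned growth, enzyme production, stoichiometric
#' homeostasis (overflow respiration and nutrient mineralization), mortality,
#' enzyme turnover, division and dispersal, leaching, and external inputs.
#' Returns a per-day flux ledger whose entries satisfy the element
#' conservation identities (respiration and leaching are the only C exits,
#' leaching the only N/P exit; everything else is an internal transfer).
#'
#' @param w a \code{dement_world}.
#' @param community a \code{dement_community}.
#' @param params a \code{\link{dement_params}} list.
#' @param ctx optional precomputed \code{\link{run_context}} (strongly
#'   recommended inside loops).
#' @return list(world, ledger) where ledger is a named numeric vector of the
#'   day's fluxes (all in mg over the whole lattice).
#' @export
step_day <- function(w, community, params = community$params,
                     ctx = run_context(community, params, w$T)) {
  w <- translocate(w, community, ctx)
  w <- degrade_substrates(w, community, params, ctx)

  grouping <- if (n_cells(w) > 0) pt_group(w$cells$pt) else NULL
  up <- take_up(w, community, params, ctx, grouping)
  w <- up$world

  nc <- n_cells(w)
  growth_resp <- 0; overflow <- 0; mineral_N <- 0; mineral_P <- 0
  prodC <- 0; prodN <- 0; uptake_C <- 0; growth_C <- 0
  if (nc > 0) {
    cs <- w$cells
    eps <- ctx$eps[cs$taxon]
    uptake_C <- sum(up$uptC)
    growth_C <- sum(eps * up$uptC)
    growth_resp <- uptake_C - growth_C
    cs$C <- cs$C + eps * up$uptC
    cs$N <- cs$N + up$uptN
    cs$P <- cs$P + up$uptP
    w$cells <- cs

    pe <- produce_enzymes(w, up$uptC, community, params, ctx)
    w <- pe$world
    prodC <- pe$prodC; prodN <- pe$prodN

    cs <- w$cells
    bal <- homeostasis(cs$C, cs$N, cs$P,
                       ctx$fC_up[cs$taxon], ctx$fN_up[cs$taxon],
                       ctx$fP_up[cs$taxon])
    w$cells$C <- bal$C; w$cells$N <- bal$N; w$cells$P <- bal$P
    overflow <- sum(bal$overflow)
    mineral_N <- sum(bal$minN)
    mineral_P <- sum(bal$minP)
    if (any(bal$minN > 0) || any(bal$minP > 0)) {
      upts <- grouping$upts
      w$inorgN[upts] <- w$inorgN[upts] + rowsum(bal$minN, grouping$grp)[, 1]
      w$inorgP[upts] <- w$inorgP[upts] + rowsum(bal$minP, grouping$grp)[, 1]
    }
  }

  mo <- mortality(w, community, params, ctx)
  w <- mo$world
  et <- enzyme_turnover(w, params)
  w <- et$world
  w <- divide_and_disperse(w, community, params, ctx)
  le <- apply_leaching(w, params)
  w <- le$world
  w <- apply_inputs(w, params)
  w$day <- w$day + 1L

  inp <- input_rates(params) * w$npts
  ledger <- c(
    input_C = unname(inp["C"]), input_N = unname(inp["N"]),
    input_P = unname(inp["P"]),
    uptake_C = uptake_C, growth_C = growth_C,
    growth_resp_C = growth_resp, overflow_resp_C = overflow,
    mineral_N = mineral_N, mineral_P = mineral_P,
    enz_prod_C = prodC, enz_prod_N = prodN,
    leach_C = unname(le$leached["C"]), leach_N = unname(le$leached["N"]),
    leach_P = unname(le$leached["P"]),
    death_C = unname(mo$dead["C"]), enz_decay_C = et$decayed_C,
    n_cells = n_cells(w)
  )
  if (!all(is.finite(ledger))) stop("step_day: non-finite ledger")
  list(world = w, ledger = ledger)
}

#' Run one simulation
#'
#' Generates (or receives) a community and an initialized world, then runs the
#' daily scheduler for \code{days} days, recording the time series used by the
#' paired-warming analysis: per-point mean substrate C, monomer C and biomass
#' C, the biomass-weighted community mean intrinsic CUE, per-taxon biomass,
#' and per-substrate pools. Scalar summaries are biomass-weighted means across
#' the whole run (days with zero biomass carry zero weight).
#'
#' The run is fully deterministic in (\code{seed}, parameters): the same seed
#' regenerates the same community, placement and dynamics. When a community
#' and world are supplied (as in paired runs), the dynamics RNG is still
#' seeded with \code{seed}, so two runs differing only in temperature share
#' every temperature-independent random draw.
#'
#' @param seed integer seed.
#' @param params a \code{\link{dement_params}} list.
#' @param T_c run temperature (degrees C).
#' @param days number of days to simulate.
#' @param scenario optional \code{"high"}/\code{"low"} tradeoff shortcut that
#'   overrides \code{m_E}/\code{m_U} via \code{\link{scenario_slopes}}.
#' @param community optional pre-generated \code{dement_community}.
#' @param world optional pre-initialized \code{dement_world} (its temperature
#'   is overridden by \code{T_c}).
#' @return A \code{dement_run}: list with \code{series} (daily data.frame,
#'   day 0 = initial state), \code{taxon_biomass} (taxa x days+1),
#'   \code{substrate_C} (substrates x days+1), \code{scalars}, and run
#'   metadata.
#' @export
run_simulation <- function(seed, params = dement_params(),
                           T_c = params$T_ref, days = params$days,
                           scenario = NULL, community = NULL, world = NULL) {
  if (!is.null(scenario)) {
    sl <- scenario_slopes(scenario)
    params$m_E <- sl$m_E
    params$m_U <- sl$m_U
  }
  if (is.null(community)) {
    community <- generate_community(seed, params)
    if (is.null(world)) world <- initialize_world(NULL, community, params, T_c)
  }
  if (is.null(world)) world <- initialize_world(seed, community, params, T_c)
  world$T <- T_c
  ctx <- run_context(community, params, T_c)
  set.seed(seed)

  n_taxa <- length(community$taxa$guild)
  nS <- params$n_substrates
  nrec <- days + 1L
  taxon_biomass <- matrix(0, n_taxa, nrec)
  substrate_C <- matrix(0, nS, nrec)
  ser_sub <- numeric(nrec); ser_mon <- numeric(nrec)
  ser_bio <- numeric(nrec); ser_cue <- rep(NA_real_, nrec)
  ser_nc <- integer(nrec)

  record <- function(w, i) {
    tb <- numeric(n_taxa)
    if (n_cells(w) > 0) {
      agg <- rowsum(w$cells$C, w$cells$taxon)
      tb[as.integer(rownames(agg))] <- agg[, 1]
    }
    taxon_biomass[, i] <<- tb
    substrate_C[, i] <<- colSums(w$subC)
    ser_sub[i] <<- sum(w$subC) / w$npts
    ser_mon[i] <<- sum(w$monC) / w$npts
    ser_bio[i] <<- sum(tb) / w$npts
    ser_nc[i] <<- n_cells(w)
    ser_cue[i] <<- if (sum(tb) > 0)
      sum(tb * community$taxa$eps_int) / sum(tb) else NA_real_
  }
  record(world, 1L)
  if (days > 0) {
    for (d in seq_len(days)) {
      st <- step_day(world, community, params, ctx)
      world <- st$world
      record(world, d + 1L)
    }
  }
  series <- data.frame(day = 0:days, substrate_C = ser_sub,
                       monomer_C = ser_mon, biomass_C = ser_bio,
                       cue_int = ser_cue, n_cells = ser_nc)

  bio_day <- colSums(taxon_biomass)
  wts <- bio_day
  wsum <- sum(wts)
  weighted <- function(v_taxon) {
    if (wsum <= 0) return(NA_real_)
    sum(taxon_biomass * v_taxon) / wsum
  }
  scalars <- list(
    cue_int_weighted = weighted(community$taxa$eps_int),
    mean_biomass_C = mean(series$biomass_C),
    mean_substrate_C = mean(series$substrate_C),
    mean_monomer_C = mean(series$monomer_C),
    mean_enzyme_genes = weighted(community$taxa$n_enz_genes),
    mean_uptake_genes = weighted(community$taxa$n_upt_genes),
    final_n_cells = series$n_cells[nrec]
  )
  structure(list(seed = seed, T = T_c, days = days,
                 scenario = if (is.null(scenario)) NA_character_ else scenario,
                 m_E = params$m_E, m_U = params$m_U,
                 series = series, taxon_biomass = taxon_biomass,
                 substrate_C = substrate_C, scalars = scalars,
                 world = world, community = community),
            class = "dement_run")
}

#' @export
print.dement_run <- function(x, ...) {
  s <- x$scalars
  cat("<dement_run> T = ", x$T, " C, ", x$days, " days, seed ", x$seed,
      if (!is.na(x$scenario)) paste0(", ", x$scenario, " tradeoff"), "\n",
      sep = "")
  cat("  biomass-weighted intrinsic CUE ", round(s$cue_int_weighted, 4),
      "; mean biomass C ", round(s$mean_biomass_C, 3),
      ", mean substrate C ", round(s$mean_substrate_C, 2),
      " mg cm^-3\n", sep = "")
  invisible(x)
}

#' Paired warming experiment
#'
#' For each pair, a fresh community is generated and the world initialized
#' from a pair-specific seed; the pair's two runs share that seed (identical
#' traits, placement and dynamics streams) and differ only in temperature.
#' Per-pair deltas (warm minus cool) of biomass-weighted intrinsic CUE, mean
#' biomass C and mean substrate C are tested against zero with one-sample
#' t-tests (equivalent to paired t-tests on the run pairs), and the
#' cross-pair relationships of the biomass and substrate deltas to the CUE
#' delta are fit by linear regression.
#'
#' @param seed root integer seed; pair seeds are drawn from it.
#' @param params a \code{\link{dement_params}} list.
#' @param scenario \code{"high"} or \code{"low"} tradeoff.
#' @param n_pairs number of simulation pairs.
#' @param T_low,T_high the two temperatures (degrees C).
#' @param days days per run.
#' @return A \code{dement_paired}: \code{pairs} data.frame (per-pair scalars
#'   and deltas), \code{t_tests} data.frame, \code{regressions} list, and
#'   metadata.
#' @export
run_paired_experiment <- function(seed, params = dement_params(),
                                  scenario = c("high", "low"),
                                  n_pairs = 20, T_low = 15, T_high = 20,
                                  days = params$days) {
  scenario <- match.arg(scenario)
  sl <- scenario_slopes(scenario)
  params$m_E <- sl$m_E
  params$m_U <- sl$m_U
  set.seed(seed)
  pair_seeds <- sample.int(2^30, n_pairs)

  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    ps <- pair_seeds[i]
    com <- generate_community(ps, params)
    w0 <- initialize_world(NULL, com, params, T_low)
    r_lo <- run_simulation(ps, params, T_low, days, community = com,
                           world = w0)
    r_hi <- run_simulation(ps, params, T_high, days, community = com,
                           world = w0)
    rows[[i]] <- data.frame(
      pair = i, seed = ps,
      cue_low = r_lo$scalars$cue_int_weighted,
      cue_high = r_hi$scalars$cue_int_weighted,
      biomass_low = r_lo$scalars$mean_biomass_C,
      biomass_high = r_hi$scalars$mean_biomass_C,
      substrate_low = r_lo$scalars$mean_substrate_C,
      substrate_high = r_hi$scalars$mean_substrate_C
    )
  }
  pairs <- do.call(rbind, rows)
  st <- paired_stats(pairs)
  structure(list(scenario = scenario, seed = seed, n_pairs = n_pairs,
                 T_low = T_low, T_high = T_high, days = days,
                 m_E = params$m_E, m_U = params$m_U,
                 pairs = st$pairs, t_tests = st$t_tests,
                 regressions = st$regressions),
            class = "dement_paired")
}

#' Paired-experiment statistics
#'
#' Computes the per-pair warming deltas, one-sample t-tests of each delta
#' against zero (equivalent to paired t-tests on the raw pairs), and linear
#' regressions of the biomass and substrate deltas on the CUE delta. Exposed
#' separately so the statistics can be applied to any table of paired run
#' summaries.
#'
#' @param pairs data.frame with columns \code{cue_low}, \code{cue_high},
#'   \code{biomass_low}, \code{biomass_high}, \code{substrate_low},
#'   \code{substrate_high}.
#' @return list(pairs, t_tests, regressions); when a delta is constant the
#'   t statistic and p value are flagged \code{NA}.
#' @export
paired_stats <- function(pairs) {
  pairs$d_cue <- pairs$cue_high - pairs$cue_low
  pairs$d_biomass <- pairs$biomass_high - pairs$biomass_low
  pairs$d_substrate <- pairs$substrate_high - pairs$substrate_low

  one_sample <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2 || stats::sd(x) == 0)
      return(c(mean = mean(x), t = NA_real_, p = NA_real_, n = length(x)))
    tt <- stats::t.test(x, mu = 0)
    c(mean = unname(tt$estimate), t = unname(tt$statistic),
      p = tt$p.value, n = length(x))
  }
  t_tests <- rbind(d_cue = one_sample(pairs$d_cue),
                   d_biomass = one_sample(pairs$d_biomass),
                   d_substrate = one_sample(pairs$d_substrate))
  t_tests <- data.frame(variable = rownames(t_tests), t_tests,
                        row.names = NULL)

  fit <- function(formula) {
    m <- stats::lm(formula, data = pairs)
    s <- summary(m)
    list(slope = unname(stats::coef(m)[2]),
         intercept = unname(stats::coef(m)[1]),
         r_squared = s$r.squared,
         p = if (nrow(s$coefficients) > 1) s$coefficients[2, 4] else NA_real_)
  }
  regressions <- list(
    biomass_vs_cue = fit(d_biomass ~ d_cue),
    substrate_vs_cue = fit(d_substrate ~ d_cue)
  )
  list(pairs = pairs, t_tests = t_tests, regressions = regressions)
}

#' @export
print.dement_paired <- function(x, ...) {
  cat("<dement_paired> ", x$scenario, " tradeoff, ", x$n_pairs, " pairs, ",
      x$T_low, " vs ", x$T_high, " C, ", x$days, " days\n", sep = "")
  cat("  mean delta intrinsic CUE (warm - cool): ",
      signif(mean(x$pairs$d_cue, na.rm = TRUE), 3),
      " (t = ", signif(x$t_tests$t[1], 3),
      ", p = ", signif(x$t_tests$p[1], 3), ")\n", sep = "")
  invisible(x)
}

#' Gene reductions equivalent to a target CUE adaptation
#'
#' Inverts the trait-CUE line (eps_int = eps0 + f_E m_E + f_U m_U) for the
#' average gene losses needed to raise intrinsic CUE by
#' \code{target_delta_cue}, splitting the gain equally between enzyme and
#' uptake investment: delta_n_E = (target/2) E_max / |m_E| and delta_n_U =
#' (target/2) N_U / |m_U|.
#'
#' @param target_delta_cue desired intrinsic CUE increase (mg mg^-1).
#' @param m_E,m_U tradeoff slopes (negative).
#' @param E_max maximum enzyme genes per taxon.
#' @param N_U number of uptake transporters.
#' @return Named vector c(enzyme_genes, uptake_genes).
#' @export
genes_for_adaptation <- function(target_delta_cue, m_E = -0.2, m_U = -0.2,
                                 E_max = 40, N_U = 14) {
  if (m_E >= 0 || m_U >= 0)
    stop("genes_for_adaptation: tradeoff slopes must be negative")
  c(enzyme_genes = target_delta_cue / 2 * E_max / abs(m_E),
    uptake_genes = target_delta_cue / 2 * N_U / abs(m_U))
}

#' Forward map: gene reductions to CUE change
#'
#' The companion of \code{\link{genes_for_adaptation}}: the intrinsic CUE
#' increase produced by shedding \code{d_enzyme} enzyme genes and
#' \code{d_uptake} uptake genes.
#'
#' @param d_enzyme,d_uptake average gene reductions.
#' @inheritParams genes_for_adaptation
#' @return Intrinsic CUE change (mg mg^-1).
#' @export
delta_cue_from_genes <- function(d_enzyme, d_uptake, m_E = -0.2, m_U = -0.2,
                                 E_max = 40, N_U = 14) {
  if (m_E >= 0 || m_U >= 0)
    stop("delta_cue_from_genes: tradeoff slopes must be negative")
  d_enzyme / E_max * abs(m_E) + d_uptake / N_U * abs(m_U)
}
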