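test_that("the day counter advances and the ledger stays finite", {
  p <- tiny_params()
  com <- generate_community(3, p)
  w <- initialize_world(NULL, com, p, 20)
  st <- step_day(w, com, p)
  expect_equal(st$world$day, 1L)
  expect_true(all(is.finite(st$ledger)))
  expect_true(all(st$ledger[c("growth_resp_C", "overflow_resp_C",
                              "leach_C", "leach_N", "leach_P",
                              "mineral_N", "mineral_P")] >= 0))
})

test_that("a uniform single-taxon world reproduces a scalar per-point oracle", {
  # one bacterial taxon, one cellulose enzyme, one monomer transporter; one
  # cell per point, random death off, division out of reach: every point is
  # an identical closed system, so a non-spatial scalar recurrence must
  # reproduce the lattice exactly
  p <- dement_params(x = 5, y = 5, n_enzymes = 1, n_transporters = 1,
                     n_taxa = 1, tau_B = 0, C_max_bact = 1e6)
  com <- single_taxon_community(p)
  Tc <- 25
  w <- make_world(com, p, T_c = Tc,
                  cells = cells_at(1:25, 1, C = 1, N = 0.19, P = 0.018))
  w$enz[, 1] <- 0.001
  ctx <- run_context(com, p, Tc)

  ## ---- independently coded scalar oracle (one lattice point) ----
  arr <- function(Ea) exp((-Ea * 1000 / 8.314) * (1 / (Tc + 273) - 1 / 293))
  VmaxT <- 100 * arr(36); KmT <- 1000 * arr(20)
  VU_T <- 5 * arr(35); KmU_T <- 1 * arr(20)
  eps_int <- 0.5 - 0.2 * (1 / 40) - 0.2 * (1 / 1)  # one-transporter pool: f_U = 1
  eps <- eps_int - 0.016 * (Tc - 20)
  sC <- 146.89; mC <- 0.045 * 146.89; lig <- 48.51
  cC <- 1; cN <- 0.19; cP <- 0.018; epool <- 0.001
  fCu <- 0.825 + 0.09; fNu <- 0.16 + 0.04; fPu <- 0.015 + 0.005
  days <- 10
  traj <- matrix(NA_real_, days, 5)
  for (d in 1:days) {
    mult <- 1 - 0.8 * lig / (lig + sC)
    decay <- min(mult * VmaxT * epool * sC / (KmT + sC), sC)
    sC <- sC - decay; mC <- mC + decay
    take <- min(VU_T * cC * mC / (KmU_T + mC), mC)
    mC <- mC - take
    cC <- cC + eps * take
    per <- 5e-5 * cC + 5e-5 * take
    f <- min(1, max(0, cC - 0.086) / per, max(0, cN - 0.012) / (0.3 * per))
    cC <- cC - f * per; cN <- cN - 0.3 * f * per; epool <- epool + f * per
    for (it in 1:8) {
      tot <- cC + cN + cP
      if (cC > fCu * tot) cC <- fCu * (cN + cP) / (1 - fCu)
      tot <- cC + cN + cP
      if (cN > fNu * tot) cN <- fNu * (cC + cP) / (1 - fNu)
      tot <- cC + cN + cP
      if (cP > fPu * tot) cP <- fPu * (cC + cN) / (1 - fPu)
    }
    epool <- epool * 0.96
    mC <- mC * 0.9
    sC <- sC + 0.4024; mC <- mC + 0.01811; lig <- lig + 0.1329
    traj[d, ] <- c(sC, mC, cC, cN, epool)
  }

  ## ---- lattice model ----
  set.seed(99)
  for (d in 1:days) {
    w <- step_day(w, com, p, ctx)$world
    expect_equal(unique(round(w$subC[, 3], 9)), round(traj[d, 1], 9))
    expect_equal(w$monC[1, 3], traj[d, 2], tolerance = 1e-10)
    expect_equal(w$cells$C[1], traj[d, 3], tolerance = 1e-10)
    expect_equal(w$cells$N[1], traj[d, 4], tolerance = 1e-10)
    expect_equal(w$enz[1, 1], traj[d, 5], tolerance = 1e-10)
  }
})

test_that("zero-length runs summarize the initial state", {
  p <- tiny_params()
  com <- generate_community(5, p)
  w <- initialize_world(NULL, com, p, 20)
  r <- run_simulation(5, p, 20, days = 0, community = com, world = w)
  expect_equal(nrow(r$series), 1)
  expect_equal(r$scalars$mean_substrate_C, sum(w$subC) / w$npts)
  expect_equal(r$scalars$mean_biomass_C, sum(w$cells$C) / w$npts)
})

test_that("community CUE is the biomass-weighted mean of taxon intrinsic CUE", {
  p <- dement_params(x = 4, y = 4, n_enzymes = 1, n_transporters = 1,
                     n_taxa = 2, fungal_fraction = 0)
  nS <- p$n_substrates
  et <- matrix(FALSE, 1, nS); et[1, 3] <- TRUE
  tt <- matrix(FALSE, 1, nS + 2); tt[1, 3] <- TRUE
  com <- manual_community(p, et, tt, c("bacterial", "bacterial"),
                          GE = matrix(TRUE, 2, 1), GU = matrix(TRUE, 2, 1))
  com$taxa$eps_int <- c(0.2, 0.4)
  w <- make_world(com, p, cells = list(
    pt = c(1L, 2L), taxon = c(1L, 2L), C = c(1, 3),
    N = c(0.19, 0.58), P = c(0.018, 0.054)))
  r <- run_simulation(1, p, 20, days = 0, community = com, world = w)
  expect_equal(r$scalars$cue_int_weighted, (1 * 0.2 + 3 * 0.4) / 4)
  # weighting bounded by the taxon range
  expect_gte(r$scalars$cue_int_weighted, 0.2)
  expect_lte(r$scalars$cue_int_weighted, 0.4)
})

test_that("runs are deterministic given seed and configuration", {
  p <- tiny_params(days = 8)
  r1 <- run_simulation(17, p, 20, days = 8, scenario = "high")
  r2 <- run_simulation(17, p, 20, days = 8, scenario = "high")
  expect_identical(r1$series, r2$series)
  expect_identical(r1$scalars, r2$scalars)
  expect_identical(as.character(run_summary_json(r1)),
                   as.character(run_summary_json(r2)))
})

test_that("paired runs at equal temperatures are stream-aligned (all deltas zero)", {
  p <- tiny_params(days = 12)
  pr <- run_paired_experiment(23, p, "high", n_pairs = 2, T_low = 20,
                              T_high = 20, days = 12)
  expect_equal(pr$pairs$d_cue, c(0, 0))
  expect_equal(pr$pairs$d_biomass, c(0, 0))
  expect_equal(pr$pairs$d_substrate, c(0, 0))
  expect_true(is.na(pr$t_tests$t[1]))   # undefined t flagged, not fabricated
})

test_that("paired statistics match closed-form t and OLS on hand-built pairs", {
  pairs <- data.frame(
    cue_low = c(0.30, 0.31, 0.29), cue_high = c(0.31, 0.33, 0.32),
    biomass_low = c(10, 10, 10), biomass_high = c(11, 12, 14),
    substrate_low = c(100, 100, 100), substrate_high = c(99, 103, 108))
  st <- paired_stats(pairs)
  d <- st$pairs$d_cue
  expect_equal(d, c(0.01, 0.02, 0.03))
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(st$t_tests$t[st$t_tests$variable == "d_cue"], t_hand)
  x <- d; y <- st$pairs$d_biomass
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2_hand <- sum((x - mean(x)) * (y - mean(y)))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(st$regressions$biomass_vs_cue$slope, slope_hand)
  expect_equal(st$regressions$biomass_vs_cue$intercept,
               mean(y) - slope_hand * mean(x))
  expect_equal(st$regressions$biomass_vs_cue$r_squared, r2_hand)
})

test_that("gene-equivalence inversion and forward map agree with the trait line", {
  g <- genes_for_adaptation(0.04, m_E = -0.2, m_U = -0.2)
  expect_equal(unname(g), c(4.0, 1.4))
  expect_equal(unname(genes_for_adaptation(0, -0.2, -0.2)), c(0, 0))
  # inversion round-trips through the forward map
  expect_equal(delta_cue_from_genes(g["enzyme_genes"], g["uptake_genes"],
                                    -0.2, -0.2), c(enzyme_genes = 0.04))
  # low-tradeoff slopes double the required gene loss
  g_lo <- genes_for_adaptation(0.04, m_E = -0.1, m_U = -0.1)
  expect_equal(unname(g_lo), c(8.0, 2.8))
  expect_error(genes_for_adaptation(0.04, m_E = 0.2), "negative")
})

test_that("run outputs round-trip to CSV and JSON", {
  p <- tiny_params(days = 5)
  r <- run_simulation(31, p, 20, days = 5, scenario = "low")
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  on.exit(unlink(c(csv, js)))
  df <- write_run_csv(r, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 6)
  expect_equal(back$subC_cellulose, r$substrate_C[3, ])
  run_summary_json(r, js)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$cue_int_weighted, r$scalars$cue_int_weighted)
  expect_equal(parsed$m_E, -0.1)
})
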