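sp <- function(...) dement_params(x = 4, y = 4, n_enzymes = 1,
                                  n_transporters = 1, n_taxa = 1,
                                  tau_B = 0, ...)

test_that("degradation matches a hand-computed single-point flux", {
  p <- sp()
  com <- single_taxon_community(p)
  w <- make_world(com, p)
  w$enz[5, 1] <- 0.02
  ctx <- run_context(com, p, 20)
  w2 <- degrade_substrates(w, com, p, ctx)

  S <- 146.89                     # cellulose is pure C
  mult <- 1 - 0.8 * 48.51 / (48.51 + 146.89)
  expected <- mult * (100 * 0.02) * S / (1000 + S)
  expect_equal(w$subC[5, 3] - w2$subC[5, 3], expected, tolerance = 1e-12)
  expect_equal(w2$monC[5, 3] - w$monC[5, 3], expected, tolerance = 1e-12)
  # all other points untouched
  expect_equal(w2$subC[-5, 3], w$subC[-5, 3])
  # no enzymes anywhere -> no decay
  w0 <- make_world(com, p)
  expect_equal(degrade_substrates(w0, com, p, ctx)$subC, w0$subC)
})

test_that("decay is capped at the standing pool under extreme enzyme loads", {
  p <- sp()
  com <- single_taxon_community(p)
  w <- make_world(com, p)
  w$enz[, 1] <- 1e9
  w2 <- degrade_substrates(w, com, p, run_context(com, p, 20))
  expect_true(all(w2$subC[, 3] >= 0))
  expect_equal(max(w2$subC[, 3]), 0)
  expect_equal(w2$monC[, 3], w$monC[, 3] + w$subC[, 3])
})

test_that("uptake saturates at capacity and respects transporter reach", {
  p <- sp()
  com <- single_taxon_community(p)
  w <- make_world(com, p, cells = cells_at(1, 1, C = 1, N = 0.19, P = 0.018))
  w$monC[] <- 0; w$monN[] <- 0; w$monP[] <- 0
  w$monC[1, 3] <- 1000            # S >> Km
  ctx <- run_context(com, p, 20)
  up <- take_up(w, com, p, ctx)
  expect_equal(up$uptC, 5 * 1 * 1000 / (1 + 1000), tolerance = 1e-12)
  expect_equal(up$uptN, 0)
  # pool the taxon cannot reach is untouched
  w$monC[1, 5] <- 50
  up2 <- take_up(w, com, p, ctx)
  expect_equal(up2$world$monC[1, 5], 50)
  expect_equal(up2$uptC, up$uptC)
})

test_that("two identical cells split a scarce local pool 50/50", {
  p <- sp()
  com <- single_taxon_community(p)
  w <- make_world(com, p,
                  cells = cells_at(c(7, 7), 1, C = 1, N = 0.19, P = 0.018))
  w$monC[] <- 0; w$monN[] <- 0; w$monP[] <- 0
  w$monC[7, 3] <- 0.01            # far less than joint demand
  up <- take_up(w, com, p, run_context(com, p, 20))
  expect_equal(up$uptC[1], up$uptC[2])
  expect_equal(sum(up$uptC), 0.01, tolerance = 1e-12)
  expect_equal(up$world$monC[7, 3], 0, tolerance = 1e-15)
})

test_that("realized CUE follows the linear temperature penalty with a floor at 0", {
  p <- dement_params()
  expect_equal(realized_cue(0.5, 20, p), 0.5)
  expect_equal(realized_cue(0.3, 25, p), 0.3 - 0.016 * 5)
  expect_equal(realized_cue(0.1, 15, p), 0.18)
  expect_equal(realized_cue(0.05, 30, p), 0)   # clamped
  # warming by 5 C costs every taxon 0.08 (absent clamping)
  eps <- c(0.1, 0.25, 0.4)
  expect_equal(realized_cue(eps, 15, p) - realized_cue(eps, 20, p),
               rep(0.08, 3))
})

test_that("growth partitions uptake C by CUE and homeostasis holds the bands", {
  p <- dement_params()
  fC <- p$frac_C_bact + p$tol_C
  fN <- p$frac_N_bact + p$tol_N
  fP <- p$frac_P_bact + p$tol_P
  # eps = 1, composition stays in band: no respiration at all
  r <- grow_and_balance(0.825, 0.160, 0.015, uptC = 0.05, uptN = 0.01,
                        uptP = 0.001, eps = 1, fC, fN, fP)
  expect_equal(r$growth_resp, 0)
  expect_equal(r$overflow, 0)
  expect_equal(r$C, 0.875)
  # eps = 0: all assimilated C respired, none retained
  r0 <- grow_and_balance(0.825, 0.160, 0.015, 0.5, 0, 0, eps = 0, fC, fN, fP)
  expect_equal(r0$growth_resp, 0.5)
  expect_equal(r0$C, 0.825)
  # pure-C overload: overflow restores the C fraction to its upper bound,
  # solved by hand from C' / (C' + N + P) = fC
  r2 <- grow_and_balance(0.825, 0.160, 0.015, uptC = 2, uptN = 0, uptP = 0,
                         eps = 1, fC, fN, fP)
  C_hand <- fC * (0.160 + 0.015) / (1 - fC)
  expect_equal(r2$C, C_hand, tolerance = 1e-12)
  expect_equal(r2$overflow, 2.825 - C_hand, tolerance = 1e-12)
  expect_equal(r2$N, 0.160)
  # pure-N overload mineralizes down to the N band
  r3 <- grow_and_balance(0.825, 0.160, 0.015, 0, uptN = 1, uptP = 0,
                         eps = 1, fC, fN, fP)
  expect_equal(r3$N / (r3$C + r3$N + r3$P), fN, tolerance = 1e-9)
  expect_equal(r3$minN, 1.160 - r3$N, tolerance = 1e-12)
  # conservation through the balance step
  expect_equal(r3$C + r3$N + r3$P + r3$minN + r3$minP + r3$overflow,
               0.825 + 1 + 0.160 + 0.015, tolerance = 1e-12)
})

test_that("enzyme production pays constitutive and inducible costs from quotas", {
  p <- dement_params(x = 4, y = 4, n_enzymes = 10, n_transporters = 1,
                     n_taxa = 1, tau_B = 0)
  nS <- p$n_substrates
  et <- matrix(FALSE, 10, nS); et[, 3] <- TRUE
  tt <- matrix(FALSE, 1, nS + 2); tt[1, 3] <- TRUE
  com <- manual_community(p, et, tt, "bacterial",
                          GE = matrix(TRUE, 1, 10), GU = matrix(TRUE, 1, 1))
  w <- make_world(com, p, cells = cells_at(2, 1, C = 1, N = 0.19, P = 0.018))
  ctx <- run_context(com, p, 20)
  out <- produce_enzymes(w, uptC = 0, com, p, ctx)
  expect_equal(out$prodC, 10 * 5e-5 * 1)       # constitutive only
  expect_equal(out$prodN, 0.3 * out$prodC)     # N cost fraction
  expect_equal(sum(out$world$enz[2, ]), out$prodC)
  expect_equal(out$world$cells$C, 1 - out$prodC)
  expect_equal(out$world$cells$N, 0.19 - out$prodN)
  # inducible component scales with gross uptake C
  out2 <- produce_enzymes(w, uptC = 0.4, com, p, ctx)
  expect_equal(out2$prodC, 10 * (5e-5 * 1 + 5e-5 * 0.4))
  # no enzyme genes -> no cost
  com0 <- manual_community(p, et, tt, "bacterial",
                           GE = matrix(FALSE, 1, 10), GU = matrix(TRUE, 1, 1))
  out0 <- produce_enzymes(w, 0.4, com0, p, run_context(com0, p, 20))
  expect_equal(out0$prodC, 0)
  expect_equal(out0$world$cells$C, 1)
})

test_that("enzyme production is pro-rated near the death thresholds", {
  p <- dement_params(x = 4, y = 4, n_enzymes = 10, n_transporters = 1,
                     n_taxa = 1, tau_B = 0)
  nS <- p$n_substrates
  et <- matrix(FALSE, 10, nS); et[, 3] <- TRUE
  tt <- matrix(FALSE, 1, nS + 2); tt[1, 3] <- TRUE
  com <- manual_community(p, et, tt, "bacterial",
                          GE = matrix(TRUE, 1, 10), GU = matrix(TRUE, 1, 1))
  # N quota sits just above N_min: only (N - N_min) worth of N cost is payable
  w <- make_world(com, p,
                  cells = cells_at(2, 1, C = 1, N = p$N_min + 1e-6, P = 0.018))
  out <- produce_enzymes(w, uptC = 0, com, p, run_context(com, p, 20))
  expect_equal(out$prodN, 1e-6, tolerance = 1e-10)
  expect_gte(out$world$cells$N, p$N_min - 1e-15)
  expect_lt(out$prodC, 10 * 5e-5)
})
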