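---
title: "Modeling carbon-use-efficiency adaptation to warming: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling carbon-use-efficiency adaptation to warming: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dementr)
```

## The scientific question

Microbial carbon use efficiency (CUE) — the fraction of assimilated carbon
allocated to biosynthesis rather than respired — is a leverage point in
microbially explicit soil carbon models: it sets how much decomposer biomass a
given carbon flux can sustain. CUE is usually assumed to decline linearly with
temperature, but communities may *adapt* to warming, i.e. their composition
may shift toward more efficient taxa so that the realized decline is smaller.
`dementr` implements two models of that adaptation built on a single
mechanism, the **rate–yield tradeoff**: acquiring resources faster (more
uptake transporters, more extracellular enzymes) carries a respiratory burden
that lowers growth yield.

## The analytical model

A homogeneous community grows at rate $G = U\,\varepsilon$, where uptake
follows Arrhenius scaling from its value $U_{ref}$ at the reference
temperature $T_{ref} = 20$ °C,

$$U = U_{ref}\exp\!\left[\frac{-E_a}{R}\left(\frac{1}{T+273} -
\frac{1}{T_{ref}+273}\right)\right],$$

realized CUE declines linearly in temperature,
$\varepsilon = \varepsilon_{int} + m_T (T - T_{ref})$, and intrinsic CUE
declines linearly in uptake investment,
$\varepsilon_{int} = \varepsilon_0 + m_U U_{ref}$ with $m_U < 0$. Maximizing
$G$ over $U_{ref}$ gives the closed forms implemented in `optimal_uref()` and
`optimal_eps_int()`:

$$U_{ref}^{*} = -\frac{\varepsilon_0 + m_T (T - T_{ref})}{2 m_U},
\qquad
\varepsilon_{int}^{*} = \frac{\varepsilon_0 - m_T (T - T_{ref})}{2}.$$

Two consequences drive everything else in the package. First,
$\varepsilon_{int}^{*}(T) - \varepsilon_{int}^{*}(T_{ref}) = -m_T (T -
T_{ref})/2$: a growth-maximizing community offsets exactly half of the
temperature-forced CUE decline, which at the defaults
($\varepsilon_0 = 0.5$, $m_T = -0.016$ mg mg$^{-1}$ °C$^{-1}$) is 0.04
mg mg$^{-1}$ for 5 °C of warming. Second, $\varepsilon_{int}^{*}$ does not
contain $m_U$: the *magnitude* of adaptation is independent of how steep the
tradeoff is, although maximum growth declines as $|m_U|$ grows. At $m_U = 0$
the optimum runs off to infinite uptake investment, so that case is an error
by design. The published expression for $\varepsilon_{int}^{*}$ is rendered
ambiguously in some sources; the form above is the unique one consistent with
substituting the optimal $U_{ref}$ into the tradeoff line, and the test suite
verifies it against a brute-force grid search of the growth curve
(step $10^{-4}$ on $U_{ref} \in [0,5]$, which brackets the optimum for every
parameter set used here).

The uptake-tradeoff scenarios for this model are $m_U = -0.4$ (high) and
$-0.2$ (low). The sources describing the model disagree internally about
which label goes with which slope; we follow the convention that the
*steeper* slope is the high-tradeoff scenario, and both values are plain
arguments so either mapping can be run.

```{r analytical}
p <- analytical_params()
optimal_eps_int(20, p) - optimal_eps_int(15, p)
analytical_sweep(c(15, 20, 25), p)
```

## The simulation model

The simulator is a DEMENT-style, spatially explicit, trait-based model of
litter decomposition. Its purpose here is to ask whether the analytical
optimum survives contact with stoichiometry, substrate specificity, and
spatial competition.

**World.** A 100 × 100 lattice with wrap-around boundaries (every point has
exactly 8 neighbors). Each point is nominally 1 cm³ and carries 12 polymeric
substrate pools (C, N, P), 12 matching monomer pools, inorganic N and P, and
one pool per community enzyme. Concentrations are mg cm⁻³. The substrate
chemistry (`substrate_table()`) describes grassland plant litter: initial
pools, daily inputs, and per-substrate decay activation energies; dead
microbial biomass and dead enzymes form two further pools that start empty
and are fed internally. Pools do not diffuse — no transport process between
points is modeled, so the only spatial fluxes are cell dispersal and fungal
translocation; local depletion is what lets taxa with different strategies
coexist. Inputs are spatially uniform, and input rates are carbon rates with
N and P following each compound's fixed stoichiometry. Monomers and
inorganic nutrients leach at $L = 0.1$ day⁻¹ (inorganic pools are dissolved
species, so they leach at the monomer rate); polymers, enzymes and cells do
not leach.

**Community generation.** The community is drawn once per run from a seed:
50 enzymes, each targeting a uniformly drawn subset of the 12 substrates
(coverage repaired so every substrate has at least `E_S` degraders), and 14
transporters over the 14 uptake targets (12 organic monomers + inorganic N
and P, coverage floor `U_M`). A specificity–efficiency tradeoff reduces a
generalist enzyme's per-substrate Vmax as $V_E\,n^{-\theta}$; with the
default $\theta = 1$ an enzyme splits a fixed total capacity across its
targets, and $\theta = 0$ turns the tradeoff off. The power form is our
choice — any monotone penalty of target count is defensible — because it
makes the two natural endpoints exact. Km is tied linearly to Vmax for both
enzymes (slope 10) and transporters (slope 0.2, giving $K_m^U = 1$ mg cm⁻³).

100 taxa (half bacterial, half fungal) each draw an enzyme gene set
(uniform size 0–40 from the 50-enzyme pool) and an uptake gene set (uniform
size 1–14). A taxon must be able to take up every monomer its own enzymes
release, and at least one organic monomer; violations are repaired by adding
randomly chosen transporters that cover the gap. The dead-microbe and
dead-enzyme monomers count as organic for this rule. Investment fractions
$f_E$ and $f_U$ are computed from the *final* gene sets — repair genes cost
CUE like any others, since the trait line is defined on possessed genes:

$$\varepsilon_{int} = \varepsilon_0 + f_E\,m_E + f_U\,m_U.$$

The warming experiment uses $m_E = m_U = -0.2$ (high tradeoff) and $-0.1$
(low tradeoff).

**Daily schedule.** Each day applies, in order: fungal translocation →
enzymatic degradation → uptake → growth → enzyme production → stoichiometric
homeostasis → mortality → enzyme turnover → division/dispersal → leaching →
inputs. Translocation is first by specification; the rest follows
source-to-sink causality (substrate must be degraded before it can be taken
up, growth happens on what was taken up, and enzyme costs are paid before
the final stoichiometric balance). The order is fixed in `step_day()` and
visible in its documentation.

Details per process:

* *Degradation*: per point and substrate, decay is the sum over enzymes of
  Michaelis–Menten fluxes with capacity Vmax × local enzyme concentration,
  capped at the standing pool. Substrate concentration is the compound's
  total mass. Cellulose decay is additionally penalized by the
  lignocellulose index LCI = lignin C / (lignin C + cellulose C) through the
  multiplier $\max(0,\,1 + \lambda\,\mathrm{LCI})$ with $\lambda = -0.8$
  (the standard litter-chemistry definition; an option extends the penalty
  to hemicellulose). Vmax and Km each follow their own Arrhenius factor;
  the Km activation energy (20 kJ mol⁻¹) is shared by enzymatic and uptake
  kinetics since a single value is specified for both.
* *Uptake*: a cell's capacity is $V_U$ × its C quota (uptake potential is
  proportional to cell mass), split equally across the monomers its
  transporters reach; each flux saturates in the local pool. When the
  summed demand at a point exceeds a pool, all takers are scaled
  proportionally — the allocation rule is unspecified in the source
  material, and proportional rationing is the neutral choice that preserves
  symmetry between identical cells. Organic monomers deliver C, N and P in
  the pool's current stoichiometry.
* *Growth*: realized CUE $\varepsilon = \varepsilon_{int} + m_T(T -
  T_{ref})$, clamped at 0 (energy stress is expressed through starvation
  rather than negative growth). $\varepsilon$ of the gross C uptake is
  retained; the remainder is growth respiration.
* *Enzyme production*: per possessed enzyme, a constitutive C cost
  ($5\times10^{-5}$ × cell C per day) plus an inducible cost
  ($5\times10^{-5}$ × the day's gross C uptake — total uptake, not
  enzyme-matched uptake, the simplest reading of induction), with N cost =
  0.3 × C cost. Costs are paid from quotas and pro-rated so production
  cannot push a quota below its death threshold.
* *Homeostasis*: biomass stoichiometry is partially homeostatic. Each guild
  has reference element fractions (bacteria 0.825/0.160/0.015 C/N/P, fungi
  0.900/0.090/0.010) with tolerances (0.090/0.040/0.005). C above the upper
  C-fraction band is respired as *overflow* — ledgered separately and
  excluded from intrinsic-CUE accounting — and N or P above band are
  mineralized to the local inorganic pools. Each excess is an exact
  one-unknown solve onto the band boundary; the three elements are relaxed
  sequentially and iterated (at most 8 passes; the upper bounds sum to more
  than 1, so a feasible composition always exists and the relaxation
  converges in one or two passes in practice).
* *Demography*: starvation death is deterministic when any quota falls below
  its minimum (0.086/0.012/0.002 mg); random death is first-order at
  $\tau_B = 0.02$, $\tau_F = 0.01$ day⁻¹. Dead cells join the dead-microbe
  pool, whose stoichiometry is unconstrained. Enzymes decay at
  $\tau_E = 0.04$ day⁻¹ into the dead-enzyme pool with their bound N.
  Division at the guild threshold (2 mg C bacterial, 50 mg fungal — fungal
  cells are 25× larger) splits all quotas 50/50; symmetric division is the
  minimal rule where none is specified. Bacterial offspring land uniformly
  on one of the 8 neighbors; fungal offspring move ±1 in y with total
  probability $\rho_y = 0.05$ and otherwise stay on the parent's point,
  which elongates fungal colonies along y (a config flag switches the
  stay-at-home alternative to a lateral x move). Offspring may stack; there
  is no crowding limit. Fungal taxa translocate: at the start of each day
  all cells of a fungal taxon have their quotas set to the taxon mean.

**Initialization.** Pools are uniform at the chemistry table values, with
monomers at $F_{MS} = 0.045$ of their substrate. Cells are placed by
per-point Poisson draws at densities 0.1 (bacteria) and 0.004 (fungi); each
cell starts at half its division threshold with reference stoichiometry, so
the 25× size ratio makes the two guilds start with equal expected biomass.

**The paired experiment.** For each of 20 pairs, a community is generated
and placed from a pair seed; the two runs share everything, including the
dynamics RNG seed, and differ only in temperature (15 vs 20 °C). Per-pair
warm-minus-cool deltas of (i) biomass-weighted mean intrinsic CUE over the
run, (ii) time-mean biomass C and (iii) time-mean substrate C are tested
against zero with one-sample t-tests — equivalent to paired t-tests on the
raw pairs — and the biomass and substrate deltas are regressed on the CUE
delta. Communities are regenerated per pair, so between-pair variation
includes trait-assignment randomness, while within-pair variation is purely
thermal. The t-tests and regressions call R's `t.test()` and `lm()`;
the test suite checks both against hand-written closed forms.

## What the generator emulates, and what it does not

The synthetic community and litter chemistry reproduce the study conditions
of the model: randomized trait assignment under coverage constraints, the
trait-linked CUE line, and a fixed grassland litter input regime. They do
not emulate real soil heterogeneity (no moisture, pH, mineral sorption or
3-D structure), trait evolution within a run (adaptation is purely
selection on a fixed trait pool), dormancy, or grazing. Passing tests
therefore demonstrate the internal consistency of the mechanism — that
warming selects for low-investment, high-CUE taxa and that this feedback
*reduces* decomposition — not that real soil communities will adapt by this
amount.

## Numerical choices

* All transfers are written as exact algebraic moves between pools, so daily
  element balances close to machine precision; the conservation test demands
  relative error ≤ 10⁻⁹ per day with full biology enabled.
* Degradation and uptake are capped at the standing pool (the saturating
  flux can overshoot in a 1-day step at high capacity).
* Michaelis–Menten fluxes define 0/0 → 0 at empty pools.
* Determinism: a run is a pure function of (seed, configuration); the same
  seed regenerates community, placement and dynamics bit-for-bit, and the
  summary JSON is byte-identical across invocations.
* Desk-scale experiments in the test suite use a 20 × 20 lattice, 500 days
  and 10 pairs per scenario — large enough for the selection signal and the
  cross-pair regressions to emerge, while a single pair runs in under a
  minute. The conservation audit uses 10 × 10 × 100 days. Full-scale runs
  (100 × 100, 5000 days, 20 pairs) use the same code path via
  `dement_params()` defaults.

## Known limitations

* The analytical optimum assumes a continuum of uptake investment; the
  simulator's gene counts are discrete, which (together with stoichiometric
  coverage requirements and reliance on neighbors' enzymes) is exactly why
  simulated adaptation falls short of the analytical prediction.
* The homeostasis relaxation resolves excesses in the fixed order C, N, P;
  a cell pathologically far outside all three bands could in principle
  depend on that order, though band geometry makes the fixed point unique
  in practice.
* At desk scale the fungal guild starts with very few individuals
  (0.004 × 400 points ≈ 1.6 cells), so fungal dynamics are noisy in small
  test lattices; at full scale the expected count is 40.
* Monomer uptake draws N and P in pool stoichiometry; cells cannot
  preferentially mine a monomer pool for a single element.
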