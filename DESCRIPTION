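Package: dementr
Title: Trait-Based Simulation of Microbial Carbon Use Efficiency Adaptation to Warming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two models of microbial carbon use efficiency (CUE) adaptation to
    warming built on the rate-yield tradeoff. A closed-form analytical model
    finds the intrinsic CUE that maximizes growth when uptake follows Arrhenius
    temperature scaling and CUE declines linearly with both temperature and
    uptake investment. A spatially explicit, trait-based, multi-taxon
    decomposition simulator (a DEMENT-style model) represents virtual bacterial
    and fungal taxa with randomly assigned extracellular enzymes and uptake
    transporters competing for litter substrates on a wrap-around lattice, with
    Michaelis-Menten kinetics, C:N:P stoichiometric homeostasis, overflow
    respiration, and demographic turnover. A paired-warming experiment driver
    runs seed-matched simulations at two temperatures and computes the
    community-level CUE adaptation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
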