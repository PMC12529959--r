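Package: micptrap
Title: Kinetic and Equilibrium Modeling of CO2 Trapping by Microbially
    Induced Carbonate Precipitation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the coupled chemistry of microbially induced calcium
    carbonate precipitation (MICP) and CO2 dissolution in a closed two-phase
    (gas/liquid) bottle reactor. Implements a 19-reaction mass-action network
    for the carbonate, ammonia and calcium system with gas-liquid transfer by
    Henry's law, Michaelis-Menten urease kinetics driven by an interpolated
    bacterial growth curve, an OD-dependent carbonic anhydrase rate law, and
    pH buffering by growth-media amino acids. Trajectories are obtained by
    stiff implicit integration (deSolve) with an analytic Jacobian; equilibrium
    states are solved algebraically from the equilibrium relations, element
    balances and a charge balance with pH as the pivot unknown. Includes named
    scenario presets for batch bottle experiments and continuous-injection
    reservoirs, parameter sweeps for solubility- and mineral-trapping capacity
    maps, and derived metrics such as the trapped-CO2 concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
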