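Package: mcreact
Title: Particle-Based Monte Carlo Reaction-Diffusion with Rule-Based Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale particle-based stochastic reaction-diffusion
    simulator with native rule-based reaction semantics. Chemistry is written
    in the BioNetGen language (BNGL): species and patterns are undirected
    graphs of elementary molecules with stateful binding components, and
    reactions are graph-rewriting rules resolved network-free at collision
    time, with species/reaction caches and periodic cleanup. Volume molecules
    diffuse as Brownian point particles inside triangulated meshes; surface
    molecules occupy barycentric grid tiles on membranes with volume
    exclusion. The scheduler executes release, diffuse-react, count and
    visualization events per fixed time step, supports reaction and wall-hit
    callbacks, and couples to explicit-Euler continuous species for hybrid
    stochastic-deterministic models. Includes bounded network expansion,
    ODE and Gillespie SSA oracles, ensemble statistics and low-pass peak
    detection for oscillatory models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
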