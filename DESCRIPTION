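Package: occlusim
Title: Mechanistic Simulation of Progressive Retinal Capillary Occlusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven simulator of progressive capillary occlusion in
    retinal microvascular networks. Couples Poiseuille network hemodynamics,
    conveyor-belt oxygen advection with inter-cellular diffusion and
    Michaelis-Menten consumption, hypoxia-driven VEGF synthesis, diffusion and
    decay on a generalized-cell contact graph, and stochastic VEGF- and
    flow-dependent capillary occlusion with threshold-VEGF edema. Ships three
    synthetic network generators (hexagonal lattice with deletions, peripheral
    arteriole-venule ladder, synthetic macular sector with a foveal avascular
    zone), replicate-ensemble drivers, patency maps, flow-oxygen phase
    trajectories and a one-at-a-time parameter sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
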