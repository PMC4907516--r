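## Replicate ensembles shared by the acceptance tests. Computed lazily, once
## per test run, under the same study conditions the acceptance script uses.

.ens_cache <- new.env(parent = emptyenv())

cached_macular_ensemble <- function(n = 30) {
  key <- paste0("mac", n)
  if (is.null(.ens_cache[[key]])) {
    sc <- macular_scenario(network_seed = 1)
    .ens_cache[[key]] <- list(
      scenario = sc,
      ensemble = run_ensemble(sc$network, sc$config, n_replicates = n,
                              first_occlusion = sc$forced_site))
  }
  .ens_cache[[key]]
}

cached_ladder_ensemble <- function(n = 20) {
  key <- paste0("lad", n)
  if (is.null(.ens_cache[[key]])) {
    sc <- peripheral_scenario(network_seed = 1)
    .ens_cache[[key]] <- list(
      scenario = sc,
      ensemble = run_ensemble(sc$network, sc$config, n_replicates = n,
                              first_occlusion = sc$forced_site))
  }
  .ens_cache[[key]]
}

cached_hex_steady <- function() {
  if (is.null(.ens_cache$hex)) {
    cfg <- sim_config()
    net <- assign_boundary_conditions(generate_hexagonal(seed = 1), cfg)
    flow <- solve_flow(net, cfg)
    tis <- build_tissue(net, cfg)
    ox <- run_oxygen_to_steady_state(net, flow, tis, cfg)
    .ens_cache$hex <- list(network = net, config = cfg, flow = flow,
                           tissue = tis, oxygen = ox)
  }
  .ens_cache$hex
}
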