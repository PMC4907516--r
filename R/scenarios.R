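#' Study scenarios
#'
#' The two disease scenarios the simulator is built around, bundled as
#' (network, configuration, forced initial occlusion site):
#'
#' * `macular_scenario()`: the synthetic juxtafoveal arteriole-venule sector
#'   under the default (calibrated) configuration, with the forced initial
#'   occlusion at the most vulnerable juxtafoveal capillary (largest induced
#'   hypoxic patch at the smallest inflow cost, see
#'   [pick_vulnerable_segment()]).
#' * `peripheral_scenario()`: the far-peripheral ladder network under the
#'   same kinetic constants but the low peripheral arteriovenous pressure
#'   gradient, with the forced initial occlusion at the middle rung of the
#'   middle A-V sector.
#'
#' @param network_seed seed for the network generator (the network is held
#'   fixed across replicates; replicate variability comes from the occlusion
#'   draws).
#' @param config optional configuration overriding the scenario default.
#' @return `list(network, config, forced_site)`.
#' @export
macular_scenario <- function(network_seed = 1L, config = sim_config()) {
  net <- assign_boundary_conditions(generate_macular_sector(seed = network_seed),
                                    config)
  list(network = net, config = config,
       forced_site = pick_vulnerable_segment(net, config, near_x = 260))
}

#' @rdname macular_scenario
#' @export
peripheral_scenario <- function(network_seed = 1L,
                                config = sim_config(p_art = 24.5, p_ven = 22)) {
  net <- assign_boundary_conditions(generate_peripheral_ladder(seed = network_seed),
                                    config)
  rungs <- net$segments[!net$segments$is_trunk, ]
  mid_sector <- stats::median(unique(rungs$sector))
  in_sector <- rungs$id[rungs$sector == mid_sector]
  list(network = net, config = config,
       forced_site = in_sector[ceiling(length(in_sector) / 2)])
}
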