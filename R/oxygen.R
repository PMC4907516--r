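#' Conveyor-belt discretization of a segment
#'
#' Each flowing segment is discretized into a chain of conveyor belts of size
#' `velocity * dt_flux`, so that one advection step moves oxygen exactly one
#' belt downstream at the local flow velocity. The last belt is truncated to
#' fit the segment length. Each belt is assigned to the capillary block (CAP)
#' that encloses its center; any oxygen already held by the segment's CAPs is
#' redistributed to the new belts proportionally to belt-block overlap, which
#' conserves the segment total exactly. A velocity of zero (or one so small
#' that the belt count would exceed `max_belts`) yields no chain: the segment
#' is stagnant and exchanges oxygen by diffusion only.
#'
#' @param segment one-row segment data.frame (`id`, `length`, `diameter`,
#'   `node_a`, `node_b`).
#' @param velocity signed flow velocity, um/s (positive = node_a -> node_b).
#' @param dt_flux advection time step, s.
#' @param cap_cells data.frame of the segment's CAP cells (`id`, `block`,
#'   `block_length`), ordered by block from node_a.
#' @param cap_volumes named oxygen volumes currently held by those CAPs.
#' @param config a [sim_config()].
#' @return a `conveyor_chain` (list) or `NULL` for a stagnant segment.
#' @export
discretize_belts <- function(segment, velocity, dt_flux, cap_cells,
                             cap_volumes = NULL, config = sim_config()) {
  if (abs(velocity) < 1e-9) return(NULL)
  L <- segment$length
  bs <- min(abs(velocity) * dt_flux, L / 2)  # at least two belts per chain
  n <- ceiling(L / bs)
  if (n > config$max_belts) return(NULL)  # effectively stagnant
  sizes <- rep(bs, n)
  sizes[n] <- L - (n - 1L) * bs
  if (n > 2L && sizes[n] < 1e-9 * bs) { n <- n - 1L; sizes <- sizes[1:n] }
  ends <- cumsum(sizes)
  centers_up <- ends - sizes / 2
  ## belt centers measured from the upstream node; block index is from node_a
  centers_a <- if (velocity >= 0) centers_up else L - centers_up
  bl <- cap_cells$block_length[1]
  nb <- nrow(cap_cells)
  blk <- pmin(nb, pmax(1L, floor(centers_a / bl) + 1L))
  cap <- cap_cells$id[match(blk, cap_cells$block)]
  area <- pi * segment$diameter^2 / 4
  vol <- numeric(n)
  if (!is.null(cap_volumes) && any(cap_volumes > 0)) {
    ## redistribute block oxygen by belt-block overlap (exact conservation)
    lo <- centers_a - sizes / 2; hi <- centers_a + sizes / 2
    for (b in seq_len(nb)) {
      b_lo <- (cap_cells$block[b] - 1L) * bl; b_hi <- cap_cells$block[b] * bl
      ov <- pmax(0, pmin(hi, b_hi) - pmax(lo, b_lo))
      cv <- cap_volumes[as.character(cap_cells$id[b])]
      if (is.na(cv)) cv <- 0
      vol <- vol + cv * ov / bl
    }
  }
  structure(list(segment_id = segment$id,
                 up_node = if (velocity >= 0) segment$node_a else segment$node_b,
                 down_node = if (velocity >= 0) segment$node_b else segment$node_a,
                 sizes = sizes,
                 geom_vol = area * sizes * max(1, abs(velocity) * dt_flux / bs),
                 vol = vol,
                 cap = cap, flow = abs(velocity) * area,
                 frac = sizes[n] / bs),
            class = "conveyor_chain")
}

#' Build all conveyor chains for the current flow solution
#'
#' @param network,flow,tissue,config current network, `flow_solution`,
#'   `tissue_model` and [sim_config()].
#' @param tension per-cell oxygen tensions used to seed belt volumes (the
#'   CAP content `alpha * C * V` is redistributed onto the belts).
#' @return named list of `conveyor_chain`s, keyed by segment id.
#' @export
build_chains <- function(network, flow, tissue, config, tension = NULL) {
  seg <- network$segments
  cells <- tissue$cells
  vel <- flow$segments$velocity[match(seg$id, flow$segments$id)]
  chains <- list()
  for (k in seq_len(nrow(seg))) {
    if (seg$state[k] == "occluded") next
    cap_cells <- cells[!is.na(cells$segment_id) &
                       cells$segment_id == seg$id[k], , drop = FALSE]
    cap_vol <- NULL
    if (!is.null(tension)) {
      idx <- match(cap_cells$id, cells$id)
      cap_vol <- stats::setNames(
        config$alpha_o2 * tension[idx] * cells$volume[idx],
        cap_cells$id)
    }
    ch <- discretize_belts(seg[k, ], vel[k], config$dt_flux, cap_cells,
                           cap_vol, config)
    if (!is.null(ch)) chains[[as.character(seg$id[k])]] <- ch
  }
  chains
}

#' One conveyor-belt advection step
#'
#' Every belt's volume moves one belt downstream. At junctions the last-belt
#' volumes of all chains flowing into a node are pooled and split among the
#' chains flowing out of it in proportion to their volumetric flows (blood
#' flow conservation); at boundary inlets the first belt is filled to the
#' node's inlet oxygen tension; at boundary outlets the last belt discharges
#' to the venous sink.
#'
#' @param chains list of `conveyor_chain`s (see [build_chains()]).
#' @param network the `vascular_network` (for boundary oxygen values).
#' @param config a [sim_config()].
#' @param node_outflow optional named vector of total volumetric outflow per
#'   junction node (all patent segments). When a node also feeds segments too
#'   slow to carry a conveyor chain, their share of the junction pool is
#'   surrendered (tallied as discharge) rather than concentrated into the
#'   chain-carrying branches. Defaults to the chain-carried outflow.
#' @return `list(chains, injected, discharged)` with the volumes that entered
#'   and left the network during the step.
#' @export
advect_step <- function(chains, network, config, node_outflow = NULL) {
  if (!length(chains)) return(list(chains = chains, injected = 0, discharged = 0))
  nd <- network$nodes
  bnd <- nd$id[nd$is_boundary]
  pool <- new.env(parent = emptyenv())
  out_flow <- new.env(parent = emptyenv())
  discharged <- 0
  for (ch in chains) {
    key <- as.character(ch$down_node)
    n <- length(ch$vol)
    ## the truncated last belt passes its content on; the fraction of the
    ## penultimate belt that overshoots the segment end passes through it
    ## within the same step (conservation of throughput)
    out <- ch$vol[n] + (1 - ch$frac) * ch$vol[n - 1L]
    if (ch$down_node %in% bnd) {
      discharged <- discharged + out
    } else {
      pool[[key]] <- (if (is.null(pool[[key]])) 0 else pool[[key]]) + out
    }
    ukey <- as.character(ch$up_node)
    out_flow[[ukey]] <- (if (is.null(out_flow[[ukey]])) 0 else out_flow[[ukey]]) +
      ch$flow
  }
  if (!is.null(node_outflow))
    for (nm in names(node_outflow))
      if (!is.null(out_flow[[nm]]))
        out_flow[[nm]] <- max(out_flow[[nm]], node_outflow[[nm]])
  injected <- 0
  for (nm in names(chains)) {
    ch <- chains[[nm]]
    n <- length(ch$vol)
    new_last <- ch$frac * ch$vol[n - 1L]
    if (n > 2L) ch$vol[2:(n - 1L)] <- ch$vol[1:(n - 2L)]
    ch$vol[n] <- new_last
    if (ch$up_node %in% bnd) {
      p_in <- nd$boundary_oxygen[match(ch$up_node, nd$id)]
      if (is.na(p_in)) p_in <- config$po2_inlet_scale * config$po2_art
      ch$vol[1] <- config$alpha_o2 * p_in * ch$geom_vol[1]
      injected <- injected + ch$vol[1]
    } else {
      key <- as.character(ch$up_node)
      pooled <- pool[[key]]
      total_out <- out_flow[[key]]
      if (is.null(pooled) || is.null(total_out) || total_out <= 0) {
        ch$vol[1] <- 0
      } else {
        ch$vol[1] <- pooled * ch$flow / total_out
      }
    }
    chains[[nm]] <- ch
  }
  taken <- new.env(parent = emptyenv())
  for (ch in chains) {
    key <- as.character(ch$up_node)
    if (!(ch$up_node %in% bnd))
      taken[[key]] <- (if (is.null(taken[[key]])) 0 else taken[[key]]) +
        ch$flow / out_flow[[key]]
  }
  for (key in ls(pool)) {
    tk <- if (is.null(taken[[key]])) 0 else min(taken[[key]], 1)
    discharged <- discharged + pool[[key]] * (1 - tk)
  }
  list(chains = chains, injected = injected, discharged = discharged)
}

#' Belt/CAP oxygen bookkeeping
#'
#' `belts_to_caps` sums every CAP's associated belt volumes into its
#' pre-diffusion oxygen volume. After diffusion, `caps_to_belts` rescales each
#' chain's belts by the host CAP's post/pre-diffusion volume ratio so the
#' belts carry the same relative change as the CAP (exact conservation); a
#' CAP with zero pre-diffusion volume leaves its belts at zero.
#'
#' @param chains list of `conveyor_chain`s.
#' @param ratio named numeric: post/pre-diffusion volume ratio per CAP id.
#' @return `belts_to_caps`: named numeric of pre-diffusion CAP volumes;
#'   `caps_to_belts`: the rescaled chains.
#' @export
belts_to_caps <- function(chains) {
  if (!length(chains)) return(numeric(0))
  cap <- unlist(lapply(chains, `[[`, "cap"), use.names = FALSE)
  vol <- unlist(lapply(chains, `[[`, "vol"), use.names = FALSE)
  out <- tapply(vol, cap, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' @rdname belts_to_caps
#' @export
caps_to_belts <- function(chains, ratio) {
  for (nm in names(chains)) {
    ch <- chains[[nm]]
    r <- ratio[as.character(ch$cap)]
    r[is.na(r)] <- 1
    ch$vol <- ch$vol * r
    chains[[nm]] <- ch
  }
  chains
}

## generic pairwise contact-surface exchange (explicit Euler), tension units;
## used by both oxygen and VEGF diffusion
exchange_step <- function(conc, cells, contact, k, dt, pinned = NULL,
                          pin_values = NULL) {
  flux <- k * contact$area * (conc[contact$i] - conc[contact$j]) * dt
  dvol <- numeric(length(conc))
  agg_i <- tapply(flux, contact$i, sum)
  agg_j <- tapply(flux, contact$j, sum)
  dvol[as.integer(names(agg_i))] <- dvol[as.integer(names(agg_i))] -
    as.numeric(agg_i)
  dvol[as.integer(names(agg_j))] <- dvol[as.integer(names(agg_j))] +
    as.numeric(agg_j)
  conc <- conc + dvol / cells$volume
  if (!is.null(pinned)) conc[pinned] <- pin_values
  conc
}

check_exchange_stability <- function(cells, contact, k, dt, what) {
  asum <- numeric(nrow(cells))
  ka <- k * contact$area
  agg_i <- tapply(ka, contact$i, sum)
  agg_j <- tapply(ka, contact$j, sum)
  asum[as.integer(names(agg_i))] <- asum[as.integer(names(agg_i))] +
    as.numeric(agg_i)
  asum[as.integer(names(agg_j))] <- asum[as.integer(names(agg_j))] +
    as.numeric(agg_j)
  lim <- max(dt * asum / cells$volume)
  if (lim >= 1)
    stop(sprintf(paste0("explicit %s exchange unstable (k*dt*A/V = %.3g >= 1): ",
                        "reduce dt_flux or coarsen the tiling"), what, lim),
         call. = FALSE)
  invisible(lim)
}

## per-contact oxygen exchange coefficient: vessel wall vs tissue-tissue
contact_k_o2 <- function(tissue, config) {
  ifelse(tissue$contact$wall, config$k_o2_wall, config$k_o2)
}

#' One inter-cellular oxygen diffusion step
#'
#' Pairwise flux `J_ij = k * A_ij * (C_i - C_j)` on the contact graph
#' (explicit Euler over `dt_flux`), with `k = k_o2` for tissue-tissue
#' contacts and `k = k_o2_wall` across the capillary wall; FAZ cells are
#' pinned at `po2_faz`. Total oxygen is conserved except at pinned cells.
#'
#' @param tension per-cell oxygen tensions, mmHg.
#' @param tissue a `tissue_model`.
#' @param config a [sim_config()].
#' @return updated tension vector.
#' @export
diffuse_step <- function(tension, tissue, config) {
  pin <- which(tissue$cells$kind == "FAZ")
  exchange_step(tension, tissue$cells, tissue$contact,
                contact_k_o2(tissue, config),
                config$dt_flux, pinned = pin,
                pin_values = rep(config$po2_faz, length(pin)))
}

#' One Michaelis-Menten oxygen consumption step
#'
#' Consumption `v_max_o2 * C / (k_m_o2 + C)` applies to Mueller cells and
#' other retinal cells only; tensions are floored at zero.
#'
#' @inheritParams diffuse_step
#' @return updated tension vector.
#' @export
consume_step <- function(tension, tissue, config) {
  kinds <- tissue$cells$kind
  use <- kinds == "MC" | kinds == "OT"
  rate <- config$v_max_o2 * tension[use] / (config$k_m_o2 + tension[use])
  tension[use] <- pmax(0, tension[use] - rate * config$dt_flux)
  tension
}

## total volumetric outflow per interior node over all patent segments
total_node_outflow <- function(network, flow) {
  seg <- network$segments
  v <- flow$segments$velocity[match(seg$id, flow$segments$id)]
  q <- abs(flow$segments$flow[match(seg$id, flow$segments$id)])
  up <- ifelse(v >= 0, seg$node_a, seg$node_b)
  keep <- seg$state != "occluded" & abs(v) >= 1e-9
  out <- tapply(q[keep], up[keep], sum)
  stats::setNames(as.numeric(out), names(out))
}

## geometric blood volume represented by the belts assigned to each CAP;
## this (not the anatomical block volume) converts a chain-fed CAP's summed
## belt volume to a tension, so that coarse belts (belt size above the block
## length) do not inflate the block tension
chain_cap_volumes <- function(chains) {
  if (!length(chains)) return(numeric(0))
  cap <- unlist(lapply(chains, `[[`, "cap"), use.names = FALSE)
  geom <- unlist(lapply(chains, `[[`, "geom_vol"), use.names = FALSE)
  out <- tapply(geom, cap, sum)
  stats::setNames(as.numeric(out), names(out))
}

## effective per-cell conversion volumes: anatomical, with chain-fed CAPs
## overridden by their assigned-belt geometric volume
effective_cell_volumes <- function(cells, chains) {
  vol <- cells$volume
  vconv <- chain_cap_volumes(chains)
  if (length(vconv)) {
    idx <- match(as.integer(names(vconv)), cells$id)
    vol[idx] <- vconv
  }
  vol
}

## one full oxygen flux iteration in R (reference path): advect -> sum belts
## to CAPs -> diffuse -> consume -> rescale belts by CAP post/pre ratio
oxygen_iteration_r <- function(tension, chains, network, tissue, config,
                               node_outflow = NULL) {
  cells <- tissue$cells
  volume <- effective_cell_volumes(cells, chains)
  adv <- advect_step(chains, network, config, node_outflow = node_outflow)
  chains <- adv$chains
  pre <- belts_to_caps(chains)
  if (length(pre)) {
    idx <- match(as.integer(names(pre)), cells$id)
    tension[idx] <- pre / (config$alpha_o2 * volume[idx])
  }
  tension <- diffuse_step_vol(tension, tissue, config, volume)
  consumed_before <- sum(config$alpha_o2 * tension * volume)
  tension <- consume_step(tension, tissue, config)
  consumed <- consumed_before - sum(config$alpha_o2 * tension * volume)
  if (length(pre)) {
    idx <- match(as.integer(names(pre)), cells$id)
    post <- config$alpha_o2 * tension[idx] * volume[idx]
    ratio <- ifelse(pre > 0, post / pre, 1)
    chains <- caps_to_belts(chains, stats::setNames(ratio, names(pre)))
  }
  list(tension = tension, chains = chains, injected = adv$injected,
       discharged = adv$discharged, consumed = consumed)
}

## diffuse_step against externally supplied conversion volumes
diffuse_step_vol <- function(tension, tissue, config, volume) {
  pin <- which(tissue$cells$kind == "FAZ")
  cells <- tissue$cells
  cells$volume <- volume
  exchange_step(tension, cells, tissue$contact,
                contact_k_o2(tissue, config),
                config$dt_flux, pinned = pin,
                pin_values = rep(config$po2_faz, length(pin)))
}

#' Run the oxygen field to steady state
#'
#' Iterates advection, belt-to-CAP conversion, diffusion and consumption (in
#' that order) with time step `dt_flux` until the maximum relative per-cell
#' tension change stays below `tol_ss` for `ss_window` consecutive
#' iterations. The production path runs in compiled code; `use_cpp = FALSE`
#' selects the reference R composition of the step operations (identical
#' update, for small problems and verification).
#'
#' @param network,flow,tissue,config current network, flow solution, tissue
#'   model and configuration.
#' @param init optional initial tension vector (warm start); defaults to zero
#'   tissue tension with pinned FAZ/boundary sources.
#' @param use_cpp run the compiled driver (default) or the R reference loop.
#' @param accelerate seed the iteration with a direct sparse steady solve
#'   (Newton on the consumption term, upwind block-level advection); the
#'   explicit iteration then verifies and polishes that state under the
#'   literal operator until the stopping rule is met. Purely a numerical
#'   accelerator: the accepted state is always a fixed point of the explicit
#'   iteration at tolerance `tol_ss`.
#' @return `list(tension, chains, iterations, converged, balance)`, where
#'   `balance` reports the final-iteration rates (volume/s): advective inflow,
#'   outflow, consumption and net storage change.
#' @export
run_oxygen_to_steady_state <- function(network, flow, tissue, config,
                                       init = NULL, use_cpp = TRUE,
                                       accelerate = use_cpp,
                                       init_direct = NULL) {
  cells <- tissue$cells
  check_exchange_stability(cells, tissue$contact, contact_k_o2(tissue, config),
                           config$dt_flux, "oxygen")
  tension <- if (is.null(init)) numeric(nrow(cells)) else init
  pin <- cells$kind == "FAZ"
  tension[pin] <- config$po2_faz
  direct <- NULL
  if (accelerate) {
    direct <- oxygen_direct_solve(network, flow, tissue, config,
                                  C0 = if (is.null(init)) NULL else init)
    tension <- direct
    ## carry the discretization offset (explicit fixed point minus direct
    ## solve) of the previous topology into the warm start; it is local to
    ## belt granularity and largely topology-independent
    if (!is.null(init) && !is.null(init_direct))
      tension <- pmax(0, direct + (init - init_direct))
    tension[pin] <- config$po2_faz
  }
  chains <- build_chains(network, flow, tissue, config, tension = tension)

  if (use_cpp) {
    arr <- flatten_flux_problem(tension, chains, network, tissue, config, flow)
    res <- oxygen_ss_cpp(arr$tension, arr$volume, arr$pin_idx, arr$pin_val,
                         arr$consume_idx, arr$ci, arr$cj, arr$karea,
                         arr$belt_vol, arr$belt_geom, arr$belt_cap,
                         arr$seg_off, arr$seg_n, arr$seg_up_pool,
                         arr$seg_down_pool, arr$seg_share, arr$seg_inlet_vol,
                         arr$seg_frac, arr$n_pools,
                         config$v_max_o2, config$k_m_o2,
                         config$alpha_o2, config$dt_flux, config$tol_ss,
                         as.integer(config$ss_window),
                         as.integer(config$ss_max_iter))
    chains <- unflatten_belts(chains, res$belt_vol)
    return(list(tension = as.numeric(res$tension), chains = chains,
                iterations = res$iterations, converged = res$converged,
                direct = direct,
                balance = list(inflow = res$injected / config$dt_flux,
                               outflow = res$discharged / config$dt_flux,
                               consumption = res$consumed / config$dt_flux)))
  }

  window <- 0L; it <- 0L
  bal <- NULL
  nof <- total_node_outflow(network, flow)
  while (it < config$ss_max_iter) {
    it <- it + 1L
    step <- oxygen_iteration_r(tension, chains, network, tissue, config,
                               node_outflow = nof)
    delta <- max(abs(step$tension - tension) / pmax(abs(tension), 0.1))
    tension <- step$tension; chains <- step$chains
    bal <- step
    window <- if (delta < config$tol_ss) window + 1L else 0L
    if (window >= config$ss_window) break
  }
  if (window < config$ss_window)
    stop(sprintf("oxygen steady state not reached in %d iterations (last max rel change %.3g)",
                 it, delta), call. = FALSE)
  list(tension = tension, chains = chains, iterations = it, converged = TRUE,
       balance = list(inflow = bal$injected / config$dt_flux,
                      outflow = bal$discharged / config$dt_flux,
                      consumption = bal$consumed / config$dt_flux))
}

## ---- flattening helpers shared with the compiled driver --------------------

flatten_flux_problem <- function(tension, chains, network, tissue, config, flow) {
  cells <- tissue$cells
  nd <- network$nodes
  bnd <- nd$id[nd$is_boundary]
  pin_idx <- which(cells$kind == "FAZ")
  consume_idx <- which(cells$kind %in% c("MC", "OT"))
  seg_n <- vapply(chains, function(ch) length(ch$vol), integer(1))
  belt_vol <- as.numeric(unlist(lapply(chains, `[[`, "vol"), use.names = FALSE))
  belt_geom <- as.numeric(unlist(lapply(chains, `[[`, "geom_vol"),
                                 use.names = FALSE))
  belt_cap <- match(as.numeric(unlist(lapply(chains, `[[`, "cap"),
                                      use.names = FALSE)), cells$id)
  if (!length(belt_cap)) belt_cap <- integer(0)
  seg_off <- c(0L, cumsum(seg_n))[seq_along(chains)]
  up <- vapply(chains, `[[`, numeric(1), "up_node")
  down <- vapply(chains, `[[`, numeric(1), "down_node")
  fl <- vapply(chains, `[[`, numeric(1), "flow")
  interior <- sort(unique(c(up[!(up %in% bnd)], down[!(down %in% bnd)])))
  up_pool <- ifelse(up %in% bnd, -1L, match(up, interior) - 1L)
  down_pool <- ifelse(down %in% bnd, -1L, match(down, interior) - 1L)
  ## total outflow per junction node over all patent segments (slow
  ## chainless branches surrender their share of the junction pool)
  seg_all <- network$segments
  q_all <- abs(flow$segments$flow[match(seg_all$id, flow$segments$id)])
  v_all <- flow$segments$velocity[match(seg_all$id, flow$segments$id)]
  up_all <- ifelse(v_all >= 0, seg_all$node_a, seg_all$node_b)
  patent <- seg_all$state != "occluded" & abs(v_all) >= 1e-9
  share <- numeric(length(chains))
  for (k in seq_along(chains)) {
    if (up_pool[k] >= 0) {
      tot <- sum(q_all[patent & up_all == up[k]])
      share[k] <- if (tot > 0) fl[k] / tot else 0
    }
  }
  inlet_vol <- numeric(length(chains))
  for (k in seq_along(chains)) {
    if (up_pool[k] < 0) {
      p_in <- nd$boundary_oxygen[match(up[k], nd$id)]
      if (is.na(p_in)) p_in <- config$po2_inlet_scale * config$po2_art
      inlet_vol[k] <- config$alpha_o2 * p_in * chains[[k]]$geom_vol[1]
    }
  }
  list(tension = tension,
       volume = effective_cell_volumes(cells, chains),
       pin_idx = as.integer(pin_idx - 1L),
       pin_val = rep(config$po2_faz, length(pin_idx)),
       consume_idx = as.integer(consume_idx - 1L),
       ci = as.integer(tissue$contact$i - 1L),
       cj = as.integer(tissue$contact$j - 1L),
       karea = contact_k_o2(tissue, config) * tissue$contact$area,
       belt_vol = belt_vol, belt_geom = belt_geom,
       belt_cap = as.integer(belt_cap - 1L),
       seg_off = as.integer(seg_off), seg_n = as.integer(seg_n),
       seg_up_pool = as.integer(up_pool), seg_down_pool = as.integer(down_pool),
       seg_share = share, seg_inlet_vol = inlet_vol,
       seg_frac = vapply(chains, `[[`, numeric(1), "frac"),
       n_pools = length(interior))
}

unflatten_belts <- function(chains, belt_vol) {
  off <- 0L
  for (nm in names(chains)) {
    n <- length(chains[[nm]]$vol)
    chains[[nm]]$vol <- belt_vol[(off + 1L):(off + n)]
    off <- off + n
  }
  chains
}
## direct sparse steady solve used to seed the explicit iteration.
## Tissue cells: pairwise contact exchange with Newton-linearized
## Michaelis-Menten consumption and an FAZ Dirichlet source. Capillary blocks
## on flowing segments follow the belt model's axial attenuation: within a
## block the relative rescale is uniform, so the transported tension decays
## multiplicatively with exponent beta * (1 - T/C) (beta = wall conductance /
## advective flow, T the host-tile tension); the factors are lagged over the
## outer Picard/Newton loop, which keeps each inner solve linear. The wall
## flux enters the host tile as kA (C_block - C_tile). Stagnant-segment
## blocks exchange by diffusion only.
oxygen_direct_solve <- function(network, flow, tissue, config, C0 = NULL,
                                newton_iter = if (is.null(C0)) 14 else 8,
                                damp = 0.7) {
  cells <- tissue$cells
  n <- nrow(cells)
  nd <- network$nodes
  seg <- network$segments
  bnd <- nd$id[nd$is_boundary]
  alpha <- config$alpha_o2
  faz <- which(cells$kind == "FAZ")
  consume <- cells$kind %in% c("MC", "OT")
  Vc <- cells$volume

  vel <- flow$segments$velocity[match(seg$id, flow$segments$id)]
  q <- abs(flow$segments$flow[match(seg$id, flow$segments$id)])
  flowing <- which(seg$state != "occluded" & abs(vel) >= 1e-9 &
                     (abs(vel) * config$dt_flux) >= seg$length / config$max_belts)
  cap_rows_all <- which(!is.na(cells$segment_id))
  cap_list <- split(cap_rows_all, cells$segment_id[cap_rows_all])
  flowing_cap <- logical(n)
  for (s in flowing) flowing_cap[cap_list[[as.character(seg$id[s])]]] <- TRUE

  ## exchange triplets; wall edges touching a flowing CAP act on the tile
  ## row only (the CAP row is the axial relation below); cap-cap lumen edges
  ## of flowing segments are absorbed into the axial chain
  ke <- contact_k_o2(tissue, config) * tissue$contact$area
  ci <- tissue$contact$i; cj <- tissue$contact$j
  cap_side_j <- tissue$contact$wall & flowing_cap[cj]  # j is the CAP
  both_cap <- tissue$contact$wall & flowing_cap[ci] & flowing_cap[cj]
  full <- !cap_side_j & !both_cap
  one_sided <- cap_side_j & !both_cap
  ti0 <- c(ci[full], cj[full], ci[full], cj[full],
           ci[one_sided], ci[one_sided])
  tj0 <- c(ci[full], cj[full], cj[full], ci[full],
           ci[one_sided], cj[one_sided])
  tx0 <- c(ke[full], ke[full], -ke[full], -ke[full],
           ke[one_sided], -ke[one_sided])

  seg_info <- vector("list", nrow(seg))
  for (s in flowing) {
    caps <- cap_list[[as.character(seg$id[s])]]
    caps <- caps[order(cells$block[caps])]
    if (vel[s] < 0) caps <- rev(caps)
    bl <- cells$block_length[caps]
    kA <- config$k_o2_wall * pi * seg$reference_diameter[s] * bl
    seg_info[[s]] <- list(
      caps = caps, tiles = cells$column[caps],
      beta = pmin(kA / (alpha * q[s]), 500),
      up = if (vel[s] >= 0) seg$node_a[s] else seg$node_b[s],
      down = if (vel[s] >= 0) seg$node_b[s] else seg$node_a[s])
  }
  axial <- which(flowing_cap)

  C <- if (is.null(C0)) rep(config$po2_art / 2, n) else pmax(C0, 0)
  for (nt in seq_len(newton_iter)) {
    ## lagged axial attenuation factors from the current iterate
    adv_i <- integer(0); adv_j <- integer(0); adv_x <- numeric(0)
    rhs_adv <- numeric(n)
    for (s in flowing) {
      info <- seg_info[[s]]
      cbar <- pmax(C[info$caps], 1e-3)
      tt <- C[info$tiles]
      x <- pmax(pmin(info$beta * (1 - tt / cbar), 60), 0)
      phi <- exp(-x)
      psi <- ifelse(abs(x) > 1e-9, (1 - phi) / x, 1)
      psi <- pmax(psi, 1e-6)
      seg_info[[s]]$phi <- phi; seg_info[[s]]$psi <- psi
      m <- length(info$caps)
      rs <- alpha * q[s]          # row scale, balances the exchange rows
      if (m > 1) {
        k1 <- seq_len(m - 1)
        adv_i <- c(adv_i, info$caps[k1 + 1], info$caps[k1 + 1])
        adv_j <- c(adv_j, info$caps[k1 + 1], info$caps[k1])
        adv_x <- c(adv_x, rep(rs, m - 1),
                   -rs * pmax(psi[k1 + 1] * phi[k1] / psi[k1], 1e-12))
      }
      adv_i <- c(adv_i, info$caps[1]); adv_j <- c(adv_j, info$caps[1])
      adv_x <- c(adv_x, rs)
    }
    for (s in flowing) {
      info <- seg_info[[s]]
      c1 <- info$caps[1]
      if (info$up %in% bnd) {
        p_in <- nd$boundary_oxygen[match(info$up, nd$id)]
        if (is.na(p_in)) p_in <- config$po2_inlet_scale * config$po2_art
        rhs_adv[c1] <- rhs_adv[c1] + alpha * q[s] * info$psi[1] * p_in
      } else {
        feeders <- flowing[vapply(flowing, function(f)
          seg_info[[f]]$down == info$up, logical(1))]
        ## the belt model splits the junction pool over the total nodal
        ## outflow (chainless slow branches surrender their share)
        up_all <- ifelse(vel >= 0, seg$node_a, seg$node_b)
        pat_all <- seg$state != "occluded" & abs(vel) >= 1e-9
        qout <- sum(q[pat_all & up_all == info$up])
        if (qout > 0) for (f in feeders) {
          fi <- seg_info[[f]]
          m <- length(fi$caps)
          adv_i <- c(adv_i, c1)
          adv_j <- c(adv_j, fi$caps[m])
          adv_x <- c(adv_x, -alpha * q[s] * info$psi[1] * (q[f] / qout) *
                       pmax(fi$phi[m] / fi$psi[m], 1e-12))
        }
      }
    }
    a <- numeric(n); b <- numeric(n)
    cp <- pmax(C[consume], 0)
    a[consume] <- config$v_max_o2 * config$k_m_o2 / (config$k_m_o2 + cp)^2
    b[consume] <- config$v_max_o2 * cp / (config$k_m_o2 + cp) - a[consume] * cp
    TI <- c(ti0, seq_len(n))
    TJ <- c(tj0, seq_len(n))
    TX <- c(tx0, a * Vc)
    rhs <- -b * Vc
    drop_ax <- TI %in% axial
    TI <- c(TI[!drop_ax], adv_i); TJ <- c(TJ[!drop_ax], adv_j)
    TX <- c(TX[!drop_ax], adv_x)
    rhs[axial] <- rhs_adv[axial]
    drop <- TI %in% faz
    A <- Matrix::sparseMatrix(i = c(TI[!drop], faz), j = c(TJ[!drop], faz),
                              x = c(TX[!drop], rep(1, length(faz))),
                              dims = c(n, n))
    rhs[faz] <- config$po2_faz
    C_new <- tryCatch(pmax(as.numeric(Matrix::solve(A, rhs)), 0),
                      error = function(e) NULL)
    if (is.null(C_new)) break   # fall back to the explicit iteration
    step <- max(abs(C_new - C))
    C <- damp * C_new + (1 - damp) * C
    if (step < 2e-3) break
  }
  C
}
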