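#' Update leaky states from the VEGF field
#'
#' A normal capillary segment turns leaky when its VEGF level (mean over its
#' capillary blocks) strictly exceeds the threshold `vegf_leak_thr`; a leaky
#' segment whose VEGF has fallen back returns to normal. Occluded segments
#' never change state, and trunk segments (arterioles, venules, shunts) never
#' leak - their muscular walls are not the site of VEGF-driven breakdown of
#' the blood-retinal barrier.
#'
#' @param network a `vascular_network`.
#' @param seg_vegf named per-segment VEGF from [segment_vegf()].
#' @param config a [sim_config()].
#' @return the network with updated segment states.
#' @export
check_leaky <- function(network, seg_vegf, config) {
  st <- network$segments$state
  v <- seg_vegf[as.character(network$segments$id)]
  above <- !is.na(v) & v > config$vegf_leak_thr & !network$segments$is_trunk
  st[st == "normal" & above] <- "leaky"
  st[st == "leaky" & !above] <- "normal"
  network$segments$state <- st
  network
}

#' Create an empty edema state
#'
#' Retinal edema is tracked as fluid volume accumulated per tissue column
#' (one column per tissue tile); thickness = base thickness + fluid column
#' height. Fluid portions are created next to leaky capillaries and drained
#' at the bottom of the system (retinal pigment epithelium) by a weekly
#' quota.
#'
#' @param tissue a `tissue_model`.
#' @return an `edema_state` list: `fluid` (um^3 per column), `created`,
#'   `removed` (running totals, um^3).
#' @export
edema_state <- function(tissue) {
  n_col <- tissue$grid$nx * tissue$grid$ny
  structure(list(fluid = numeric(n_col), created = 0, removed = 0),
            class = "edema_state")
}

#' Weekly edema formation and drainage
#'
#' Adds one fluid unit (`fp_unit_volume`) beside every capillary block of
#' every leaky segment, then drains up to `fp_removal_volume` from each
#' column holding fluid. Net thickening therefore requires sustained
#' leakage.
#'
#' @param network current `vascular_network` (leaky states current).
#' @param edema an `edema_state`.
#' @param tissue a `tissue_model`.
#' @param config a [sim_config()].
#' @return the updated `edema_state`.
#' @export
form_edema <- function(network, edema, tissue, config) {
  leaky <- network$segments$id[network$segments$state == "leaky"]
  if (length(leaky)) {
    caps <- tissue$cells[!is.na(tissue$cells$segment_id) &
                         tissue$cells$segment_id %in% leaky, , drop = FALSE]
    add <- tapply(rep(config$fp_unit_volume, nrow(caps)), caps$column, sum)
    idx <- as.integer(names(add))
    edema$fluid[idx] <- edema$fluid[idx] + as.numeric(add)
    edema$created <- edema$created + config$fp_unit_volume * nrow(caps)
  }
  drain <- pmin(edema$fluid, config$fp_removal_volume)
  edema$fluid <- edema$fluid - drain
  edema$removed <- edema$removed + sum(drain)
  edema
}

#' Thickness map
#'
#' @param edema an `edema_state`.
#' @param tissue a `tissue_model`.
#' @return numeric vector of per-column thickness, um (base + fluid height).
#' @export
thickness_map <- function(edema, tissue) {
  area <- tissue$grid$px * tissue$grid$py
  tissue$base_thickness + edema$fluid / area
}

#' Occlusion probability per check
#'
#' `p = p_occ_max * V^h / (V^h + vegf_half^h) * exp(-|v| / vel_scale)`:
#' a Hill function of the segment VEGF level (strictly increasing) with
#' exponential protection by flow velocity (strictly decreasing), reflecting
#' VEGF-driven ICAM-mediated leukostasis opposed by shear washout.
#'
#' @param segment_vegf VEGF level(s), A.U.
#' @param segment_velocity flow velocity (um/s); the magnitude is used.
#' @param config a [sim_config()].
#' @return probability (or vector) in `[0, p_occ_max]`.
#' @export
occlusion_probability <- function(segment_vegf, segment_velocity, config) {
  v <- pmax(0, segment_vegf)
  h <- config$hill_h
  hill <- ifelse(v > 0, v^h / (v^h + config$vegf_half^h), 0)
  p <- config$p_occ_max * hill * exp(-abs(segment_velocity) / config$vel_scale)
  names(p) <- names(segment_vegf)
  p
}

#' Monthly stochastic occlusion checks
#'
#' One independent Bernoulli draw per patent non-trunk segment, in ascending
#' segment-id order from the current RNG stream; successes occlude the whole
#' segment (irreversibly). Trunk segments are never drawn - they can only be
#' lost by disconnection.
#'
#' @param network a `vascular_network`.
#' @param seg_vegf named per-segment VEGF levels.
#' @param flow current `flow_solution`.
#' @param config a [sim_config()].
#' @return `list(network, occluded_ids)`.
#' @export
apply_occlusion_checks <- function(network, seg_vegf, flow, config) {
  seg <- network$segments
  cand <- which(seg$state != "occluded" & !seg$is_trunk)
  cand <- cand[order(seg$id[cand])]
  if (!length(cand)) return(list(network = network, occluded_ids = integer(0)))
  vel <- flow$segments$velocity[match(seg$id[cand], flow$segments$id)]
  p <- occlusion_probability(seg_vegf[as.character(seg$id[cand])], vel, config)
  hit <- stats::runif(length(cand)) < p
  ids <- seg$id[cand][hit]
  if (length(ids)) network <- occlude(network, ids, config)
  list(network = network, occluded_ids = ids)
}
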