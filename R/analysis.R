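#' Shape checks for a progressive trajectory
#'
#' The qualitative signatures of a progressive macular run: (a) non-monotone
#' total inflow (a genuine rise after an earlier minimum, followed by decline
#' below 90\% of the pre-occlusion baseline), (b) monotone non-decreasing
#' scaled minimal cell-to-vessel distance, (c) transition of the cellular
#' oxygen histogram from unimodal to at least bimodal, (d) clockwise
#' flow-oxygen phase passage: after mean oxygen has fallen below 85\% of
#' baseline, total inflow is at least as high as it ever was while oxygen
#' was still near-normal - the oxygen decline leads the flow decline, which
#' is passage through the high-flow/low-oxygen zone. This quadrant-passage
#' reading of orientation is robust for open trajectories (including runs
#' still in the hyperemic transition stage); the net signed area of
#' [phase_orientation()] is dominated by the arbitrary closing chord.
#'
#' @param trajectory a `trajectory` from [run_simulation()].
#' @param rise_frac minimum relative rise that counts as hyperemic recovery.
#' @return named logical vector with elements `rise_then_fall`,
#'   `dmin_monotone`, `bimodal_transition`, `clockwise`.
#' @export
trajectory_shape_checks <- function(trajectory, rise_frac = 0.01) {
  ck <- trajectory$checkpoints
  base <- ck$total_inflow[1]
  x <- ck$total_inflow[ck$model_week >= 0]
  rise_then_fall <- FALSE
  if (length(x) >= 3) {
    for (t1 in seq_len(length(x) - 2)) {
      later <- (t1 + 1):length(x)
      t2 <- later[which(x[later] >= x[t1] + rise_frac * base)]
      if (length(t2)) {
        t2 <- t2[1]
        if (t2 < length(x) && any(x[(t2 + 1):length(x)] < 0.9 * base)) {
          rise_then_fall <- TRUE
          break
        }
      }
    }
  }
  dmin_monotone <- all(diff(ck$mean_dmin_scaled) >= -1e-9)
  h <- trajectory$histograms
  bimodal_transition <- length(h) >= 2 &&
    count_modes(h[[1]]) == 1 && count_modes(h[[length(h)]]) >= 2
  ## clockwise passage: once oxygen has fallen well below the normal
  ## condition, flow is at least what it was, post-onset, while oxygen was
  ## still near-normal - the oxygen decline leads the flow decline
  ## (counterclockwise would be the reverse). The pre-onset equilibrium is
  ## the reference state, not part of the traced loop.
  post <- ck[ck$model_week >= 0, ]
  o2 <- post$mean_mc_o2 / ck$mean_mc_o2[1]
  low_o2 <- o2 < 0.85
  flow_before <- suppressWarnings(max(post$total_inflow[o2 >= 0.92]))
  clockwise <- any(low_o2) && is.finite(flow_before) &&
    any(post$total_inflow[low_o2] >= flow_before - 0.02 * base)
  c(rise_then_fall = rise_then_fall,
    dmin_monotone = dmin_monotone,
    bimodal_transition = bimodal_transition,
    clockwise = clockwise)
}

#' Locality of secondary occlusions
#'
#' Pools, over an ensemble with a common forced initial occlusion, the graph
#' (hop) distances from the initial site to every secondary occlusion, and
#' compares their mean with a uniform-random null over the segments at risk
#' on the same network by permutation.
#'
#' @param ensemble an `ensemble_summary` run with a fixed network and forced
#'   initial site.
#' @param network the shared `vascular_network`.
#' @param forced_site the forced initial segment id.
#' @param n_perm number of permutation resamples.
#' @param seed RNG seed for the permutation draw.
#' @return `list(observed_mean, null_mean, p_value, n_secondary)`.
#' @export
occlusion_locality <- function(ensemble, network, forced_site,
                               n_perm = 2000, seed = 1L) {
  d <- segment_graph_distances(network, forced_site)
  at_risk <- network$segments$id[!network$segments$is_trunk &
                                   network$segments$id != forced_site]
  obs <- unlist(lapply(ensemble$runs, function(r) {
    if (is.null(r)) return(numeric(0))
    ev <- r$events
    sec <- ev$segment_id[ev$event == "occlusion" & ev$segment_id != forced_site]
    d[as.character(sec)]
  }))
  obs <- obs[is.finite(obs)]
  if (!length(obs))
    return(list(observed_mean = NA_real_, null_mean = NA_real_,
                p_value = NA_real_, n_secondary = 0L))
  set.seed(seed)
  null_means <- replicate(n_perm, mean(d[as.character(
    sample(at_risk, length(obs), replace = TRUE))]))
  list(observed_mean = mean(obs),
       null_mean = mean(null_means),
       p_value = (sum(null_means <= mean(obs)) + 1) / (n_perm + 1),
       n_secondary = length(obs))
}

#' Sector confinement of ladder occlusions
#'
#' Follows, for each replicate of a peripheral-ladder ensemble with a forced
#' initial rung occlusion, the growth of the initiating lesion: each later
#' occluded rung within `link_um` of the lesion extends it. The run is
#' confined if the lesion never crosses the bounding arteriole/venule into a
#' different A-V sector. Spontaneous occlusions far from the lesion seed new
#' independent lesions (the model, like the periphery in vivo, develops
#' occasional new ischemic areas) and do not count against confinement of
#' the initiating one.
#'
#' @param ensemble an `ensemble_summary` on a fixed ladder network.
#' @param network the shared ladder `vascular_network` (rung segments carry
#'   a `sector` column).
#' @param forced_site the forced initial rung id.
#' @param link_um maximum segment-to-segment distance (um) at which a new
#'   occlusion is attributed to the growing lesion.
#' @return `list(fraction_confined, per_run)`.
#' @export
sector_confinement <- function(ensemble, network, forced_site,
                               link_um = 200) {
  seg <- network$segments
  nd <- network$nodes
  ends <- cbind(nd$x[match(seg$node_a, nd$id)],
                nd$y[match(seg$node_a, nd$id)],
                nd$x[match(seg$node_b, nd$id)],
                nd$y[match(seg$node_b, nd$id)])
  p2s <- function(px, py, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    tt <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) /
                         (dx * dx + dy * dy)))
    sqrt((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2)
  }
  seg_dist <- function(i, j)
    min(p2s(ends[i, 1], ends[i, 2], ends[j, 1], ends[j, 2], ends[j, 3], ends[j, 4]),
        p2s(ends[i, 3], ends[i, 4], ends[j, 1], ends[j, 2], ends[j, 3], ends[j, 4]),
        p2s(ends[j, 1], ends[j, 2], ends[i, 1], ends[i, 2], ends[i, 3], ends[i, 4]),
        p2s(ends[j, 3], ends[j, 4], ends[i, 1], ends[i, 2], ends[i, 3], ends[i, 4]))
  sec0 <- seg$sector[match(forced_site, seg$id)]
  per_run <- vapply(ensemble$runs, function(r) {
    if (is.null(r)) return(NA)
    ev <- r$events[r$events$event == "occlusion", ]
    ev <- ev[order(ev$model_week), ]
    lesion <- match(forced_site, seg$id)
    confined <- TRUE
    for (sid in ev$segment_id[ev$segment_id != forced_site]) {
      k <- match(sid, seg$id)
      if (is.na(seg$sector[k])) next          # trunks carry no sector
      linked <- any(vapply(lesion, function(l) seg_dist(l, k) <= link_um,
                           logical(1)))
      if (!linked) next                       # a new, independent lesion
      if (seg$sector[k] != sec0) confined <- FALSE
      lesion <- c(lesion, k)
    }
    confined
  }, logical(1))
  list(fraction_confined = mean(per_run, na.rm = TRUE), per_run = per_run)
}
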