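#' Solve Poiseuille flow on the network
#'
#' Interior node pressures solve mass conservation with segment conductance
#' `g = pi d^4 / (128 mu L)`; boundary nodes hold their assigned Dirichlet
#' pressures. Occluded segments keep the infinitesimal diameter `eps_d`, so
#' the linear system remains well posed while those segments carry effectively
#' zero flow. Flows are signed in the node_a -> node_b direction; velocity is
#' `Q / (pi d^2 / 4)`.
#'
#' @param network a `vascular_network` with boundary pressures assigned.
#' @param config a [sim_config()].
#' @return an object of class `flow_solution`: `node_pressures` (named by node
#'   id), `segments` (id, flow um^3/s, velocity um/s, conductance),
#'   `total_inflow` (um^3/s), `boundary_flows` (named, positive = into the
#'   network) and `kirchhoff_residual` (max interior imbalance).
#' @export
solve_flow <- function(network, config) {
  nd <- network$nodes
  seg <- network$segments
  if (!any(!is.na(nd$boundary_pressure)))
    stop("no boundary pressures assigned; call assign_boundary_conditions()",
         call. = FALSE)
  n <- nrow(nd)
  ia <- match(seg$node_a, nd$id)
  ib <- match(seg$node_b, nd$id)
  g <- pi * seg$diameter^4 / (128 * config$mu_blood * seg$length)
  ## occluded segments have effectively infinite resistance; carrying their
  ## eps_d^4 conductance through the solve only degrades conditioning
  g[seg$state == "occluded"] <- 0

  fixed <- nd$is_boundary & !is.na(nd$boundary_pressure)
  p <- numeric(n)
  p[fixed] <- nd$boundary_pressure[fixed]
  ## patent components anchored to at least one pressure boundary are solved;
  ## components cut off by occlusion take the pressure of their nearest
  ## anchored node (all their internal flows are exactly zero)
  patent_seg <- which(g > 0)
  g_pat <- igraph::graph_from_data_frame(
    data.frame(from = ia[patent_seg], to = ib[patent_seg]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  memb <- igraph::components(g_pat)$membership[as.character(seq_len(n))]
  anchored_comp <- unique(memb[fixed])
  anchored <- memb %in% anchored_comp
  free <- which(!fixed & anchored)
  if (length(free)) {
    idx <- rep(NA_integer_, n)
    idx[free] <- seq_along(free)
    tri_i <- c(ia, ib, ia, ib)
    tri_j <- c(ia, ib, ib, ia)
    tri_x <- c(g, g, -g, -g)
    keep <- !is.na(idx[tri_i]) & tri_x != 0
    A <- Matrix::sparseMatrix(i = idx[tri_i[keep]],
                              j = tri_j[keep],
                              x = tri_x[keep],
                              dims = c(length(free), n))
    Aff <- A[, free, drop = FALSE]
    b <- -as.numeric(A[, -free, drop = FALSE] %*% p[-free])
    sol <- tryCatch(Matrix::solve(Aff, b),
                    error = function(e)
                      stop("pressure system is singular: a patent component ",
                           "is isolated from every pressure boundary ",
                           "(orphan nodes: ",
                           paste(utils::head(nd$id[free], 10), collapse = ", "),
                           ")", call. = FALSE))
    p[free] <- as.numeric(sol)
  }
  orphan <- which(!anchored)
  if (length(orphan)) {
    ## hop distance over the full graph (occluded conduits included) to the
    ## anchored set; inherit the nearest anchored node's pressure
    g_all <- igraph::graph_from_data_frame(
      data.frame(from = ia, to = ib), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    d <- igraph::distances(g_all, v = as.character(orphan),
                           to = as.character(which(anchored)))
    for (k in seq_along(orphan)) {
      j <- which.min(d[k, ])
      p[orphan[k]] <- if (is.finite(d[k, j])) p[which(anchored)[j]]
                      else config$p_ven
    }
    ## equalize within each orphan component so internal flows vanish
    for (cm in unique(memb[orphan])) {
      sel <- which(memb == cm & !anchored)
      p[sel] <- mean(p[sel])
    }
  }
  q <- g * (p[ia] - p[ib])                  # signed a -> b
  vel <- q / (pi * seg$diameter^2 / 4)
  ## interior conservation residual
  div <- numeric(n)
  for (k in seq_along(q)) {
    div[ia[k]] <- div[ia[k]] - q[k]
    div[ib[k]] <- div[ib[k]] + q[k]
  }
  boundary_flows <- -div[fixed]             # positive = into network
  names(boundary_flows) <- nd$id[fixed]
  total_inflow <- sum(pmax(boundary_flows, 0))
  res <- if (length(free)) max(abs(div[free])) else 0
  structure(list(
    node_pressures = stats::setNames(p, nd$id),
    segments = data.frame(id = seg$id, flow = q, velocity = vel,
                          conductance = g),
    total_inflow = total_inflow,
    boundary_flows = boundary_flows,
    kirchhoff_residual = res), class = "flow_solution")
}

#' @method print flow_solution
#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> total inflow %.4g um^3/s, residual %.2e\n",
              x$total_inflow, x$kirchhoff_residual))
  invisible(x)
}

#' Occlude a capillary segment
#'
#' Sets the segment state to `occluded` and its diameter to the infinitesimal
#' `eps_d`, making its flow resistance effectively infinite. Occlusion is
#' irreversible; occluding an already occluded segment is a no-op with a
#' warning. The caller must re-solve the flow.
#'
#' @param network a `vascular_network`.
#' @param segment_id id(s) of segment(s) to occlude.
#' @param config a [sim_config()] (supplies `eps_d`).
#' @return the modified network.
#' @export
occlude <- function(network, segment_id, config = sim_config()) {
  k <- match(segment_id, network$segments$id)
  if (anyNA(k)) stop("unknown segment id", call. = FALSE)
  already <- network$segments$state[k] == "occluded"
  if (any(already)) {
    warning("segment(s) already occluded: ",
            paste(segment_id[already], collapse = ", "), call. = FALSE)
    k <- k[!already]
  }
  network$segments$state[k] <- "occluded"
  network$segments$diameter[k] <- config$eps_d
  network
}

#' Wall shear stress per segment
#'
#' `tau = 32 mu |Q| / (pi d^3)`, the Poiseuille wall shear used by the
#' adaptation rule.
#' @param network a `vascular_network`.
#' @param flow a `flow_solution` for the same topology.
#' @param config a [sim_config()].
#' @return numeric vector of shear stresses (mmHg), aligned with segments.
#' @export
wall_shear <- function(network, flow, config) {
  q <- flow$segments$flow[match(network$segments$id, flow$segments$id)]
  32 * config$mu_blood * abs(q) / (pi * network$segments$diameter^3)
}

#' Adapt capillary diameters to wall shear stress
#'
#' After each occlusion event, every patent non-trunk capillary adjusts its
#' diameter by the shear-log law `d <- d * (1 + k_adapt * log(tau/tau_ref))`,
#' clipped to at most 1\% per event and to `[0.8, 1.3]` times the reference
#' (construction-time) diameter. `tau_ref` is each segment's wall shear in the
#' intact network, making the pre-occlusion state a fixed point. This is the
#' hemodynamic component of adaptation only; no metabolic term is modeled.
#'
#' @param network a `vascular_network`.
#' @param flow_solution current `flow_solution`.
#' @param config a [sim_config()].
#' @param tau_ref per-segment reference shear (from [wall_shear()] at t = 0).
#' @return the network with adapted diameters.
#' @export
adapt_diameters <- function(network, flow_solution, config, tau_ref) {
  seg <- network$segments
  tau <- wall_shear(network, flow_solution, config)
  adj <- seg$state != "occluded" & !seg$is_trunk & tau > 0 & tau_ref > 0
  factor <- 1 + pmin(0.01, pmax(-0.01, config$k_adapt * log(tau / tau_ref)))
  d_new <- seg$diameter * factor
  d_new <- pmin(1.3 * seg$reference_diameter,
                pmax(0.8 * seg$reference_diameter, d_new))
  seg$diameter[adj] <- d_new[adj]
  network$segments <- seg
  network
}
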