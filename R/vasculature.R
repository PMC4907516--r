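#' Vascular network objects
#'
#' A `vascular_network` is a geometric graph: a node table (3-D positions in
#' micrometers, boundary flags and boundary pressures/oxygen tensions) and a
#' segment table (straight capillary segments with diameters, lengths and a
#' state machine normal -> leaky -> occluded, occluded being absorbing).
#' Optionally a foveal avascular zone (FAZ) polygon in the XY plane and the
#' simulation domain box.
#'
#' @param nodes data.frame with columns `id, x, y, z, is_boundary,
#'   boundary_pressure, boundary_oxygen, is_arterial_trunk, is_venous_trunk`.
#' @param segments data.frame with columns `id, node_a, node_b, diameter,
#'   state, reference_diameter, is_trunk` (`length` is recomputed from node
#'   positions if absent).
#' @param faz optional two-column matrix of polygon vertices (um, XY plane).
#' @param domain numeric length-6 box `c(xmin, xmax, ymin, ymax, zmin, zmax)`.
#' @param meta free-form provenance list (generator name, parameters, seed).
#' @return an object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, segments, faz = NULL, domain = NULL,
                             meta = list()) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  need_n <- c("id", "x", "y", "z", "is_boundary")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss))
    stop("nodes table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in c("boundary_pressure", "boundary_oxygen"))
    if (is.null(nodes[[f]])) nodes[[f]] <- NA_real_
  for (f in c("is_arterial_trunk", "is_venous_trunk"))
    if (is.null(nodes[[f]])) nodes[[f]] <- FALSE
  need_s <- c("id", "node_a", "node_b", "diameter")
  miss <- setdiff(need_s, names(segments))
  if (length(miss))
    stop("segments table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(segments$state)) segments$state <- "normal"
  if (is.null(segments$reference_diameter))
    segments$reference_diameter <- segments$diameter
  if (is.null(segments$is_trunk)) segments$is_trunk <- FALSE
  ia <- match(segments$node_a, nodes$id)
  ib <- match(segments$node_b, nodes$id)
  if (anyNA(ia) || anyNA(ib))
    stop("segment endpoint refers to unknown node id", call. = FALSE)
  segments$length <- sqrt((nodes$x[ia] - nodes$x[ib])^2 +
                          (nodes$y[ia] - nodes$y[ib])^2 +
                          (nodes$z[ia] - nodes$z[ib])^2)
  if (any(segments$length <= 0))
    stop("zero-length segment (coincident endpoints)", call. = FALSE)
  bad <- segments$state != "occluded" & segments$diameter <= 0
  if (any(bad))
    stop("patent segment with non-positive diameter: id ",
         paste(segments$id[bad], collapse = ", "), call. = FALSE)
  if (is.null(domain)) {
    pad <- 10
    domain <- c(min(nodes$x) - pad, max(nodes$x) + pad,
                min(nodes$y) - pad, max(nodes$y) + pad, 0, 50)
  }
  structure(list(nodes = nodes, segments = segments, faz = faz,
                 domain = domain, meta = meta),
            class = "vascular_network")
}

#' @method print vascular_network
#' @export
print.vascular_network <- function(x, ...) {
  n_occ <- sum(x$segments$state == "occluded")
  cat(sprintf("<vascular_network> %d nodes, %d segments (%d occluded), %s FAZ\n",
              nrow(x$nodes), nrow(x$segments), n_occ,
              if (is.null(x$faz)) "no" else "with"))
  cat(sprintf("  domain %g x %g x %g um, %d boundary nodes\n",
              diff(x$domain[1:2]), diff(x$domain[3:4]), diff(x$domain[5:6]),
              sum(x$nodes$is_boundary)))
  invisible(x)
}

## ---- graph helpers ---------------------------------------------------------

network_igraph <- function(network, patent_only = FALSE, weighted = FALSE) {
  seg <- network$segments
  if (patent_only) seg <- seg[seg$state != "occluded", , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(seg$node_a), to = as.character(seg$node_b),
               weight = if (weighted) seg$length else rep(1, nrow(seg))),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$id)))
  g
}

#' Is there a patent arteriole-to-venule path?
#'
#' @param network a `vascular_network` with designated trunk nodes.
#' @return `TRUE` if at least one path of non-occluded segments joins an
#'   arterial trunk node to a venous trunk node.
#' @export
has_av_path <- function(network) {
  a <- network$nodes$id[network$nodes$is_arterial_trunk]
  v <- network$nodes$id[network$nodes$is_venous_trunk]
  if (!length(a) || !length(v)) return(FALSE)
  g <- network_igraph(network, patent_only = TRUE)
  d <- igraph::distances(g, v = as.character(a), to = as.character(v))
  any(is.finite(d))
}

## even-odd point-in-polygon (polygon: 2-column matrix)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## delete edges one by one keeping the whole segment graph connected
delete_edges_keep_connected <- function(nodes, edges, candidates, n_delete) {
  if (n_delete == 0) return(edges)
  order_cand <- sample(candidates)
  kept <- rep(TRUE, nrow(edges))
  deleted <- 0L
  for (e in order_cand) {
    if (deleted == n_delete) break
    kept[e] <- FALSE
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$node_a[kept]),
                 to = as.character(edges$node_b[kept])),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes$id)))
    if (igraph::components(g)$no == 1L) deleted <- deleted + 1L
    else kept[e] <- TRUE
  }
  if (deleted < n_delete)
    stop(sprintf(paste0("cannot delete %d edges while keeping the ",
                        "arterial-to-venous network connected (only %d ",
                        "removable)"), n_delete, deleted), call. = FALSE)
  edges[kept, , drop = FALSE]
}

## ---- generators ------------------------------------------------------------

#' Hexagonal capillary lattice with random deletions
#'
#' Honeycomb lattice of capillaries (the idealized geometry used to probe how
#' propagation of occlusion depends on capillary spacing), with a fraction of
#' non-boundary edges removed uniformly at random subject to the network
#' remaining connected. Feeding arteriolar stubs are attached along the left
#' lattice side and draining venular stubs along the right side; the middle
#' stub of each side is designated the arterial / venous trunk.
#'
#' @param edge_length_um hexagon edge length, um (65 reproduces the critical
#'   spacing at which occlusions begin to propagate).
#' @param n_rows,n_cols number of hexagons vertically / horizontally.
#' @param deleted_edge_fraction fraction of interior lattice edges removed.
#' @param seed RNG seed (deletion pattern and diameters).
#' @param diameter_mean,diameter_sd capillary diameter distribution, um.
#' @return a `vascular_network`.
#' @export
generate_hexagonal <- function(edge_length_um = 65, n_rows = 5, n_cols = 6,
                               deleted_edge_fraction = 0, seed = 1L,
                               diameter_mean = 5, diameter_sd = 0.5) {
  if (edge_length_um <= 0) stop("edge_length_um must be positive", call. = FALSE)
  if (deleted_edge_fraction < 0 || deleted_edge_fraction >= 1)
    stop("deleted_edge_fraction must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  a <- edge_length_um
  ## flat-top hexagon centers on an offset grid
  verts <- list()
  edges <- list()
  k <- 0L
  ang <- seq(0, 300, by = 60) * pi / 180
  for (i in seq_len(n_cols)) {
    for (j in seq_len(n_rows)) {
      cx <- 1.5 * a * (i - 1)
      cy <- sqrt(3) * a * (j - 1) + (i %% 2) * sqrt(3) / 2 * a
      vx <- cx + a * cos(ang)
      vy <- cy + a * sin(ang)
      for (m in 1:6) {
        k <- k + 1L
        verts[[k]] <- c(vx[m], vy[m])
        edges[[k]] <- c(k, if (m < 6) k + 1L else k - 5L)
      }
    }
  }
  vmat <- do.call(rbind, verts)
  key <- paste(round(vmat[, 1], 3), round(vmat[, 2], 3))
  uid <- match(key, unique(key))
  umat <- vmat[!duplicated(key), , drop = FALSE]
  emat <- unique(t(apply(do.call(rbind, edges), 1,
                         function(e) sort(c(uid[e[1]], uid[e[2]])))))
  nodes <- data.frame(id = seq_len(nrow(umat)), x = umat[, 1], y = umat[, 2],
                      z = 25, is_boundary = FALSE,
                      boundary_pressure = NA_real_, boundary_oxygen = NA_real_,
                      is_arterial_trunk = FALSE, is_venous_trunk = FALSE)
  edges <- data.frame(node_a = emat[, 1], node_b = emat[, 2])

  ## boundary stubs on the two opposite (left/right) lattice sides
  attach_stubs <- function(nodes, edges, side) {
    xr <- range(nodes$x[seq_len(nrow(umat))])
    sel <- if (side == "left") which(nodes$x < xr[1] + 0.55 * a)
           else which(nodes$x > xr[2] - 0.55 * a)
    sel <- sel[order(nodes$y[sel])]
    tip_x <- if (side == "left") xr[1] - 0.4 * a else xr[2] + 0.4 * a
    trunk_idx <- sel[ceiling(length(sel) / 2)]
    for (s in sel) {
      nid <- max(nodes$id) + 1L
      nodes <- rbind(nodes, data.frame(
        id = nid, x = tip_x, y = nodes$y[s], z = 25,
        is_boundary = TRUE, boundary_pressure = NA_real_,
        boundary_oxygen = NA_real_,
        is_arterial_trunk = side == "left" && s == trunk_idx,
        is_venous_trunk = side == "right" && s == trunk_idx))
      edges <- rbind(edges, data.frame(node_a = nodes$id[s], node_b = nid))
    }
    list(nodes = nodes, edges = edges)
  }
  n_lattice_edges <- nrow(edges)
  tmp <- attach_stubs(nodes, edges, "left")
  tmp <- attach_stubs(tmp$nodes, tmp$edges, "right")
  nodes <- tmp$nodes; edges <- tmp$edges
  stub <- seq_len(nrow(edges)) > n_lattice_edges

  n_delete <- round(deleted_edge_fraction * n_lattice_edges)
  edges <- delete_edges_keep_connected(nodes, edges, which(!stub), n_delete)
  stub <- c(rep(FALSE, nrow(edges) - sum(stub)), rep(TRUE, sum(stub)))

  d <- pmax(1, stats::rnorm(nrow(edges), diameter_mean, diameter_sd))
  segments <- data.frame(id = seq_len(nrow(edges)),
                         node_a = edges$node_a, node_b = edges$node_b,
                         diameter = d, state = "normal",
                         reference_diameter = d, is_trunk = stub)
  vascular_network(nodes, segments,
                   meta = list(generator = "hexagonal",
                               edge_length_um = edge_length_um,
                               n_rows = n_rows, n_cols = n_cols,
                               deleted_edge_fraction = deleted_edge_fraction,
                               seed = seed))
}

#' Peripheral arteriole-venule ladder network
#'
#' Parallel arteriolar and venular rails joined apically by shunt vessels
#' (18 um lumen) and transversally by rung capillaries (10 um), the simple
#' far-peripheral retinal architecture. Rails alternate A, V, A, ... so that
#' `n_sectors` A-V sectors lie between `n_sectors + 1` rails; rail bases are
#' the pressure boundary nodes.
#'
#' @param n_sectors number of A-V sectors (>= 1).
#' @param rung_count rung capillaries per sector (>= 2).
#' @param rung_spacing_um vertical spacing between rungs, um.
#' @param seed RNG seed (small diameter jitter of the rungs).
#' @param sector_width_um rail-to-rail distance, um.
#' @return a `vascular_network`; rung segments carry a `sector` column.
#' @export
generate_peripheral_ladder <- function(n_sectors = 3, rung_count = 5,
                                       rung_spacing_um = 160, seed = 1L,
                                       sector_width_um = 320) {
  if (n_sectors < 1 || rung_count < 2)
    stop("need n_sectors >= 1 and rung_count >= 2", call. = FALSE)
  if (rung_spacing_um <= 0 || sector_width_um <= 0)
    stop("rung spacing and sector width must be positive", call. = FALSE)
  set.seed(seed)
  n_rails <- n_sectors + 1L
  x0 <- 30; y0 <- 30
  rail_x <- x0 + (seq_len(n_rails) - 1L) * sector_width_um
  ## thin margins below the first rung and above the apical shunt
  rung_y <- y0 + 40 + rung_spacing_um * (seq_len(rung_count) - 1L)
  apex_y <- max(rung_y) + 40
  arterial <- (seq_len(n_rails) %% 2L) == 1L   # A, V, A, V, ...

  nodes <- NULL; segs <- NULL; nid <- 0L; sid <- 0L
  rail_node <- matrix(NA_integer_, nrow = n_rails, ncol = rung_count + 2L)
  add_node <- function(x, y, boundary = FALSE, art = FALSE, ven = FALSE) {
    nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(
      id = nid, x = x, y = y, z = 25, is_boundary = boundary,
      boundary_pressure = NA_real_, boundary_oxygen = NA_real_,
      is_arterial_trunk = art, is_venous_trunk = ven))
    nid
  }
  add_seg <- function(a, b, d, trunk, sector = NA_integer_) {
    sid <<- sid + 1L
    segs <<- rbind(segs, data.frame(
      id = sid, node_a = a, node_b = b, diameter = d, state = "normal",
      reference_diameter = d, is_trunk = trunk, sector = sector))
    sid
  }
  for (r in seq_len(n_rails)) {
    rail_node[r, 1] <- add_node(rail_x[r], y0, boundary = TRUE,
                                art = arterial[r], ven = !arterial[r])
    for (i in seq_len(rung_count))
      rail_node[r, i + 1L] <- add_node(rail_x[r], rung_y[i])
    rail_node[r, rung_count + 2L] <- add_node(rail_x[r], apex_y)
    for (i in seq_len(rung_count + 1L))
      add_seg(rail_node[r, i], rail_node[r, i + 1L], 15, trunk = TRUE)
  }
  for (r in seq_len(n_sectors))       # apical shunts, 18 um lumen
    add_seg(rail_node[r, rung_count + 2L], rail_node[r + 1L, rung_count + 2L],
            18, trunk = TRUE)
  for (r in seq_len(n_sectors))       # rung capillaries, ~10 um lumen
    for (i in seq_len(rung_count))
      add_seg(rail_node[r, i + 1L], rail_node[r + 1L, i + 1L],
              pmax(1, stats::rnorm(1, 10, 0.5)), trunk = FALSE, sector = r)
  vascular_network(nodes, segs,
                   meta = list(generator = "peripheral_ladder",
                               n_sectors = n_sectors, rung_count = rung_count,
                               rung_spacing_um = rung_spacing_um, seed = seed))
}

#' Synthetic macular arteriole-venule sector
#'
#' A synthetic stand-in for an imaged juxtafoveal capillary sector: a
#' 510 x 600 um footprint with an arteriolar trunk entering at the lower
#' right and a venular trunk exiting at the upper right (diameters tapering
#' from 10 um), an interconnecting capillary mesh with diameters drawn from a
#' truncated Gaussian (mean 5 um, SD 0.5 um), a foveal avascular zone along
#' the left edge left free of vessels, and capillary density decreasing toward
#' the FAZ border. Side branches reaching the domain edge terminate in
#' boundary nodes. This network is synthetic: it emulates the topology and
#' statistics of an AOSLO-derived sector, not any individual retina.
#'
#' @param seed RNG seed; the same seed yields the identical network.
#' @return a `vascular_network` with an FAZ polygon.
#' @export
generate_macular_sector <- function(seed = 1L) {
  if (length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  set.seed(as.integer(seed))
  W <- 510; H <- 600
  ## FAZ: half-ellipse hugging the left edge
  th <- seq(-pi / 2, pi / 2, length.out = 41)
  faz <- cbind(x = pmax(0, 95 * cos(th)), y = 300 + 185 * sin(th))
  faz <- rbind(faz, c(0, 485), c(0, 115))

  nid <- 0L; nodes <- NULL
  add_node <- function(x, y, boundary = FALSE, art = FALSE, ven = FALSE) {
    nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(
      id = nid, x = x, y = y, z = 25, is_boundary = boundary,
      boundary_pressure = NA_real_, boundary_oxygen = NA_real_,
      is_arterial_trunk = art, is_venous_trunk = ven))
    nid
  }
  ## trunks along bottom (arteriole) and top (venule), tapering 10 -> 7 um
  trunk_pts <- function(y_edge, bend) {
    xs <- seq(W, 70, by = -44)
    ys <- y_edge + bend * ((W - xs) / (W - 70))^1.5
    cbind(xs, ys)
  }
  a_pts <- trunk_pts(55, -18)   # dips toward bottom edge
  v_pts <- trunk_pts(545, 18)
  a_ids <- integer(nrow(a_pts)); v_ids <- integer(nrow(v_pts))
  for (i in seq_len(nrow(a_pts)))
    a_ids[i] <- add_node(a_pts[i, 1], a_pts[i, 2], boundary = i == 1L,
                         art = i == 1L)
  for (i in seq_len(nrow(v_pts)))
    v_ids[i] <- add_node(v_pts[i, 1], v_pts[i, 2], boundary = i == 1L,
                         ven = i == 1L)

  ## capillary mesh: jittered triangular lattice, sparser near the FAZ
  ## capillary mesh: jittered triangular lattice; sparse juxtafoveal
  ## annulus (the vulnerable zone) grading into a denser far field
  pitch <- 75
  mesh_ids <- integer(0)
  row <- 0L
  for (y in seq(105, 505, by = pitch * 0.87)) {
    row <- row + 1L
    xs <- seq(55 + (row %% 2) * pitch / 2, 475, by = pitch)
    for (x in xs) {
      jx <- x + stats::runif(1, -8, 8); jy <- y + stats::runif(1, -8, 8)
      dmin <- min(sqrt((jx - faz[, 1])^2 + (jy - faz[, 2])^2))
      if (point_in_polygon(jx, jy, faz) || dmin < 25) next
      keep_p <- if (dmin < 150) 0.45 + 0.55 * (dmin / 150)^1.3 else 1
      if (stats::runif(1) > keep_p) next
      mesh_ids <- c(mesh_ids, add_node(jx, jy))
    }
  }

  ## edges: mesh neighbors within radius, trunk chains, trunk side branches
  edges <- NULL
  add_edge <- function(a, b, d, trunk = FALSE) {
    edges <<- rbind(edges, data.frame(node_a = a, node_b = b, diameter = d,
                                      is_trunk = trunk))
  }
  taper <- function(i, n) 10 - 3 * (i - 1) / (n - 1)
  for (i in seq_len(length(a_ids) - 1L))
    add_edge(a_ids[i], a_ids[i + 1L], taper(i, length(a_ids)), trunk = TRUE)
  for (i in seq_len(length(v_ids) - 1L))
    add_edge(v_ids[i], v_ids[i + 1L], taper(i, length(v_ids)), trunk = TRUE)

  mx <- nodes$x[mesh_ids]; my <- nodes$y[mesh_ids]
  nm <- length(mesh_ids)
  for (i in seq_len(nm - 1L)) {
    dx <- mx[(i + 1L):nm] - mx[i]; dy <- my[(i + 1L):nm] - my[i]
    nb <- which(dx * dx + dy * dy < (1.55 * pitch)^2)
    for (j in nb)
      add_edge(mesh_ids[i], mesh_ids[i + j],
               max(3.2, stats::rnorm(1, 5, 0.5)))
  }
  ## side branches from trunks up/down into the mesh
  link_trunk <- function(t_ids, mesh_sel) {
    for (t in t_ids[seq(2, length(t_ids), by = 2)]) {
      d2 <- (nodes$x[mesh_sel] - nodes$x[t])^2 +
            (nodes$y[mesh_sel] - nodes$y[t])^2
      near <- mesh_sel[order(d2)[1]]
      if (min(d2) < (2.2 * pitch)^2)
        add_edge(t, near, max(3.5, stats::rnorm(1, 6, 0.5)))
    }
  }
  link_trunk(a_ids, mesh_ids[my < 220])
  link_trunk(v_ids, mesh_ids[my > 390])

  ## side branches crossing the domain boundary become boundary nodes
  for (sb in list(c(60, 1), c(60, -1), c(250, 1), c(250, -1),
                  c(420, 1), c(420, -1), c(540, -1), c(540, 1))) {
    yb <- sb[1]; dir <- sb[2]
    cand <- mesh_ids[abs(my - yb) < 60]
    if (!length(cand)) next
    edge_x <- if (dir > 0) W else 0
    if (dir < 0 && yb > 110 && yb < 490) next  # left edge is the FAZ side
    d2 <- (nodes$x[cand] - edge_x)^2
    src <- cand[order(d2)[1]]
    if (sqrt(min(d2)) > 2.2 * pitch) next
    yb2 <- nodes$y[src] + stats::runif(1, -10, 10)
    ## the left edge is the FAZ side: keep its stubs clear of the FAZ span
    if (edge_x == 0 && yb2 > 108 && yb2 < 492)
      yb2 <- if (yb2 > 300) 492 else 108
    b <- add_node(edge_x, yb2, boundary = TRUE)
    add_edge(src, b, max(3.2, stats::rnorm(1, 5, 0.5)))
  }

  ## irregularity: random removable mesh edges, keeping the graph connected
  cand <- which(!edges$is_trunk)
  edges_all <- edges
  keep <- tryCatch(
    delete_edges_keep_connected(nodes, edges_all, cand,
                                round(0.10 * length(cand))),
    error = function(e) edges_all)
  edges <- keep

  segs <- data.frame(id = seq_len(nrow(edges)), node_a = edges$node_a,
                     node_b = edges$node_b, diameter = edges$diameter,
                     state = "normal", reference_diameter = edges$diameter,
                     is_trunk = edges$is_trunk)
  net <- vascular_network(nodes, segs, faz = faz,
                          domain = c(0, W, 0, H, 0, 50),
                          meta = list(generator = "macular_sector",
                                      seed = seed))
  ## drop any stray component not attached to the arterial trunk
  g <- network_igraph(net)
  comp <- igraph::components(g)
  main <- comp$membership[as.character(net$nodes$id[net$nodes$is_arterial_trunk])]
  keep_nodes <- net$nodes$id[comp$membership[as.character(net$nodes$id)] == main]
  if (length(keep_nodes) < nrow(net$nodes)) {
    net$nodes <- net$nodes[net$nodes$id %in% keep_nodes, , drop = FALSE]
    net$segments <- net$segments[net$segments$node_a %in% keep_nodes &
                                 net$segments$node_b %in% keep_nodes, ,
                                 drop = FALSE]
    net$segments$id <- seq_len(nrow(net$segments))
  }
  net
}

## ---- boundary conditions ---------------------------------------------------

#' Assign boundary pressures and inlet oxygen tensions
#'
#' The arterial trunk node receives `p_art` and the venous trunk `p_ven`;
#' every other boundary node is assigned a pressure interpolated linearly in
#' normalized graph distance (centerline length metric) between the two
#' trunks. Boundary nodes other than the arterial trunk receive an inlet
#' oxygen tension of `po2_inlet_scale * po2_art` (used only where flow enters
#' the network); the arterial trunk receives `po2_art`. If the network has an
#' FAZ it acts later as a Dirichlet oxygen source at `po2_faz`.
#'
#' @param network a `vascular_network` with designated trunk nodes.
#' @param config a [sim_config()].
#' @return the network with `boundary_pressure` / `boundary_oxygen` filled in.
#' @export
assign_boundary_conditions <- function(network, config) {
  nd <- network$nodes
  a <- which(nd$is_arterial_trunk); v <- which(nd$is_venous_trunk)
  if (!length(a) || !length(v))
    stop("network has no designated arterial and venous trunk nodes",
         call. = FALSE)
  g <- network_igraph(network, weighted = TRUE)
  dA <- apply(igraph::distances(g, v = as.character(nd$id[a]),
                                weights = igraph::E(g)$weight), 2, min)
  dV <- apply(igraph::distances(g, v = as.character(nd$id[v]),
                                weights = igraph::E(g)$weight), 2, min)
  bnd <- which(nd$is_boundary)
  for (b in bnd) {
    key <- as.character(nd$id[b])
    da <- dA[key]; dv <- dV[key]
    frac <- if (!is.finite(da) || !is.finite(dv) || da + dv == 0) 0.5
            else da / (da + dv)
    nd$boundary_pressure[b] <- config$p_art + (config$p_ven - config$p_art) * frac
    nd$boundary_oxygen[b] <- config$po2_inlet_scale * config$po2_art
  }
  nd$boundary_pressure[a] <- config$p_art
  nd$boundary_oxygen[a] <- config$po2_art
  nd$boundary_pressure[v] <- config$p_ven
  network$nodes <- nd
  network
}
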