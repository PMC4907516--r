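#' Build the generalized-cell tissue model
#'
#' Tiles the domain footprint with Mueller cells (MC) and other retinal cells
#' (OT) on a grid of pitch `a_mc`, interleaved to the configured MC fraction
#' (checkerboard at 0.5), lays capillary blocks (CAP) of fixed length along
#' every segment centerline, tags the FAZ footprint as a source/sink region
#' (not cellularized as tissue), and computes the contact-area adjacency used
#' by inter-cellular diffusion: shared tile edges times local thickness for
#' tile pairs, lateral cylinder surface for a CAP and its enclosing tile, and
#' the lumen cross-section between consecutive CAP blocks of one segment.
#'
#' The representation is 2.5-D: tiles live in the XY plane of the vascular
#' lamina and carry a thickness attribute (initially `base_thickness`); the Z
#' extent enters only the contact areas and the thickness/edema map.
#'
#' @param network a `vascular_network` lying inside its domain box.
#' @param config a [sim_config()].
#' @return an object of class `tissue_model`: `cells` (id, kind in
#'   CAP/MC/OT/FAZ, centroid, area, thickness, volume, segment_id, block
#'   index, column = index of the supporting tissue column), `contact`
#'   (cell id pairs `i < j` with `area` in um^2) and the grid geometry.
#' @export
build_tissue <- function(network, config) {
  dom <- network$domain
  nd <- network$nodes
  if (any(nd$x < dom[1] - 1e-6 | nd$x > dom[2] + 1e-6 |
          nd$y < dom[3] - 1e-6 | nd$y > dom[4] + 1e-6))
    stop("vessel nodes lie outside the domain box", call. = FALSE)
  W <- dom[2] - dom[1]; H <- dom[4] - dom[3]
  nx <- max(1L, round(W / config$a_mc)); ny <- max(1L, round(H / config$a_mc))
  px <- W / nx; py <- H / ny
  h0 <- config$base_thickness

  ti <- rep(seq_len(nx), times = ny)
  tj <- rep(seq_len(ny), each = nx)
  tx <- dom[1] + (ti - 0.5) * px
  ty <- dom[3] + (tj - 0.5) * py
  n_tiles <- nx * ny

  kind <- rep("OT", n_tiles)
  if (!is.null(network$faz))
    kind[point_in_polygon(tx, ty, network$faz)] <- "FAZ"
  tissue_idx <- which(kind != "FAZ")
  ## uniform interleaving: checkerboard ranking, exact at fraction 0.5
  rank_key <- ((ti + tj) %% 2L) + (ti * 131L + tj * 17L %% 97L) / 1e6
  ord <- tissue_idx[order(rank_key[tissue_idx])]
  n_mc <- round(config$mc_fraction * length(tissue_idx))
  kind[ord[seq_len(n_mc)]] <- "MC"

  cells <- data.frame(id = seq_len(n_tiles), kind = kind, x = tx, y = ty,
                      area = px * py, thickness = h0, volume = px * py * h0,
                      segment_id = NA_integer_, block = NA_integer_,
                      block_length = NA_real_, column = seq_len(n_tiles))

  tile_of <- function(x, y) {
    i <- pmin(nx, pmax(1L, ceiling((x - dom[1]) / px)))
    j <- pmin(ny, pmax(1L, ceiling((y - dom[3]) / py)))
    (j - 1L) * nx + i
  }

  ## CAP blocks along segments
  seg <- network$segments
  ia <- match(seg$node_a, nd$id); ib <- match(seg$node_b, nd$id)
  cap_rows <- vector("list", nrow(seg))
  next_id <- n_tiles
  for (k in seq_len(nrow(seg))) {
    L <- seg$length[k]
    nb <- max(1L, round(L / config$cap_block_len))
    bl <- L / nb
    t_mid <- (seq_len(nb) - 0.5) / nb
    cx <- nd$x[ia[k]] + t_mid * (nd$x[ib[k]] - nd$x[ia[k]])
    cy <- nd$y[ia[k]] + t_mid * (nd$y[ib[k]] - nd$y[ia[k]])
    d0 <- seg$reference_diameter[k]
    cap_rows[[k]] <- data.frame(
      id = next_id + seq_len(nb), kind = "CAP", x = cx, y = cy,
      area = d0 * bl, thickness = h0,
      volume = pi * d0^2 / 4 * bl,
      segment_id = seg$id[k], block = seq_len(nb), block_length = bl,
      column = tile_of(cx, cy))
    next_id <- next_id + nb
  }
  caps <- do.call(rbind, cap_rows)
  ## a CAP whose center falls on an FAZ tile leans on the nearest tissue tile
  faz_cols <- which(kind == "FAZ")
  bad <- which(caps$column %in% faz_cols)
  if (length(bad)) {
    ok <- which(kind != "FAZ")
    for (b in bad) {
      d2 <- (tx[ok] - caps$x[b])^2 + (ty[ok] - caps$y[b])^2
      caps$column[b] <- ok[which.min(d2)]
    }
  }
  cells <- rbind(cells, caps)

  ## contact graph
  con <- list()
  right <- which(ti < nx)
  con$tile_h <- data.frame(i = right, j = right + 1L, area = py * h0,
                           wall = FALSE)
  up <- which(tj < ny)
  con$tile_v <- data.frame(i = up, j = up + nx, area = px * h0, wall = FALSE)
  cap_tile <- data.frame(i = caps$column, j = caps$id,
                         area = pi * seg$reference_diameter[
                           match(caps$segment_id, seg$id)] * caps$block_length,
                         wall = TRUE)
  con$cap_tile <- cap_tile
  same <- which(diff(caps$segment_id) == 0 & diff(caps$block) == 1L)
  if (length(same)) {
    d0 <- seg$reference_diameter[match(caps$segment_id[same], seg$id)]
    con$cap_cap <- data.frame(i = caps$id[same], j = caps$id[same + 1L],
                              area = pi * d0^2 / 4, wall = TRUE)
  }
  contact <- do.call(rbind, con)
  rownames(contact) <- NULL
  sw <- contact$i > contact$j
  tmp <- contact$i[sw]; contact$i[sw] <- contact$j[sw]; contact$j[sw] <- tmp

  structure(list(cells = cells, contact = contact,
                 grid = list(nx = nx, ny = ny, px = px, py = py,
                             origin = dom[c(1, 3)]),
                 base_thickness = h0),
            class = "tissue_model")
}

#' @method print tissue_model
#' @export
print.tissue_model <- function(x, ...) {
  tab <- table(x$cells$kind)
  cat("<tissue_model> ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "; ", nrow(x$contact), " contacts\n", sep = "")
  invisible(x)
}

#' Minimal Mueller-cell-to-patent-vessel distance
#'
#' Euclidean XY distance from each Mueller cell centroid to the nearest
#' patent (non-occluded) segment centerline. With no patent segment left the
#' distances are `Inf`.
#'
#' @param tissue a `tissue_model`.
#' @param network the `vascular_network` (current states).
#' @return named numeric vector (um), one entry per MC cell.
#' @export
min_cell_vessel_distance <- function(tissue, network) {
  mc <- tissue$cells[tissue$cells$kind == "MC", , drop = FALSE]
  seg <- network$segments[network$segments$state != "occluded", , drop = FALSE]
  out <- rep(Inf, nrow(mc))
  if (nrow(seg)) {
    nd <- network$nodes
    ia <- match(seg$node_a, nd$id); ib <- match(seg$node_b, nd$id)
    for (k in seq_len(nrow(seg))) {
      x1 <- nd$x[ia[k]]; y1 <- nd$y[ia[k]]
      dx <- nd$x[ib[k]] - x1; dy <- nd$y[ib[k]] - y1
      len2 <- dx * dx + dy * dy
      t <- pmin(1, pmax(0, ((mc$x - x1) * dx + (mc$y - y1) * dy) / len2))
      d <- sqrt((mc$x - (x1 + t * dx))^2 + (mc$y - (y1 + t * dy))^2)
      out <- pmin(out, d)
    }
  }
  stats::setNames(out, mc$id)
}
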