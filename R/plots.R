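#' Plot a vascular network
#'
#' Draws segments colored by state (patent black/blue, leaky orange,
#' occluded light gray) and optionally scaled by flow velocity.
#'
#' @param network a `vascular_network`.
#' @param flow optional `flow_solution`; line width then tracks velocity.
#' @param ... passed to [graphics::plot()].
#' @export
plot_network <- function(network, flow = NULL, ...) {
  nd <- network$nodes
  seg <- network$segments
  graphics::plot(NA, xlim = network$domain[1:2], ylim = network$domain[3:4],
                 asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  if (!is.null(network$faz))
    graphics::polygon(network$faz[, 1], network$faz[, 2],
                      col = "#f2e9dc", border = NA)
  ia <- match(seg$node_a, nd$id); ib <- match(seg$node_b, nd$id)
  col <- c(normal = "#1f3552", leaky = "#e08214", occluded = "#cccccc")[seg$state]
  lwd <- rep(1.2, nrow(seg))
  if (!is.null(flow)) {
    v <- abs(flow$segments$velocity[match(seg$id, flow$segments$id)])
    lwd <- 0.6 + 2.4 * v / max(v, 1e-12)
  }
  graphics::segments(nd$x[ia], nd$y[ia], nd$x[ib], nd$y[ib],
                     col = col, lwd = lwd)
  b <- nd$is_boundary
  graphics::points(nd$x[b], nd$y[b], pch = 21,
                   bg = ifelse(nd$is_arterial_trunk[b], "red",
                               ifelse(nd$is_venous_trunk[b], "blue", "white")))
  invisible(network)
}

#' Plot a per-cell scalar field
#'
#' Heat-map style rendering of a field (oxygen tension, VEGF, thickness) on
#' the tissue tiling; capillary blocks are drawn as points on top.
#'
#' @param tissue a `tissue_model`.
#' @param values per-cell numeric vector (tiles and CAP blocks).
#' @param palette a color ramp function, e.g. from [grDevices::colorRampPalette()].
#' @param main plot title.
#' @param zlim optional value range for the color scale.
#' @export
plot_cell_field <- function(tissue, values,
                            palette = grDevices::colorRampPalette(
                              c("#08306b", "#2171b5", "#f7fbff",
                                "#fb6a4a", "#a50f15")),
                            main = "", zlim = NULL) {
  cells <- tissue$cells
  tiles <- cells[is.na(cells$segment_id) & cells$kind != "FAZ", , drop = FALSE]
  caps <- cells[!is.na(cells$segment_id), , drop = FALSE]
  if (is.null(zlim)) zlim <- range(values, finite = TRUE)
  ramp <- palette(64)
  idx <- function(v) pmin(64L, pmax(1L, 1L + floor(63 *
    (v - zlim[1]) / max(zlim[2] - zlim[1], 1e-12))))
  px <- tissue$grid$px; py <- tissue$grid$py
  graphics::plot(NA, xlim = range(cells$x) + c(-px, px),
                 ylim = range(cells$y) + c(-py, py), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", main = main)
  graphics::rect(tiles$x - px / 2, tiles$y - py / 2,
                 tiles$x + px / 2, tiles$y + py / 2,
                 col = ramp[idx(values[match(tiles$id, cells$id)])],
                 border = NA)
  graphics::points(caps$x, caps$y, pch = 15, cex = 0.4,
                   col = ramp[idx(values[match(caps$id, cells$id)])])
  invisible(tissue)
}

#' Export per-cell fields as CSV
#'
#' @param tissue a `tissue_model`.
#' @param fields named list of per-cell vectors (e.g. oxygen, vegf).
#' @param path output CSV path.
#' @export
export_cell_fields <- function(tissue, fields, path) {
  df <- tissue$cells[, c("id", "kind", "x", "y", "area", "thickness")]
  for (nm in names(fields)) df[[nm]] <- fields[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a flow solution
#'
#' Writes the per-segment table (segment id, flow, velocity) as CSV and, if
#' `json` is given, a JSON summary with the total inflow.
#'
#' @param flow a `flow_solution`.
#' @param path CSV output path.
#' @param json optional JSON summary path.
#' @export
export_flow <- function(flow, path, json = NULL) {
  utils::write.csv(flow$segments[, c("id", "flow", "velocity")], path,
                   row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(total_inflow = flow$total_inflow,
                              kirchhoff_residual = flow$kirchhoff_residual),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a per-cell field to PNG
#'
#' Renders [plot_cell_field()] into a PNG raster (e.g. oxygen or VEGF maps,
#' or the thickness map from [thickness_map()]).
#'
#' @inheritParams plot_cell_field
#' @param path PNG output path.
#' @param width,height raster size in pixels.
#' @export
export_heatmap <- function(tissue, values, path, width = 800, height = 900,
                           main = "", zlim = NULL) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot_cell_field(tissue, values, main = main, zlim = zlim)
  invisible(path)
}
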