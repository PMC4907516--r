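#' Read and write vascular networks
#'
#' The primary on-disk format is JSON (schema `occlusim-network/1`): node and
#' segment tables, the FAZ polygon, the domain box and free-form metadata.
#' Unknown top-level fields survive a round trip under the reserved key
#' `extra`. A CSV node/edge table pair is accepted for interoperability: pass
#' a path ending in `.json` for JSON, otherwise the path is taken as a prefix
#' and `<prefix>_nodes.csv` / `<prefix>_edges.csv` are used (edge columns
#' `id,node_a,node_b,diameter_um,state`).
#'
#' @param network a `vascular_network`.
#' @param path file path (see above).
#' @return `read_network` returns a `vascular_network`; `write_network`
#'   returns `path` invisibly. `write_network(read_network(p))` is the
#'   identity on all fields.
#' @export
write_network <- function(network, path) {
  if (grepl("\\.json$", path)) {
    obj <- list(schema = "occlusim-network/1",
                nodes = network$nodes,
                segments = network$segments,
                faz = if (is.null(network$faz)) NULL else
                  as.data.frame(network$faz),
                domain = network$domain,
                meta = network$meta)
    if (!is.null(network$extra)) obj$extra <- network$extra
    jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, null = "null")
  } else {
    utils::write.csv(network$nodes, paste0(path, "_nodes.csv"),
                     row.names = FALSE)
    seg <- network$segments
    edges <- data.frame(id = seg$id, node_a = seg$node_a, node_b = seg$node_b,
                        diameter_um = seg$diameter, state = seg$state)
    utils::write.csv(edges, paste0(path, "_edges.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$schema) || !startsWith(obj$schema, "occlusim-network"))
      stop("not an occlusim network file (missing field: schema)", call. = FALSE)
    for (f in c("nodes", "segments"))
      if (is.null(obj[[f]]))
        stop("network file is missing field: ", f, call. = FALSE)
    nodes <- as.data.frame(obj$nodes)
    segments <- as.data.frame(obj$segments)
    check_cols(nodes, c("id", "x", "y", "z", "is_boundary"), "nodes")
    check_cols(segments, c("id", "node_a", "node_b", "diameter"), "segments")
    faz <- if (is.null(obj$faz)) NULL else as.matrix(as.data.frame(obj$faz))
    known <- c("schema", "nodes", "segments", "faz", "domain", "meta", "extra")
    extra <- obj[setdiff(names(obj), known)]
    if (!is.null(obj$extra)) extra <- c(obj$extra, extra)
    net <- vascular_network(nodes, segments, faz = faz,
                            domain = unlist(obj$domain), meta = obj$meta)
    if (length(extra)) net$extra <- extra
    net
  } else {
    nf <- paste0(path, "_nodes.csv"); ef <- paste0(path, "_edges.csv")
    for (f in c(nf, ef))
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    nodes <- utils::read.csv(nf)
    edges <- utils::read.csv(ef)
    check_cols(nodes, c("id", "x", "y", "z", "is_boundary"), "nodes")
    check_cols(edges, c("id", "node_a", "node_b", "diameter_um", "state"),
               "edges")
    segments <- data.frame(id = edges$id, node_a = edges$node_a,
                           node_b = edges$node_b, diameter = edges$diameter_um,
                           state = edges$state)
    vascular_network(nodes, segments)
  }
}

check_cols <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
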