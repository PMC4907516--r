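## Small networks built in code for unit tests.

## straight A -> V pipe with n_mid interior nodes
pipe_network <- function(n_mid = 1, length_um = 100, diameter = 5,
                         y = 50, height = 100) {
  n <- n_mid + 2L
  xs <- seq(0, length_um * (n - 1L), by = length_um)
  nodes <- data.frame(
    id = seq_len(n), x = xs, y = y, z = 25,
    is_boundary = c(TRUE, rep(FALSE, n_mid), TRUE),
    boundary_pressure = NA_real_, boundary_oxygen = NA_real_,
    is_arterial_trunk = c(TRUE, rep(FALSE, n - 1L)),
    is_venous_trunk = c(rep(FALSE, n - 1L), TRUE))
  segs <- data.frame(id = seq_len(n - 1L), node_a = seq_len(n - 1L),
                     node_b = 2:n, diameter = diameter)
  vascular_network(nodes, segs,
                   domain = c(0, max(xs), 0, height, 0, 50))
}

## symmetric Y: inlet trunk splitting into two identical daughters
y_network <- function(diameter = 5) {
  nodes <- data.frame(
    id = 1:4,
    x = c(0, 100, 200, 200), y = c(100, 100, 160, 40), z = 25,
    is_boundary = c(TRUE, FALSE, TRUE, TRUE),
    boundary_pressure = NA_real_, boundary_oxygen = NA_real_,
    is_arterial_trunk = c(TRUE, FALSE, FALSE, FALSE),
    is_venous_trunk = c(FALSE, FALSE, TRUE, FALSE))
  nodes$is_venous_trunk[4] <- TRUE
  segs <- data.frame(id = 1:3, node_a = c(1, 2, 2), node_b = c(2, 3, 4),
                     diameter = diameter)
  vascular_network(nodes, segs, domain = c(0, 200, 0, 200, 0, 50))
}

small_hex <- function(seed = 1, ...) {
  generate_hexagonal(n_rows = 2, n_cols = 3, seed = seed, ...)
}

## fast config for small steady-state tests
fast_config <- function(...) sim_config(...)
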