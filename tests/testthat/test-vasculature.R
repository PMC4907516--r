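test_that("hexagonal lattice has the honeycomb degree structure", {
  net <- generate_hexagonal(edge_length_um = 65, n_rows = 3, n_cols = 4,
                            deleted_edge_fraction = 0, seed = 1)
  deg <- table(c(net$segments$node_a, net$segments$node_b))
  nd <- net$nodes
  ## interior lattice nodes (away from the perimeter and the stubs)
  xr <- range(nd$x[!nd$is_boundary]); yr <- range(nd$y[!nd$is_boundary])
  interior <- nd$id[!nd$is_boundary &
                    nd$x > xr[1] + 70 & nd$x < xr[2] - 70 &
                    nd$y > yr[1] + 70 & nd$y < yr[2] - 70]
  expect_true(length(interior) > 5)
  expect_true(all(deg[as.character(interior)] == 3))
  ## edge length respected
  lat <- net$segments[!net$segments$is_trunk, ]
  expect_true(all(abs(lat$length - 65) < 1e-6))
  ## boundary nodes have degree 1
  expect_true(all(deg[as.character(nd$id[nd$is_boundary])] == 1))
})

test_that("hexagonal edge deletion is seeded, counted and keeps connectivity", {
  n0 <- generate_hexagonal(n_rows = 3, n_cols = 4, seed = 7)
  n1 <- generate_hexagonal(n_rows = 3, n_cols = 4,
                           deleted_edge_fraction = 0.2, seed = 7)
  n2 <- generate_hexagonal(n_rows = 3, n_cols = 4,
                           deleted_edge_fraction = 0.2, seed = 7)
  expect_identical(n1$segments$node_a, n2$segments$node_a)
  expect_identical(n1$segments$node_b, n2$segments$node_b)
  n_lat0 <- sum(!n0$segments$is_trunk)
  n_lat1 <- sum(!n1$segments$is_trunk)
  expect_equal(n_lat0 - n_lat1, round(0.2 * n_lat0))
  expect_true(has_av_path(n1))
  ## an impossible deletion request fails naming the constraint
  expect_error(generate_hexagonal(n_rows = 2, n_cols = 2,
                                  deleted_edge_fraction = 0.9, seed = 1),
               "connected")
})

test_that("peripheral ladder wires rungs between an A and a V rail", {
  net <- generate_peripheral_ladder(n_sectors = 3, rung_count = 5, seed = 1)
  seg <- net$segments
  rungs <- seg[!seg$is_trunk, ]
  expect_equal(nrow(rungs), 15)
  expect_equal(sort(unique(rungs$sector)), 1:3)
  ## shunts are the 18-um trunks, rungs about 10 um
  expect_true(any(abs(seg$diameter[seg$is_trunk] - 18) < 1e-9))
  expect_true(all(abs(rungs$diameter - 10) < 3))
  ## every rung joins the arteriolar rail to the venular rail of its sector
  nd <- net$nodes
  rail_x <- sort(unique(nd$x[!nd$is_boundary]))
  for (k in seq_len(nrow(rungs))) {
    xa <- nd$x[match(rungs$node_a[k], nd$id)]
    xb <- nd$x[match(rungs$node_b[k], nd$id)]
    expect_equal(abs(match(xa, rail_x) - match(xb, rail_x)), 1)
  }
  ## bases are pressure boundaries, one per rail
  expect_equal(sum(nd$is_boundary), 4)
  expect_error(generate_peripheral_ladder(rung_spacing_um = -5), "positive")
})

test_that("macular sector emulates the juxtafoveal geometry", {
  net <- generate_macular_sector(seed = 3)
  expect_equal(net$domain[1:4], c(0, 510, 0, 600))
  caps <- net$segments[!net$segments$is_trunk, ]
  ## capillary diameters drawn around 5 um
  expect_lt(abs(mean(caps$diameter) - 5), 0.5)
  expect_true(all(net$segments$diameter <= 10 + 1e-9))
  ## FAZ region is avascular
  nd <- net$nodes
  expect_false(any(point_in_polygon(nd$x, nd$y, net$faz)))
  expect_true(has_av_path(net))
  ## same seed, identical network; different seed, different mesh
  n2 <- generate_macular_sector(seed = 3)
  expect_identical(net$nodes, n2$nodes)
  expect_identical(net$segments, n2$segments)
  n3 <- generate_macular_sector(seed = 4)
  expect_false(nrow(n3$nodes) == nrow(net$nodes) &&
                 all(n3$nodes$x == net$nodes$x))
})

test_that("boundary conditions interpolate pressures by graph distance", {
  cfg <- sim_config()
  net <- pipe_network(n_mid = 3)
  ## add a side boundary stub at the middle node, equidistant from A and V
  nd <- net$nodes
  mid <- nd$id[ceiling(nrow(nd) / 2)]
  nd <- rbind(nd, data.frame(id = 99, x = nd$x[mid], y = nd$y[mid] + 40,
                             z = 25, is_boundary = TRUE,
                             boundary_pressure = NA_real_,
                             boundary_oxygen = NA_real_,
                             is_arterial_trunk = FALSE,
                             is_venous_trunk = FALSE))
  seg <- rbind(net$segments,
               data.frame(id = 98, node_a = mid, node_b = 99, diameter = 5,
                          state = "normal", reference_diameter = 5,
                          is_trunk = FALSE, length = 40))
  net2 <- vascular_network(nd, seg, domain = net$domain)
  net2 <- assign_boundary_conditions(net2, cfg)
  nd2 <- net2$nodes
  expect_equal(nd2$boundary_pressure[nd2$is_arterial_trunk], cfg$p_art)
  expect_equal(nd2$boundary_pressure[nd2$is_venous_trunk], cfg$p_ven)
  expect_equal(nd2$boundary_pressure[nd2$id == 99],
               (cfg$p_art + cfg$p_ven) / 2)
  expect_equal(unname(nd2$boundary_oxygen[nd2$is_arterial_trunk]),
               cfg$po2_art)
  expect_error(assign_boundary_conditions(
    vascular_network(net$nodes[, !(names(net$nodes) %in%
                                     c("is_arterial_trunk", "is_venous_trunk"))],
                     net$segments, domain = net$domain), cfg),
    "trunk")
})

test_that("generator determinism extends to byte-identical serialization", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network(generate_macular_sector(seed = 11), f1)
  write_network(generate_macular_sector(seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("every generated network keeps diameters positive and an A-V path", {
  cfg <- sim_config()
  nets <- list(generate_hexagonal(n_rows = 3, n_cols = 3,
                                  deleted_edge_fraction = 0.15, seed = 2),
               generate_peripheral_ladder(seed = 2),
               generate_macular_sector(seed = 2))
  for (net in nets) {
    patent <- net$segments$state != "occluded"
    expect_true(all(net$segments$diameter[patent] > cfg$eps_d))
    expect_true(has_av_path(net))
  }
})
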