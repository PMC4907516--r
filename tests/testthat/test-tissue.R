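test_that("tiling partitions the footprint and interleaves MC/OT evenly", {
  cfg <- sim_config()
  net <- pipe_network(n_mid = 1, height = 120)
  tis <- build_tissue(net, cfg)
  cells <- tis$cells
  tiles <- cells[is.na(cells$segment_id), ]
  dom_area <- diff(net$domain[1:2]) * diff(net$domain[3:4])
  expect_lt(abs(sum(tiles$area) - dom_area) / dom_area, 1e-3)
  n_mc <- sum(tiles$kind == "MC"); n_ot <- sum(tiles$kind == "OT")
  expect_lte(abs(n_mc - n_ot), 1)
  ## checkerboard: MC tiles rarely touch MC tiles laterally
  con <- tis$contact[!tis$contact$wall, ]
  same_mc <- mean(cells$kind[con$i] == "MC" & cells$kind[con$j] == "MC")
  expect_lt(same_mc, 0.05)
})

test_that("contact graph is symmetric-positive and every CAP reaches tissue", {
  cfg <- sim_config()
  net <- generate_hexagonal(n_rows = 2, n_cols = 2, seed = 1)
  tis <- build_tissue(net, cfg)
  con <- tis$contact
  expect_true(all(con$area > 0))
  expect_true(all(con$i < con$j))          # stored once per unordered pair
  expect_false(any(duplicated(paste(con$i, con$j))))
  cells <- tis$cells
  caps <- cells$id[!is.na(cells$segment_id)]
  for (cp in caps) {
    nb <- c(con$j[con$i == cp], con$i[con$j == cp])
    expect_true(any(cells$kind[nb] != "CAP"))
  }
  ## FAZ footprint is tagged, not cellularized as tissue
  mac <- generate_macular_sector(seed = 1)
  tis2 <- build_tissue(mac, cfg)
  faz_tiles <- tis2$cells[tis2$cells$kind == "FAZ", ]
  expect_gt(nrow(faz_tiles), 10)
  expect_true(all(point_in_polygon(faz_tiles$x, faz_tiles$y, mac$faz)))
  ## vessels outside the domain are rejected
  bad <- net; bad$domain <- c(0, 50, 0, 50, 0, 50)
  expect_error(build_tissue(bad, cfg), "outside")
})

test_that("minimal cell-to-vessel distance responds to occlusion monotonically", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(generate_hexagonal(n_rows = 2, n_cols = 3,
                                                       seed = 4), cfg)
  tis <- build_tissue(net, cfg)
  d0 <- min_cell_vessel_distance(tis, net)
  expect_true(all(is.finite(d0)))
  ## an MC essentially on a centerline is at distance ~ 0
  expect_lt(min(d0), cfg$a_mc / 2)
  ## occluding any segment can only increase every MC's distance
  sid <- net$segments$id[!net$segments$is_trunk][7]
  d1 <- min_cell_vessel_distance(tis, occlude(net, sid, cfg))
  expect_true(all(d1 >= d0 - 1e-12))
  expect_true(any(d1 > d0 + 1e-9))
  ## with no patent segment the distances are the infinite sentinel
  all_occ <- occlude(net, net$segments$id, cfg)
  expect_true(all(is.infinite(min_cell_vessel_distance(tis, all_occ))))
})
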