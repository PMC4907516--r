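test_that("single-segment flow matches the Poiseuille closed form", {
  cfg <- sim_config(p_art = 40, p_ven = 20)
  net <- assign_boundary_conditions(pipe_network(n_mid = 0), cfg)
  fl <- solve_flow(net, cfg)
  q_expected <- pi * 5^4 * 20 / (128 * cfg$mu_blood * 100)
  expect_equal(fl$segments$flow, q_expected, tolerance = 1e-12)
  expect_equal(fl$segments$velocity, q_expected / (pi * 25 / 4),
               tolerance = 1e-12)
  expect_gt(fl$segments$velocity, 0)   # toward the low-pressure end
  expect_equal(fl$total_inflow, q_expected, tolerance = 1e-12)
})

test_that("series segments put the midpoint pressure at the mean", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(pipe_network(n_mid = 1), cfg)
  fl <- solve_flow(net, cfg)
  mid <- fl$node_pressures["2"]
  expect_equal(unname(mid), (cfg$p_art + cfg$p_ven) / 2, tolerance = 1e-9)
})

test_that("a symmetric Y-branch splits flow equally", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(y_network(), cfg)
  fl <- solve_flow(net, cfg)
  q <- fl$segments$flow
  expect_equal(q[2], q[3], tolerance = 1e-9 * abs(q[2]))
  expect_equal(q[1], q[2] + q[3], tolerance = 1e-9 * abs(q[1]))
})

test_that("Kirchhoff residuals are far below the inflow on generated networks", {
  cfg <- sim_config()
  for (net in list(generate_hexagonal(n_rows = 3, n_cols = 3, seed = 3),
                   generate_peripheral_ladder(seed = 3),
                   generate_macular_sector(seed = 3))) {
    fl <- solve_flow(assign_boundary_conditions(net, cfg), cfg)
    expect_lt(fl$kirchhoff_residual, 1e-9 * fl$total_inflow)
    ## global conservation: inflow equals outflow
    expect_lt(abs(sum(fl$boundary_flows)), 1e-9 * fl$total_inflow)
  }
})

test_that("occlusion is absorbing, kills flow, and conserves the rest", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(generate_hexagonal(n_rows = 2, n_cols = 3,
                                                       seed = 2), cfg)
  sid <- net$segments$id[!net$segments$is_trunk][5]
  net2 <- occlude(net, sid, cfg)
  k <- match(sid, net2$segments$id)
  expect_equal(net2$segments$state[k], "occluded")
  expect_equal(net2$segments$diameter[k], cfg$eps_d)
  expect_warning(occlude(net2, sid, cfg), "already")
  fl <- solve_flow(net2, cfg)
  expect_equal(fl$segments$velocity[k], 0)
  expect_lt(abs(sum(fl$boundary_flows)), 1e-9 * fl$total_inflow)
  ## occluding the sole A-V path zeroes the inflow
  pipe <- assign_boundary_conditions(pipe_network(n_mid = 1), cfg)
  pipe <- occlude(pipe, 1, cfg)
  expect_equal(solve_flow(pipe, cfg)$total_inflow, 0)
})

test_that("diameter adaptation is a bounded fixed point at reference shear", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(y_network(), cfg)
  fl <- solve_flow(net, cfg)
  tau_ref <- wall_shear(net, fl, cfg)
  same <- adapt_diameters(net, fl, cfg, tau_ref)
  expect_equal(same$segments$diameter, net$segments$diameter)
  ## occlude one daughter: the survivor gains flow and dilates, at most 1%
  net2 <- occlude(net, 2, cfg)
  fl2 <- solve_flow(net2, cfg)
  net3 <- adapt_diameters(net2, fl2, cfg, tau_ref)
  d_old <- net$segments$diameter[3]; d_new <- net3$segments$diameter[3]
  expect_gt(d_new, d_old)
  expect_lte(d_new / d_old, 1.01 + 1e-12)
  ## repeated adaptation stays within the hard envelope
  for (i in 1:60) {
    fl2 <- solve_flow(net2, cfg)
    net2 <- adapt_diameters(net2, fl2, cfg, tau_ref)
  }
  ratio <- net2$segments$diameter / net2$segments$reference_diameter
  patent <- net2$segments$state != "occluded"
  expect_true(all(ratio[patent] <= 1.3 + 1e-12))
  expect_true(all(ratio[patent] >= 0.8 - 1e-12))
})

test_that("removing a zero-flow segment leaves the solution unchanged", {
  cfg <- sim_config()
  ## dead-end spur carries no flow by construction
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 100), y = c(50, 50, 50, 120),
                      z = 25, is_boundary = c(TRUE, FALSE, TRUE, FALSE),
                      boundary_pressure = NA_real_, boundary_oxygen = NA_real_,
                      is_arterial_trunk = c(TRUE, FALSE, FALSE, FALSE),
                      is_venous_trunk = c(FALSE, FALSE, TRUE, FALSE))
  segs <- data.frame(id = 1:3, node_a = c(1, 2, 2), node_b = c(2, 3, 4),
                     diameter = 5)
  net <- assign_boundary_conditions(
    vascular_network(nodes, segs, domain = c(0, 200, 0, 150, 0, 50)), cfg)
  fl <- solve_flow(net, cfg)
  expect_lt(abs(fl$segments$flow[3]), 1e-12 * fl$total_inflow)
  net2 <- net
  net2$segments <- net2$segments[1:2, ]
  net2$nodes <- net2$nodes[1:3, ]
  fl2 <- solve_flow(net2, cfg)
  expect_equal(fl2$segments$flow[1:2], fl$segments$flow[1:2],
               tolerance = 1e-12)
})
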