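## minimal hand-built tissue for field-operator tests
toy_tissue <- function(n, volume = 1, kind = rep("OT", n), area = 1) {
  cells <- data.frame(id = seq_len(n), kind = kind, x = seq_len(n), y = 0,
                      area = 1, thickness = 1, volume = volume,
                      segment_id = NA_integer_, block = NA_integer_,
                      block_length = NA_real_, column = seq_len(n))
  contact <- if (n > 1)
    data.frame(i = seq_len(n - 1), j = 2:n, area = area, wall = FALSE)
  else data.frame(i = integer(0), j = integer(0), area = numeric(0),
                  wall = logical(0))
  structure(list(cells = cells, contact = contact,
                 grid = list(nx = n, ny = 1, px = 1, py = 1, origin = c(0, 0)),
                 base_thickness = 1), class = "tissue_model")
}

test_that("belt discretization follows velocity and conserves on rebuild", {
  cfg <- sim_config()
  seg <- data.frame(id = 1, node_a = 1, node_b = 2, diameter = 5, length = 100)
  cap_cells <- data.frame(id = 101:110, block = 1:10, block_length = 10)
  ch <- discretize_belts(seg, 500, 0.002, cap_cells, config = cfg)
  expect_equal(length(ch$vol), 100)
  expect_equal(ch$sizes[1], 1)
  ch2 <- discretize_belts(seg, 1000, 0.002, cap_cells, config = cfg)
  expect_equal(ch2$sizes[1], 2)
  expect_lte(abs(length(ch2$vol) - 50), 1)
  ## redistribution of existing block oxygen conserves the segment total
  vols <- stats::setNames(runif(10, 0, 5), 101:110)
  ch3 <- discretize_belts(seg, 731, 0.002, cap_cells, cap_volumes = vols,
                          config = cfg)
  expect_equal(sum(ch3$vol), sum(vols), tolerance = 1e-12)
  ## zero velocity means no chain
  expect_null(discretize_belts(seg, 0, 0.002, cap_cells, config = cfg))
})

test_that("advection conserves oxygen exactly on a closed loop", {
  cfg <- sim_config()
  nodes <- data.frame(id = 1:3, x = c(0, 100, 50), y = c(0, 0, 80), z = 25,
                      is_boundary = FALSE, boundary_pressure = NA_real_,
                      boundary_oxygen = NA_real_, is_arterial_trunk = FALSE,
                      is_venous_trunk = FALSE)
  segs <- data.frame(id = 1:3, node_a = c(1, 2, 3), node_b = c(2, 3, 1),
                     diameter = 5)
  net <- vascular_network(nodes, segs, domain = c(0, 100, 0, 80, 0, 50))
  chains <- list()
  for (k in 1:3) {
    cap_cells <- data.frame(id = 100 * k + 1:5, block = 1:5,
                            block_length = net$segments$length[k] / 5)
    ch <- discretize_belts(net$segments[k, ], 700, 0.002, cap_cells,
                           config = cfg)
    ch$vol <- runif(length(ch$vol))
    chains[[as.character(k)]] <- ch
  }
  total0 <- sum(vapply(chains, function(ch) sum(ch$vol), numeric(1)))
  for (s in 1:25) {
    adv <- advect_step(chains, net, cfg)
    chains <- adv$chains
    expect_equal(adv$injected, 0)
    expect_equal(adv$discharged, 0)
  }
  total1 <- sum(vapply(chains, function(ch) sum(ch$vol), numeric(1)))
  expect_equal(total1, total0, tolerance = 1e-14)
})

test_that("a symmetric branch splits the parent's outgoing volume in half", {
  cfg <- sim_config()
  net <- y_network()
  chains <- list()
  vel <- c(800, 400, 400)    # flow-conserving for equal diameters
  for (k in 1:3) {
    cap_cells <- data.frame(id = 100 * k + 1:5, block = 1:5,
                            block_length = net$segments$length[k] / 5)
    chains[[as.character(k)]] <-
      discretize_belts(net$segments[k, ], vel[k], 0.002, cap_cells,
                       config = cfg)
  }
  chains[["1"]]$vol[] <- 0
  n1 <- length(chains[["1"]]$vol)
  chains[["1"]]$vol[n1] <- 1    # the parent's last belt holds one unit
  adv <- advect_step(chains, net, cfg)
  expect_equal(adv$chains[["2"]]$vol[1], 0.5, tolerance = 1e-12)
  expect_equal(adv$chains[["3"]]$vol[1], 0.5, tolerance = 1e-12)
})

test_that("belt/block bookkeeping matches the canonical worked example", {
  ex <- conveyor_worked_example()
  expect_equal(ex$belt1[1], 0.8)                       # step 1
  expect_equal(ex$cap1_post[2], 1.44)                  # step 2
  expect_equal(ex$transfer_into_third[3], 0.64)        # step 3
  expect_equal(ex$cap2_diffused_fraction[3], 0.15625)  # step 3, 15.625%
  expect_equal(ex$cap1_pre[2], 1.8)
  expect_equal(ex$cap1_diffused_fraction[2], 0.2)
  ## ratio one (no diffusion) leaves belts unchanged
  ex0 <- conveyor_worked_example(steps = 2,
                                 losses = list(c("1" = 0), c("1" = 0)))
  expect_equal(ex0$belt1, c(1, 1))
  expect_equal(ex0$belt2[2], 1)
})

test_that("pairwise diffusion conserves mass and relaxes to exact profiles", {
  cfg <- sim_config()
  ## two isolated cells: capacity-weighted mean, total conserved
  tis <- toy_tissue(2, volume = c(1, 3))
  conc <- c(8, 0)
  for (i in 1:4000)
    conc <- occlusim:::exchange_step(conc, tis$cells, tis$contact, 1, 0.1)
  expect_equal(sum(conc * c(1, 3)), 8, tolerance = 1e-9)
  expect_equal(conc[1], conc[2], tolerance = 1e-6)
  expect_equal(conc[1], 2, tolerance = 1e-5)
  ## 1-D chain with pinned ends: linear steady tension profile
  n <- 9
  tis <- toy_tissue(n)
  conc <- rep(0, n)
  for (i in 1:6000)
    conc <- occlusim:::exchange_step(conc, tis$cells, tis$contact, 1, 0.2,
                                     pinned = c(1, n), pin_values = c(10, 26))
  expect_equal(conc, seq(10, 26, length.out = n), tolerance = 1e-5)
  ## equal tensions: zero net flux
  same <- occlusim:::exchange_step(c(5, 5), toy_tissue(2)$cells,
                                   toy_tissue(2)$contact, 1, 0.1)
  expect_equal(same, c(5, 5))
})

test_that("Michaelis-Menten consumption matches the implicit analytic solution", {
  cfg <- sim_config(v_max_o2 = 0.5, k_m_o2 = 2)
  tis <- toy_tissue(1, kind = "MC")
  C0 <- 10; C <- C0
  n_steps <- 2500
  for (i in seq_len(n_steps)) C <- consume_step(C, tis, cfg)
  t_num <- n_steps * cfg$dt_flux
  t_analytic <- (C0 - C) / cfg$v_max_o2 +
    cfg$k_m_o2 / cfg$v_max_o2 * log(C0 / C)
  expect_lt(abs(t_analytic - t_num) / t_num, 1e-3)
  ## half saturation and the zero boundary
  drop <- cfg$k_m_o2 - consume_step(cfg$k_m_o2, tis, cfg)
  expect_equal(drop, cfg$v_max_o2 / 2 * cfg$dt_flux, tolerance = 1e-12)
  expect_equal(consume_step(0, tis, cfg), 0)
})

test_that("compiled steady-state driver reproduces the reference iteration", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(pipe_network(n_mid = 1), cfg)
  flow <- solve_flow(net, cfg)
  tis <- build_tissue(net, cfg)
  nof <- occlusim:::total_node_outflow(net, flow)
  set.seed(42)
  for (trial in 1:3) {
    tension <- runif(nrow(tis$cells), 0, 40)
    chains <- build_chains(net, flow, tis, cfg, tension = tension)
    arr <- occlusim:::flatten_flux_problem(tension, chains, net, tis, cfg, flow)
    res <- occlusim:::oxygen_ss_cpp(
      arr$tension, arr$volume, arr$pin_idx, arr$pin_val, arr$consume_idx,
      arr$ci, arr$cj, arr$karea, arr$belt_vol, arr$belt_geom, arr$belt_cap,
      arr$seg_off, arr$seg_n, arr$seg_up_pool, arr$seg_down_pool,
      arr$seg_share, arr$seg_inlet_vol, arr$seg_frac, arr$n_pools,
      cfg$v_max_o2, cfg$k_m_o2, cfg$alpha_o2, cfg$dt_flux, cfg$tol_ss,
      0L, 1L)   # window 0: exactly one iteration
    ref <- occlusim:::oxygen_iteration_r(tension, chains, net, tis, cfg,
                                         node_outflow = nof)
    expect_equal(as.numeric(res$tension), ref$tension, tolerance = 1e-12)
    ref_belts <- unlist(lapply(ref$chains, `[[`, "vol"), use.names = FALSE)
    expect_equal(as.numeric(res$belt_vol), ref_belts, tolerance = 1e-12)
    expect_equal(res$injected, ref$injected, tolerance = 1e-12)
    expect_equal(res$discharged, ref$discharged, tolerance = 1e-12)
  }
})

test_that("oxygen steady state honors sources, sinks and monotonicity", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(pipe_network(n_mid = 3, height = 80), cfg)
  flow <- solve_flow(net, cfg)
  tis <- build_tissue(net, cfg)
  ox <- run_oxygen_to_steady_state(net, flow, tis, cfg)
  expect_true(ox$converged)
  expect_true(all(ox$tension >= 0))
  ## downstream monotonicity along the perfused pipe crossing consuming tissue
  caps <- which(!is.na(tis$cells$segment_id))
  ord <- caps[order(tis$cells$x[caps])]
  expect_true(all(diff(ox$tension[ord]) <= 1e-6))
  ## global balance: inflow - outflow - consumption ~ 0
  bal <- ox$balance
  expect_lt(abs(bal$inflow - bal$outflow - bal$consumption),
            0.02 * bal$inflow)
  ## steady state is independent of the initial guess
  set.seed(9)
  ox2 <- run_oxygen_to_steady_state(net, flow, tis, cfg,
                                    init = runif(nrow(tis$cells), 0, 40))
  expect_lt(max(abs(ox2$tension - ox$tension)), 1)
  ## a fully occluded network with no FAZ decays to zero everywhere
  dead <- occlude(net, net$segments$id, cfg)
  fl0 <- solve_flow(dead, cfg)
  ox0 <- run_oxygen_to_steady_state(dead, fl0, tis, cfg)
  expect_lt(max(ox0$tension), 0.5)
})
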