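test_that("checkpoint metrics and histogram behave at the extremes", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(pipe_network(n_mid = 1), cfg)
  tis <- build_tissue(net, cfg)
  fl <- solve_flow(net, cfg)
  n <- nrow(tis$cells)
  hyp_all <- tis$cells$kind == "MC"
  m <- compute_metrics(net, fl, tis, rep(1, n), hyp_all, NULL, cfg)
  expect_equal(m$hypoxic_fraction, 1)
  expect_equal(m$patent_fraction, 1)
  h <- oxygen_histogram(stats::runif(n, 0, 55), tis)
  expect_equal(sum(h), 1)
  expect_named(h)
})

test_that("mode counting separates unimodal from bimodal histograms", {
  uni <- c(0.01, 0.03, 0.1, 0.2, 0.25, 0.2, 0.12, 0.06, 0.02, 0.01,
           0, 0, 0, 0, 0)
  expect_equal(count_modes(uni), 1)
  bi <- c(0.2, 0.1, 0.02, 0.01, 0.02, 0.05, 0.15, 0.22, 0.15, 0.05,
          0.02, 0.01, 0, 0, 0)
  expect_equal(count_modes(bi), 2)
})

test_that("phase orientation signs match hand-built loops", {
  ## clockwise: hyperemic high-flow/low-O2 leg before the collapse
  cw <- data.frame(total_inflow = c(1, 1.1, 1.12, 0.7, 0.6),
                   mean_mc_o2 = c(1, 0.9, 0.7, 0.55, 0.5))
  expect_true(phase_orientation(cw)$clockwise)
  ccw <- data.frame(total_inflow = rev(cw$total_inflow),
                    mean_mc_o2 = rev(cw$mean_mc_o2))
  expect_false(phase_orientation(ccw)$clockwise)
})

test_that("segment graph distances count hops through shared nodes", {
  net <- pipe_network(n_mid = 2)     # three segments in a row
  d <- segment_graph_distances(net, 1)
  expect_equal(unname(d), c(0, 1, 2))
})

test_that("frozen dynamics leave the trajectory constant", {
  cfg <- sim_config(p_occ_max = 0, horizon_weeks = 12L, seed = 3)
  net <- small_hex(seed = 2)
  tr <- run_simulation(net, cfg, first_occlusion = "spontaneous")
  ck <- tr$checkpoints
  expect_equal(length(unique(round(ck$total_inflow, 9))), 1)
  expect_equal(sum(tr$events$event == "occlusion"), 0)
  expect_equal(utils::tail(ck$patent_count, 1), nrow(net$segments))
  expect_false(is_progressive(tr))
})

test_that("a run halts when no effective flow path remains", {
  cfg <- sim_config(horizon_weeks = 12L, seed = 1)
  net <- small_hex(seed = 2)
  tr <- run_simulation(net, cfg, first_occlusion = net$segments$id)
  expect_true(tr$terminated_early)
  expect_true("no_av_path" %in% tr$events$event)
  expect_lte(max(tr$checkpoints$model_week), 0)
})

test_that("trajectories are deterministic under a fixed seed", {
  cfg <- sim_config(horizon_weeks = 16L, seed = 11,
                    p_occ_max = 0.6, vegf_half = 1.2)  # frequent events
  net <- small_hex(seed = 2)
  tr1 <- run_simulation(net, cfg, first_occlusion = "spontaneous")
  tr2 <- run_simulation(net, cfg, first_occlusion = "spontaneous")
  expect_identical(tr1$checkpoints, tr2$checkpoints)
  expect_identical(tr1$events, tr2$events)
  ## damage is monotone: patent count never increases
  expect_true(all(diff(tr1$checkpoints$patent_count) <= 0))
  ## minimal cell-to-vessel distance never decreases
  expect_true(all(diff(tr1$checkpoints$mean_dmin_scaled) >= -1e-9))
})

test_that("ensembles are reproducible and summarize patency", {
  cfg <- sim_config(horizon_weeks = 8L, p_occ_max = 0.5, vegf_half = 1.5)
  net <- small_hex(seed = 2)
  ens <- run_ensemble(net, cfg, n_replicates = 2, seeds = c(5L, 5L),
                      first_occlusion = "spontaneous")
  expect_identical(ens$runs[[1]]$checkpoints, ens$runs[[2]]$checkpoints)
  expect_true(all(ens$patency_freq >= 0 & ens$patency_freq <= 1))
  expect_equal(length(ens$patency_freq), nrow(net$segments))
  expect_true(all(is.finite(ens$patency_index)))
  ## trunk segments are never drawn: patent unless disconnected
  trunk_ids <- as.character(net$segments$id[net$segments$is_trunk])
  expect_true(all(ens$patency_freq[trunk_ids] == 1))
})

test_that("the sweep harness reproduces the base run at multiplier one", {
  cfg <- sim_config(horizon_weeks = 8L, seed = 21)
  net <- small_hex(seed = 2)
  tab <- sweep_parameters(net, cfg, grid = list(p_occ_max = c(0, 1)),
                          n_replicates = 2, first_occlusion = "spontaneous")
  expect_equal(nrow(tab), 2)
  ## p_occ_max = 0 keeps every capillary patent
  expect_equal(tab$mean_patency_index[tab$multiplier == 0], 100)
  base <- run_ensemble(net, cfg, n_replicates = 2,
                       first_occlusion = "spontaneous")
  expect_equal(tab$mean_patency_index[tab$multiplier == 1],
               mean(base$patency_index))
})

test_that("the calibration search lands the hexagonal targets", {
  out <- calibrate_defaults(hex_args = list(edge_length_um = 65, n_rows = 3,
                                            n_cols = 3, seed = 1),
                            max_bisect = 6)
  expect_s3_class(out$report, "data.frame")
  expect_true(all(c("min_tension", "spontaneous_rate_per_year") %in%
                    out$report$check))
  expect_gte(out$report$value[out$report$check == "min_tension"], 4)
  expect_gt(out$config$p_occ_max, 0)
  expect_lte(out$config$p_occ_max, 1)
})
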