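test_that("leaky transitions follow the threshold and spare occluded/trunk", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(small_hex(), cfg)
  ids <- as.character(net$segments$id)
  basal <- stats::setNames(rep(cfg$vegf_basal, length(ids)), ids)
  expect_true(all(check_leaky(net, basal, cfg)$segments$state == "normal"))
  high <- basal; high[] <- cfg$vegf_leak_thr + 0.01
  net2 <- check_leaky(net, high, cfg)
  cap <- !net2$segments$is_trunk
  expect_true(all(net2$segments$state[cap] == "leaky"))
  expect_true(all(net2$segments$state[!cap] == "normal"))   # trunks never leak
  ## reversal on falling VEGF
  net3 <- check_leaky(net2, basal, cfg)
  expect_true(all(net3$segments$state == "normal"))
  ## occluded stays occluded
  sid <- net$segments$id[cap][1]
  occ <- occlude(net, sid, cfg)
  occ2 <- check_leaky(occ, high, cfg)
  expect_equal(occ2$segments$state[match(sid, occ2$segments$id)], "occluded")
})

test_that("edema bookkeeping follows creation minus drainage arithmetic", {
  cfg <- sim_config(fp_unit_volume = 200, fp_removal_volume = 50)
  net <- assign_boundary_conditions(pipe_network(n_mid = 0), cfg)
  tis <- build_tissue(net, cfg)
  ed <- edema_state(tis)
  ## no leaky segments: thickness stays at base
  ed0 <- form_edema(net, ed, tis, cfg)
  expect_true(all(thickness_map(ed0, tis) == cfg$base_thickness))
  ## k weekly checks with one leaky segment: per column, k*(unit - quota)
  net$segments$state <- "leaky"
  k <- 6
  for (i in seq_len(k)) ed <- form_edema(net, ed, tis, cfg)
  caps <- tis$cells[!is.na(tis$cells$segment_id), ]
  per_col <- table(caps$column)
  for (colid in names(per_col)) {
    expected <- k * (200 * per_col[[colid]] - 50)
    expect_equal(ed$fluid[as.integer(colid)], expected)
  }
  expect_equal(ed$created, k * nrow(caps) * 200)
  th <- thickness_map(ed, tis)
  expect_true(all(th >= cfg$base_thickness))
  expect_gt(max(th), cfg$base_thickness)
})

test_that("occlusion probability has the stated shape and limits", {
  cfg <- sim_config()
  expect_equal(occlusion_probability(0, 500, cfg), 0)
  ## strictly increasing in VEGF, strictly decreasing in velocity
  v <- seq(0.5, 30, by = 0.5)
  p_v <- occlusion_probability(v, 500, cfg)
  expect_true(all(diff(p_v) > 0))
  vel <- seq(0, 8000, by = 250)
  p_vel <- occlusion_probability(5, vel, cfg)
  expect_true(all(diff(p_vel) < 0))
  expect_lt(occlusion_probability(1e6, 1e9, cfg), 1e-12)   # v -> Inf limit
  expect_true(all(p_v >= 0 & p_v <= cfg$p_occ_max))
  ## Hill midpoint: half of the velocity-protected maximum
  expect_equal(occlusion_probability(cfg$vegf_half, 0, cfg),
               cfg$p_occ_max / 2, tolerance = 1e-12)
})

test_that("empirical occlusion frequency matches the stated probability", {
  cfg <- sim_config()
  p <- occlusion_probability(4, 800, cfg)
  n <- 1e5
  set.seed(123)
  hits <- sum(stats::runif(n) < p)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})

test_that("monthly checks draw per patent non-trunk segment, reproducibly", {
  cfg <- sim_config(p_occ_max = 1, vegf_half = 0.1, vel_scale = 1e9)
  net <- assign_boundary_conditions(small_hex(), cfg)
  fl <- solve_flow(net, cfg)
  sv <- stats::setNames(rep(10, nrow(net$segments)),
                        net$segments$id)   # forces p ~ 1
  set.seed(1)
  res <- apply_occlusion_checks(net, sv, fl, cfg)
  cap_ids <- net$segments$id[!net$segments$is_trunk]
  expect_setequal(res$occluded_ids, cap_ids)   # every capillary drawn, p ~ 1
  expect_true(all(res$network$segments$state[
    match(cap_ids, res$network$segments$id)] == "occluded"))
  ## trunks are never drawn
  expect_true(all(res$network$segments$state[res$network$segments$is_trunk] !=
                    "occluded"))
  ## p = 0 leaves the topology invariant
  cfg0 <- sim_config(p_occ_max = 0)
  res0 <- apply_occlusion_checks(net, sv, fl, cfg0)
  expect_length(res0$occluded_ids, 0)
  ## identical seed, identical draw sequence
  cfg_half <- sim_config(p_occ_max = 0.5, vegf_half = 5)
  set.seed(77); a <- apply_occlusion_checks(net, sv, fl, cfg_half)
  set.seed(77); b <- apply_occlusion_checks(net, sv, fl, cfg_half)
  expect_identical(a$occluded_ids, b$occluded_ids)
})
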