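test_that("Mueller hypoxia state uses a strict, reversible threshold", {
  cfg <- sim_config()
  net <- pipe_network(n_mid = 1)
  tis <- build_tissue(net, cfg)
  n <- nrow(tis$cells)
  tension <- rep(cfg$o2_hyp, n)       # exactly at threshold: normal
  expect_false(any(update_mc_states(tension, tis, cfg)))
  tension[] <- cfg$o2_hyp - 0.01
  hyp <- update_mc_states(tension, tis, cfg)
  expect_true(all(hyp[tis$cells$kind == "MC"]))
  expect_false(any(hyp[tis$cells$kind != "MC"]))
  ## re-oxygenation reverses the state
  tension[] <- 30
  expect_false(any(update_mc_states(tension, tis, cfg)))
})

test_that("VEGF synthesis saturates and only Mueller cells respond to hypoxia", {
  cfg <- sim_config()
  net <- pipe_network(n_mid = 1)
  tis <- build_tissue(net, cfg)
  n <- nrow(tis$cells)
  mc <- tis$cells$kind == "MC"
  hyp <- mc
  tension <- rep(0, n)
  v0 <- rep(0, n)
  v1 <- synthesize_step(v0, hyp, tension, tis, cfg)
  expect_equal(unique(v1[mc]),
               (cfg$k_syn + cfg$k_dec * cfg$vegf_basal) * cfg$dt_flux)
  expect_equal(unique(v1[!mc & tis$cells$kind != "FAZ"]),
               cfg$k_dec * cfg$vegf_basal * cfg$dt_flux)
  ## at saturation the hypoxic term vanishes
  v_sat <- rep(cfg$vegf_sat, n)
  v2 <- synthesize_step(v_sat, hyp, tension, tis, cfg)
  expect_equal(v2 - v_sat,
               rep(cfg$k_dec * cfg$vegf_basal * cfg$dt_flux, n))
})

test_that("uniform basal VEGF is a stationary state without hypoxia", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(small_hex(), cfg)   # no FAZ
  tis <- build_tissue(net, cfg)
  n <- nrow(tis$cells)
  hyp <- rep(FALSE, n)
  v <- rep(cfg$vegf_basal, n)
  v1 <- synthesize_step(v, hyp, rep(30, n), tis, cfg)
  v1 <- diffuse_decay_step(v1, tis, cfg)
  expect_equal(v1, v, tolerance = 1e-6)
  res <- run_vegf_to_steady_state(NULL, hyp, rep(30, n), tis, cfg)
  expect_equal(res$vegf, rep(cfg$vegf_basal, n), tolerance = 1e-3)
})

test_that("an isolated hypoxic source satisfies the scalar fixed point", {
  ## single driven cell with no neighbors: synthesis balances decay at
  ## V* solving k_syn (1 - V*/sat) + k_dec V_b = k_dec' V*
  cfg <- sim_config()
  cells <- data.frame(id = 1L, kind = "MC", x = 0, y = 0, area = 1,
                      thickness = 1, volume = 1, segment_id = NA_integer_,
                      block = NA_integer_, block_length = NA_real_,
                      column = 1L)
  tis <- structure(list(cells = cells,
                        contact = data.frame(i = integer(0), j = integer(0),
                                             area = numeric(0),
                                             wall = logical(0)),
                        grid = list(nx = 1, ny = 1, px = 1, py = 1,
                                    origin = c(0, 0)),
                        base_thickness = 1), class = "tissue_model")
  res <- run_vegf_to_steady_state(NULL, TRUE, 0, tis, cfg, use_cpp = TRUE)
  kd <- cfg$k_dec / (1 - cfg$k_dec * cfg$dt_flux)  # discrete-update decay
  v_star <- (cfg$k_syn + cfg$k_dec * cfg$vegf_basal) /
    (kd + cfg$k_syn / cfg$vegf_sat)
  expect_equal(res$vegf, v_star, tolerance = 1e-3)
})

test_that("VEGF spreads from a hypoxic patch with a finite screened range", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(pipe_network(n_mid = 5, height = 60), cfg)
  tis <- build_tissue(net, cfg)
  cells <- tis$cells
  n <- nrow(cells)
  ## force a compact hypoxic patch of MCs at the left end
  hyp <- cells$kind == "MC" & cells$x < 60
  expect_gt(sum(hyp), 0)
  tension <- rep(30, n); tension[hyp] <- 0
  res <- run_vegf_to_steady_state(NULL, hyp, tension, tis, cfg)
  v <- res$vegf
  ## monotone decrease with distance from the patch (binned in x)
  mid <- cells$kind %in% c("MC", "OT") & abs(cells$y - 50) < 25
  bins <- cut(cells$x[mid], seq(0, 620, by = 60))
  prof <- tapply(v[mid], bins, mean)
  prof <- prof[!is.na(prof)]
  expect_true(all(diff(prof) < 0))
  ## far field falls below 1% of the peak elevation above basal
  far <- cells$x > 500
  expect_lt(max(v[far] - cfg$vegf_basal),
            0.01 * max(v - cfg$vegf_basal))
  ## steady state independent of initialization
  set.seed(3)
  res2 <- run_vegf_to_steady_state(runif(n, 0, 10), hyp, tension, tis, cfg)
  expect_lt(max(abs(res2$vegf - v)), 0.05 * max(v))
})

test_that("adding occlusions never lowers steady-state VEGF anywhere", {
  cfg <- sim_config()
  net <- assign_boundary_conditions(generate_macular_sector(seed = 2), cfg)
  tis <- build_tissue(net, cfg)
  run_fields <- function(net) {
    fl <- solve_flow(net, cfg)
    ox <- run_oxygen_to_steady_state(net, fl, tis, cfg)
    hyp <- update_mc_states(ox$tension, tis, cfg)
    run_vegf_to_steady_state(NULL, hyp, ox$tension, tis, cfg)$vegf
  }
  sid <- pick_vulnerable_segment(net, cfg, near_x = 260)
  net1 <- occlude(net, sid, cfg)
  v1 <- run_fields(net1)
  ## nested: one more occlusion adjacent to the first
  d <- segment_graph_distances(net1, sid)
  sid2 <- net1$segments$id[net1$segments$state != "occluded" &
                             !net1$segments$is_trunk & d <= 2][1]
  v2 <- run_fields(occlude(net1, sid2, cfg))
  expect_true(all(v2 >= v1 - 0.05 * max(v1)))
  expect_gt(max(v2), max(v1) - 1e-9)
})
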