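#' Checkpoint metrics
#'
#' The summary quantities tracked along a run: total volume inflow rate, mean
#' Mueller-cell oxygen tension, hypoxic MC fraction, mean minimal
#' cell-to-vessel distance in Mueller-cell-size units, patent segment count
#' and fraction, and mean retinal thickness change.
#'
#' @param network,flow,tissue current state.
#' @param tension per-cell oxygen tensions.
#' @param hypoxic logical hypoxic-MC vector ([update_mc_states()]).
#' @param edema an `edema_state` (or NULL).
#' @param config a [sim_config()].
#' @return one-row data.frame of metrics.
#' @export
compute_metrics <- function(network, flow, tissue, tension, hypoxic, edema,
                            config) {
  cells <- tissue$cells
  mc <- cells$kind == "MC"
  dmin <- min_cell_vessel_distance(tissue, network)
  patent <- sum(network$segments$state != "occluded")
  th_change <- if (is.null(edema)) 0 else {
    th <- thickness_map(edema, tissue)
    100 * (mean(th) - tissue$base_thickness) / tissue$base_thickness
  }
  data.frame(
    total_inflow = flow$total_inflow,
    mean_mc_o2 = mean(tension[mc]),
    hypoxic_fraction = mean(hypoxic[mc]),
    mean_dmin_scaled = if (all(is.infinite(dmin))) NA_real_
                       else mean(dmin[is.finite(dmin)]) / config$a_mc,
    patent_count = patent,
    patent_fraction = patent / nrow(network$segments),
    thickness_change_pct = th_change)
}

#' Oxygen tension histogram in 4-mmHg bins
#'
#' Fraction of cells (CAP, MC and OT; the FAZ source region is excluded) per
#' 4-mmHg oxygen bin.
#'
#' @param tension per-cell oxygen tensions.
#' @param tissue a `tissue_model`.
#' @param bin_width bin width in mmHg (4 matches the reference presentation).
#' @param max_po2 upper edge of the last bin.
#' @return named numeric vector of fractions (sums to 1).
#' @export
oxygen_histogram <- function(tension, tissue, bin_width = 4, max_po2 = 60) {
  use <- tissue$cells$kind %in% c("CAP", "MC", "OT")
  x <- pmin(tension[use], max_po2 - 1e-9)
  br <- seq(0, max_po2, by = bin_width)
  h <- hist(x, breaks = br, plot = FALSE)
  stats::setNames(h$counts / sum(h$counts),
                  paste0("[", br[-length(br)], ",", br[-1], ")"))
}

#' Count modes of a binned distribution
#'
#' Light 1-2-1 smoothing, then counts local maxima of at least `min_peak`
#' mass that are separated by a trough below `trough_ratio` times the lower
#' of the two peaks. Used to classify the oxygen histogram as unimodal or
#' bimodal.
#'
#' @param fractions histogram fractions ([oxygen_histogram()]).
#' @param min_peak minimum peak mass.
#' @param trough_ratio maximum trough/peak ratio separating two modes.
#' @return integer mode count.
#' @export
count_modes <- function(fractions, min_peak = 0.04, trough_ratio = 0.7) {
  f <- as.numeric(fractions)
  n <- length(f)
  s <- f
  if (n >= 3)
    s[2:(n - 1)] <- 0.25 * f[1:(n - 2)] + 0.5 * f[2:(n - 1)] + 0.25 * f[3:n]
  peaks <- integer(0)
  for (i in seq_len(n)) {
    left <- if (i > 1) s[i - 1] else -Inf
    right <- if (i < n) s[i + 1] else -Inf
    if (s[i] >= left && s[i] >= right && s[i] >= min_peak)
      peaks <- c(peaks, i)
  }
  if (length(peaks) <= 1) return(length(peaks))
  ## merge peaks not separated by a real trough
  modes <- 1L
  last <- peaks[1]
  for (p in peaks[-1]) {
    trough <- min(s[last:p])
    if (trough < trough_ratio * min(s[last], s[p])) {
      modes <- modes + 1L
      last <- p
    } else if (s[p] > s[last]) last <- p
  }
  modes
}

#' Orientation of a flow-oxygen phase trajectory
#'
#' Signed (shoelace) area of the closed polygon traced by the checkpoints in
#' the (total inflow, mean MC oxygen) plane, both normalized to their
#' baseline. Negative area = clockwise passage (the progressive pattern:
#' hyperemic high-flow/low-oxygen excursion before the low-flow/low-oxygen
#' end state).
#'
#' @param checkpoints checkpoint data.frame of a trajectory.
#' @return `list(area, clockwise)`.
#' @export
phase_orientation <- function(checkpoints) {
  x <- checkpoints$total_inflow / checkpoints$total_inflow[1]
  y <- checkpoints$mean_mc_o2 / checkpoints$mean_mc_o2[1]
  n <- length(x)
  if (n < 3) return(list(area = 0, clockwise = NA))
  xs <- c(x, x[1]); ys <- c(y, y[1])
  area <- 0.5 * sum(xs[-(n + 1)] * ys[-1] - xs[-1] * ys[-(n + 1)])
  list(area = area, clockwise = area < 0)
}

## internal: resolve all steady states for the current topology
resolve_states <- function(net, tissue, config, warm = NULL) {
  flow <- solve_flow(net, config)
  ox <- run_oxygen_to_steady_state(net, flow, tissue, config,
                                   init = warm$tension,
                                   init_direct = warm$direct)
  hyp <- update_mc_states(ox$tension, tissue, config)
  vg <- run_vegf_to_steady_state(warm$vegf, hyp, ox$tension, tissue, config)
  list(flow = flow, tension = ox$tension, chains = ox$chains,
       hypoxic = hyp, vegf = vg$vegf, direct = ox$direct,
       seg_vegf = segment_vegf(vg$vegf, tissue, net),
       balance = ox$balance)
}

#' Run one simulation trajectory
#'
#' The event loop: solve flow, run oxygen and VEGF to steady state, then
#' advance the calendar week by week. Every week capillary leakiness and
#' edema are checked; every fourth week each patent non-trunk segment faces
#' an independent occlusion draw. After any occlusion the diameters adapt
#' (shear-log rule against the intact-network reference shear) and all
#' steady states are re-established. The run stops at the horizon or as soon
#' as no patent arteriole-to-venule path remains.
#'
#' Week 0 is the week of the first occlusion. In `"spontaneous"` mode the
#' waiting time to the first basal-rate occlusion is sampled analytically
#' (geometric over monthly checks) and the clock re-zeroed; a numeric
#' `first_occlusion` forces that segment occluded at week 0; `"none"` starts
#' the clock immediately with no forced event.
#'
#' @param network a `vascular_network` (boundary conditions are assigned
#'   internally if missing).
#' @param config a [sim_config()]; `config$seed` drives all randomness.
#' @param first_occlusion `"spontaneous"` (default), `"none"`, or a segment
#'   id to occlude at week 0.
#' @return an object of class `trajectory`: `checkpoints` (metrics per
#'   recorded week), `events` (model_week, event, segment_id), `histograms`
#'   (oxygen histogram per checkpoint), `baseline` and `final` state bundles,
#'   and the effective `config`.
#' @export
run_simulation <- function(network, config = sim_config(),
                           first_occlusion = "spontaneous") {
  set.seed(config$seed)
  net <- network
  if (all(is.na(net$nodes$boundary_pressure)))
    net <- assign_boundary_conditions(net, config)
  tissue <- build_tissue(net, config)
  edema <- edema_state(tissue)
  flow0 <- solve_flow(net, config)
  tau_ref <- wall_shear(net, flow0, config)
  st <- resolve_states(net, tissue, config)

  events <- data.frame(model_week = integer(0), event = character(0),
                       segment_id = integer(0))
  checkpoints <- NULL
  histograms <- list()
  note_checkpoint <- function(week, st) {
    m <- compute_metrics(net, st$flow, tissue, st$tension, st$hypoxic, edema,
                         config)
    m <- cbind(data.frame(model_week = week), m)
    checkpoints <<- rbind(checkpoints, m)
    histograms[[as.character(week)]] <<-
      oxygen_histogram(st$tension, tissue)
  }
  baseline <- list(flow = st$flow, tension = st$tension, vegf = st$vegf,
                   metrics = compute_metrics(net, st$flow, tissue, st$tension,
                                             st$hypoxic, edema, config))

  occlude_and_refresh <- function(ids, week) {
    net <<- occlude(net, ids, config)
    events <<- rbind(events, data.frame(model_week = week, event = "occlusion",
                                        segment_id = ids))
    fl <- solve_flow(net, config)
    net <<- adapt_diameters(net, fl, config, tau_ref)
    st <<- resolve_states(net, tissue, config,
                          warm = list(tension = st$tension, vegf = st$vegf,
                                      direct = st$direct))
  }

  ## first occlusion / clock zeroing
  if (is.numeric(first_occlusion)) {
    note_checkpoint(-4L, st)                  # pre-occlusion normal condition
    occlude_and_refresh(as.integer(first_occlusion), 0L)
    note_checkpoint(0L, st)
  } else if (identical(first_occlusion, "spontaneous")) {
    note_checkpoint(-4L, st)
    seg <- net$segments
    cand <- which(seg$state != "occluded" & !seg$is_trunk)
    cand <- cand[order(seg$id[cand])]
    vel <- st$flow$segments$velocity[match(seg$id[cand], st$flow$segments$id)]
    p <- occlusion_probability(st$seg_vegf[as.character(seg$id[cand])], vel,
                               config)
    P <- 1 - prod(1 - p)
    if (P > 0) {
      waited <- stats::rgeom(1, P)            # checks before first success
      first <- sample(seg$id[cand], 1, prob = p / sum(p))
      events <- rbind(events,
                      data.frame(model_week = 0L, event = "first_after_checks",
                                 segment_id = as.integer(waited)))
      occlude_and_refresh(first, 0L)
      note_checkpoint(0L, st)
    }
  } else if (!identical(first_occlusion, "none")) {
    stop("first_occlusion must be 'spontaneous', 'none' or a segment id",
         call. = FALSE)
  } else {
    note_checkpoint(0L, st)
  }

  occl_every <- as.integer(config$dt_occl_days / config$dt_edema_days)
  terminated <- !has_av_path(net)
  if (terminated)
    events <- rbind(events, data.frame(model_week = 0L, event = "no_av_path",
                                       segment_id = NA_integer_))
  for (week in seq_len(if (terminated) 0L else config$horizon_weeks)) {
    ## weekly leakiness / edema
    net <- check_leaky(net, st$seg_vegf, config)
    edema <- form_edema(net, edema, tissue, config)
    had_event <- FALSE
    if (week %% occl_every == 0L) {
      res <- apply_occlusion_checks(net, st$seg_vegf, st$flow, config)
      if (length(res$occluded_ids)) {
        net <- res$network
        ## adapt + refresh via the shared path (minus double occlude)
        events <- rbind(events,
                        data.frame(model_week = week, event = "occlusion",
                                   segment_id = res$occluded_ids))
        fl <- solve_flow(net, config)
        net <- adapt_diameters(net, fl, config, tau_ref)
        st <- resolve_states(net, tissue, config,
                             warm = list(tension = st$tension, vegf = st$vegf,
                                      direct = st$direct))
        had_event <- TRUE
        if (!has_av_path(net)) {
          note_checkpoint(week, st)
          events <- rbind(events,
                          data.frame(model_week = week, event = "no_av_path",
                                     segment_id = NA_integer_))
          terminated <- TRUE
          break
        }
      }
    }
    if (week %% 4L == 0L || had_event) note_checkpoint(week, st)
  }

  structure(list(checkpoints = checkpoints, events = events,
                 histograms = histograms, baseline = baseline,
                 final = list(network = net, flow = st$flow,
                              tension = st$tension, vegf = st$vegf,
                              hypoxic = st$hypoxic, edema = edema,
                              tissue = tissue, balance = st$balance),
                 terminated_early = terminated,
                 config = config),
            class = "trajectory")
}

#' @method print trajectory
#' @export
print.trajectory <- function(x, ...) {
  n_occ <- sum(x$events$event == "occlusion")
  last <- utils::tail(x$checkpoints, 1)
  cat(sprintf("<trajectory> %d checkpoints, %d occlusions%s\n",
              nrow(x$checkpoints), n_occ,
              if (x$terminated_early) " (terminated: no A-V path)" else ""))
  if (nrow(x$checkpoints))
    cat(sprintf("  final week %d: inflow %.3g (%.0f%% of baseline), hypoxic MC %.1f%%\n",
                last$model_week, last$total_inflow,
                100 * last$total_inflow / x$baseline$metrics$total_inflow,
                100 * last$hypoxic_fraction))
  invisible(x)
}

#' Is a trajectory progressive?
#'
#' A run is progressive if its final total inflow or final mean Mueller-cell
#' oxygen tension lies below 75\% of the pre-occlusion baseline.
#'
#' @param trajectory a `trajectory`.
#' @param threshold fraction of baseline (default 0.75).
#' @return logical.
#' @export
is_progressive <- function(trajectory, threshold = 0.75) {
  base <- trajectory$baseline$metrics
  last <- utils::tail(trajectory$checkpoints, 1)
  (last$total_inflow < threshold * base$total_inflow) ||
    (last$mean_mc_o2 < threshold * base$mean_mc_o2)
}

#' Run a replicate ensemble
#'
#' Independent replicates differing only in their RNG streams (and, when
#' `network` is a generator function, in network realization). Collects
#' per-segment patency frequencies at the horizon, the patency index per run
#' (percent patent segments), the flow-oxygen phase table and the
#' progressive classification. Individual run failures are recorded and the
#' ensemble continues.
#'
#' @param network a `vascular_network` (identical across replicates, the
#'   patency-map design) or a `function(seed)` returning one.
#' @param config a [sim_config()].
#' @param n_replicates number of replicates.
#' @param seeds optional integer vector of per-replicate seeds.
#' @param first_occlusion passed to [run_simulation()].
#' @return an `ensemble_summary`: `runs`, `patency_freq`, `patency_index`,
#'   `phase`, `progressive`, `errors`.
#' @export
run_ensemble <- function(network, config = sim_config(), n_replicates = 20,
                         seeds = NULL, first_occlusion = "spontaneous") {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (is.null(seeds))
    seeds <- (config$seed + 1009L * seq_len(n_replicates)) %% 2147483647L
  runs <- vector("list", n_replicates)
  errors <- character(0)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seeds[i]
    net_i <- if (is.function(network)) network(seeds[i]) else network
    runs[[i]] <- tryCatch(
      run_simulation(net_i, cfg, first_occlusion = first_occlusion),
      error = function(e) {
        errors <<- c(errors, sprintf("replicate %d (seed %d): %s", i, seeds[i],
                                     conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(runs, is.null, logical(1))
  pat_freq <- NULL
  if (!is.function(network) && any(ok)) {
    ids <- network$segments$id
    pat <- sapply(runs[ok], function(r)
      r$final$network$segments$state[match(ids, r$final$network$segments$id)] !=
        "occluded")
    pat_freq <- stats::setNames(rowMeans(pat), ids)
  }
  phase <- do.call(rbind, lapply(which(ok), function(i) {
    ck <- runs[[i]]$checkpoints
    data.frame(run = i, model_week = ck$model_week,
               total_inflow = ck$total_inflow, mean_mc_o2 = ck$mean_mc_o2)
  }))
  structure(list(
    runs = runs,
    seeds = seeds,
    patency_freq = pat_freq,
    patency_index = vapply(runs, function(r)
      if (is.null(r)) NA_real_ else 100 * utils::tail(r$checkpoints, 1)$patent_fraction,
      numeric(1)),
    progressive = vapply(runs, function(r)
      if (is.null(r)) NA else is_progressive(r), logical(1)),
    phase = phase,
    errors = errors), class = "ensemble_summary")
}

#' @method print ensemble_summary
#' @export
print.ensemble_summary <- function(x, ...) {
  ok <- !vapply(x$runs, is.null, logical(1))
  cat(sprintf("<ensemble_summary> %d/%d replicates succeeded, %d progressive\n",
              sum(ok), length(ok), sum(x$progressive, na.rm = TRUE)))
  cat(sprintf("  patency index: median %.1f%% (range %.1f-%.1f)\n",
              stats::median(x$patency_index, na.rm = TRUE),
              min(x$patency_index, na.rm = TRUE),
              max(x$patency_index, na.rm = TRUE)))
  invisible(x)
}

#' Graph distance between segments
#'
#' Hop distance on the segment adjacency graph (two segments are adjacent if
#' they share a node), used for occlusion-propagation locality statistics.
#'
#' @param network a `vascular_network`.
#' @param from_id source segment id.
#' @return named numeric vector of hop distances to every segment.
#' @export
segment_graph_distances <- function(network, from_id) {
  seg <- network$segments
  n <- nrow(seg)
  ## line-graph adjacency: segments sharing a node are neighbors
  incident <- split(rep(seq_len(n), 2), c(seg$node_a, seg$node_b))
  pairs <- do.call(rbind, lapply(incident, function(s) {
    s <- unique(s)
    if (length(s) < 2) NULL else t(utils::combn(s, 2))
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(pairs)) g <- igraph::add_edges(g, t(pairs))
  d <- igraph::distances(g, v = match(from_id, seg$id))
  stats::setNames(as.numeric(d[1, ]), seg$id)
}

#' Calibrate default constants on the hexagonal reference lattice
#'
#' Deterministic search fixing the oxygen constants so that the intact
#' 65-um hexagonal network has (i) no cell below the hypoxia threshold,
#' (ii) the bulk of cells between 10 and 25 mmHg and (iii) near-vessel cells
#' in the 35-40 mmHg range; then scales the occlusion model so that (iv) the
#' VEGF peak after a single central occlusion exceeds the Hill midpoint over
#' the ischemic patch and (v) the basal spontaneous occlusion rate is about
#' one segment per network-year. The package defaults are the output of this
#' procedure; rerunning it reproduces them.
#'
#' @param config starting [sim_config()].
#' @param hex_args arguments to [generate_hexagonal()].
#' @param target_min desired range for the minimum cell tension, mmHg.
#' @param spont_rate_per_year target basal occlusion rate (segments/year).
#' @param max_bisect bisection steps for the consumption rate.
#' @return `list(config, report)`; `report` is a data.frame of checks.
#' @export
calibrate_defaults <- function(config = sim_config(),
                               hex_args = list(edge_length_um = 65,
                                               n_rows = 5, n_cols = 6,
                                               seed = 1L),
                               target_min = c(6, 10),
                               spont_rate_per_year = 1,
                               max_bisect = 12) {
  net <- do.call(generate_hexagonal, hex_args)
  net <- assign_boundary_conditions(net, config)
  tissue <- build_tissue(net, config)
  eval_state <- function(cfg) {
    flow <- solve_flow(net, cfg)
    ox <- run_oxygen_to_steady_state(net, flow, tissue, cfg)
    list(flow = flow, tension = ox$tension)
  }
  ## (1) bisect the consumption ceiling: higher v_max -> lower minimum
  lo <- 0.1; hi <- 6
  cfg <- config
  for (i in seq_len(max_bisect)) {
    cfg$v_max_o2 <- sqrt(lo * hi)
    st <- eval_state(cfg)
    mn <- min(st$tension[tissue$cells$kind %in% c("MC", "OT")])
    if (mn < target_min[1]) hi <- cfg$v_max_o2
    else if (mn > target_min[2]) lo <- cfg$v_max_o2
    else break
  }
  st <- eval_state(cfg)
  tis <- tissue$cells$kind %in% c("MC", "OT")
  near <- unique(c(tissue$contact$i[tissue$cells$kind[tissue$contact$j] == "CAP"],
                   tissue$contact$j[tissue$cells$kind[tissue$contact$i] == "CAP"]))
  near <- near[tissue$cells$kind[near] %in% c("MC", "OT")]
  report <- data.frame(
    check = c("min_tension", "bulk_fraction_10_25", "near_vessel_mean"),
    value = c(min(st$tension[tis]),
              mean(st$tension[tis] >= 10 & st$tension[tis] <= 25),
              mean(st$tension[near])),
    target = c(paste(target_min, collapse = "-"), ">=0.5", "35-40"))
  ## (2) occlusion model: Hill midpoint below the single-occlusion VEGF peak
  hyp <- update_mc_states(st$tension, tissue, cfg)
  vg <- run_vegf_to_steady_state(NULL, hyp, st$tension, tissue, cfg)
  seg_v <- segment_vegf(vg$vegf, tissue, net)
  mid <- which(!net$segments$is_trunk)
  ctr <- mid[which.min((rowMeans(cbind(
    net$nodes$x[match(net$segments$node_a[mid], net$nodes$id)],
    net$nodes$x[match(net$segments$node_b[mid], net$nodes$id)])) -
      mean(range(net$nodes$x)))^2)]
  net1 <- occlude(net, net$segments$id[ctr], cfg)
  tissue1 <- tissue
  flow1 <- solve_flow(net1, cfg)
  ox1 <- run_oxygen_to_steady_state(net1, flow1, tissue1, cfg)
  hyp1 <- update_mc_states(ox1$tension, tissue1, cfg)
  vg1 <- run_vegf_to_steady_state(NULL, hyp1, ox1$tension, tissue1, cfg)
  seg_v1 <- segment_vegf(vg1$vegf, tissue1, net1)
  patent1 <- net1$segments$state != "occluded" & !net1$segments$is_trunk
  peak <- max(seg_v1[as.character(net1$segments$id[patent1])], na.rm = TRUE)
  if (peak <= cfg$vegf_half) cfg$vegf_half <- 0.8 * peak
  report <- rbind(report, data.frame(check = "single_occlusion_vegf_peak",
                                     value = peak,
                                     target = paste0("> vegf_half (",
                                                     signif(cfg$vegf_half, 3), ")")))
  ## (3) basal spontaneous rate: p is linear in p_occ_max
  vel <- st$flow$segments$velocity[match(net$segments$id, st$flow$segments$id)]
  cand <- net$segments$state != "occluded" & !net$segments$is_trunk
  p <- occlusion_probability(seg_v[as.character(net$segments$id[cand])],
                             vel[cand], cfg)
  checks_per_year <- 365 / cfg$dt_occl_days
  rate <- checks_per_year * sum(p)
  if (rate > 0) cfg$p_occ_max <- min(1, cfg$p_occ_max * spont_rate_per_year / rate)
  report <- rbind(report, data.frame(check = "spontaneous_rate_per_year",
                                     value = rate,
                                     target = sprintf("rescaled to %g",
                                                      spont_rate_per_year)))
  list(config = cfg, report = report)
}

#' One-at-a-time parameter sweep
#'
#' Varies named configuration fields one at a time over supplied multipliers
#' (or absolute values), running a replicate ensemble per grid cell and
#' reporting the mean patency index (percent patent segments at the end) and
#' the mean percent thickness change.
#'
#' @param network a `vascular_network` or generator `function(seed)`.
#' @param config base [sim_config()].
#' @param grid named list: for each parameter, the multipliers to apply to
#'   the base value (a multiplier of 1 reproduces the base configuration).
#' @param n_replicates replicates per grid cell (28 by default).
#' @param first_occlusion passed to [run_simulation()].
#' @return data.frame: parameter, multiplier, value, mean_patency_index,
#'   mean_thickness_change_pct, n_ok.
#' @export
sweep_parameters <- function(network, config = sim_config(), grid,
                             n_replicates = 28,
                             first_occlusion = "spontaneous") {
  out <- NULL
  for (par in names(grid)) {
    if (is.null(config[[par]]))
      stop("unknown config field in sweep grid: ", par, call. = FALSE)
    for (mult in grid[[par]]) {
      cfg <- config
      cfg[[par]] <- cfg[[par]] * mult
      ens <- run_ensemble(network, cfg, n_replicates = n_replicates,
                          first_occlusion = first_occlusion)
      th <- vapply(ens$runs, function(r)
        if (is.null(r)) NA_real_ else
          utils::tail(r$checkpoints, 1)$thickness_change_pct, numeric(1))
      out <- rbind(out, data.frame(
        parameter = par, multiplier = mult, value = cfg[[par]],
        mean_patency_index = mean(ens$patency_index, na.rm = TRUE),
        mean_thickness_change_pct = mean(th, na.rm = TRUE),
        n_ok = sum(!is.na(ens$patency_index))))
    }
  }
  out
}

#' Pick the most vulnerable patent segment
#'
#' Deterministically scores every patent non-trunk segment by the number of
#' Mueller cells that would fall below the hypoxia threshold if that segment
#' alone were occluded (steady states approximated by the direct solver), and
#' returns the id with the largest impact - the natural choice for a forced
#' initial occlusion, mirroring the vulnerable juxtafoveal sites.
#'
#' @param network a `vascular_network` (boundary conditions assigned).
#' @param config a [sim_config()].
#' @param near_x optional upper bound on segment midpoint x (um) to restrict
#'   the search, e.g. to the FAZ side of a macular sector.
#' @return a segment id.
#' @export
pick_vulnerable_segment <- function(network, config = sim_config(),
                                    near_x = Inf) {
  flow <- solve_flow(network, config)
  tissue <- build_tissue(network, config)
  ox <- run_oxygen_to_steady_state(network, flow, tissue, config)
  seg <- network$segments; nd <- network$nodes
  mx <- (nd$x[match(seg$node_a, nd$id)] + nd$x[match(seg$node_b, nd$id)]) / 2
  cand <- which(seg$state != "occluded" & !seg$is_trunk & mx <= near_x)
  mc <- tissue$cells$kind == "MC"
  score <- numeric(length(cand))
  cost <- numeric(length(cand))
  for (k in seq_along(cand)) {
    n2 <- occlude(network, seg$id[cand[k]], config)
    f2 <- solve_flow(n2, config)
    d2 <- oxygen_direct_solve(n2, f2, tissue, config, C0 = ox$tension)
    score[k] <- sum(mc & d2 < config$o2_hyp)
    cost[k] <- 1 - f2$total_inflow / flow$total_inflow
  }
  ## among hypoxia-inducing sites prefer the one that costs the least total
  ## inflow - the slow capillary whose loss starves tissue without cutting a
  ## feeding conduit, the kind of vessel that occludes first in vivo
  good <- which(score >= max(1, 0.3 * max(score)))
  if (!length(good)) good <- which(score == max(score))
  seg$id[cand[good[which.min(cost[good])]]]
}
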