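#' Simulation configuration
#'
#' Builds the full parameter set of the simulator: the three clocks of the
#' model (flux integration step, weekly edema check, monthly occlusion check),
#' boundary values, oxygen and VEGF transport/kinetic constants, the occlusion
#' probability model, diameter adaptation, tissue tiling geometry and numerical
#' tolerances. Defaults reproduce the calibrated normal state on the 65-micron
#' hexagonal lattice (no cell below 4 mmHg, tissue bulk at 10-25 mmHg,
#' near-vessel cells at 35-40 mmHg) and a basal spontaneous occlusion rate of
#' roughly one segment per network-year; see the package vignette for the
#' calibration procedure. All values can be overridden by name.
#'
#' Units: lengths in micrometers, time in seconds for fluxes and days/weeks for
#' the event clocks, pressures and oxygen tensions in mmHg, VEGF in arbitrary
#' units (A.U.) with the basal level defining 1 A.U.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return An object of class `sim_config` (a validated named list).
#'
#' @section Main fields:
#' \describe{
#'   \item{dt_flux}{flux integration time step, s (0.002).}
#'   \item{dt_edema_days, dt_occl_days}{edema/leakiness check interval (7 d)
#'     and occlusion check interval (28 d).}
#'   \item{horizon_weeks}{simulated horizon after the first occlusion (156).}
#'   \item{p_art, p_ven}{arteriolar / venular terminal pressures, mmHg.}
#'   \item{po2_art, po2_faz, po2_inlet_scale}{arterial and foveal-avascular-zone
#'     oxygen tensions, and the factor (<1) applied to secondary inlets.}
#'   \item{v_max_o2, k_m_o2}{Michaelis-Menten consumption: maximal rate
#'     (mmHg/s) and half-saturation tension (mmHg); MC and OT cells only.}
#'   \item{k_o2, k_o2_wall, alpha_o2}{contact-surface oxygen exchange
#'     coefficients (um/s) for tissue-tissue and vessel-wall contacts, and the
#'     tension-to-volume conversion (volume per mmHg per um^3).}
#'   \item{mu_blood}{effective blood viscosity, mmHg s (2 cP).}
#'   \item{o2_hyp}{hypoxia threshold for Mueller cells, mmHg.}
#'   \item{k_syn, k_dec, k_vegf, vegf_basal, vegf_sat}{VEGF synthesis rate
#'     (A.U./s), first-order decay (1/s), contact-surface exchange coefficient
#'     (um/s), basal level (A.U.) and saturation level (A.U.).}
#'   \item{vegf_leak_thr}{VEGF threshold above which a capillary turns leaky.}
#'   \item{p_occ_max, vegf_half, vel_scale, hill_h}{occlusion probability
#'     model p = p_occ_max * V^h/(V^h + vegf_half^h) * exp(-v/vel_scale).}
#'   \item{k_adapt}{shear-log diameter adaptation gain (step clipped to 1\%
#'     per event, diameters to 0.8-1.3 x reference).}
#'   \item{a_mc, mc_fraction, cap_block_len}{Mueller-cell tile pitch (um), MC
#'     share of tissue tiles, capillary block length along centerlines (um).}
#'   \item{eps_d}{diameter assigned to occluded segments (um).}
#'   \item{tol_ss, ss_window, ss_max_iter}{steady-state stopping rule: maximum
#'     relative per-iteration tension change below tol_ss for ss_window
#'     consecutive iterations, hard cap ss_max_iter.}
#'   \item{fp_unit_volume, fp_removal_volume}{edema fluid added per leaky
#'     capillary block per weekly check and drainage quota per tissue column
#'     per week, um^3.}
#'   \item{base_thickness}{initial retinal thickness, um (50).}
#'   \item{max_belts}{cap on conveyor-belt count per segment; slower segments
#'     are treated as stagnant for advection.}
#'   \item{seed}{base RNG seed for a run.}
#' }
#'
#' @examples
#' cfg <- sim_config(p_occ_max = 0)   # occlusion switched off
#' cfg$p_occ_max
#' @export
sim_config <- function(...) {
  cfg <- list(
    ## clocks
    dt_flux       = 0.002,   # s
    dt_edema_days = 7,
    dt_occl_days  = 28,
    horizon_weeks = 156L,
    ## hemodynamic boundary values
    p_art = 45,              # mmHg
    p_ven = 19,              # mmHg
    mu_blood = 2e-3 / 133.322, # 2 cP in mmHg s
    ## oxygen
    po2_art = 50,            # mmHg
    po2_faz = 20,            # mmHg
    po2_inlet_scale = 0.8,
    v_max_o2 = 0.18,         # mmHg/s (calibrated)
    k_m_o2   = 1,            # mmHg
    k_o2     = 2,            # um/s tissue-tissue contact permeability (calibrated)
    k_o2_wall = 40,          # um/s vessel-wall (CAP) contact permeability
    alpha_o2 = 1,            # volume units per (mmHg um^3)
    o2_hyp   = 4,            # mmHg
    ## VEGF
    k_syn      = 250,        # A.U./s at full hypoxic drive
    k_dec      = 0.15,       # 1/s
    k_vegf     = 96,         # um/s contact permeability
    vegf_basal = 1,          # A.U.
    vegf_sat   = 50,         # A.U.
    ## pathology
    vegf_leak_thr = 4.5,     # A.U.
    p_occ_max = 0.04,
    vegf_half = 3,           # A.U.
    vel_scale = 2000,        # um/s
    hill_h    = 3,
    ## adaptation
    k_adapt = 1,
    ## tissue
    a_mc          = 12,      # um
    mc_fraction   = 0.5,
    cap_block_len = 10,      # um
    base_thickness = 50,     # um
    ## numerics
    eps_d       = 1e-6,      # um
    tol_ss      = 1e-6,
    ss_window   = 10L,
    ss_max_iter = 1e6,
    max_belts   = 2000L,
    ## edema bookkeeping
    fp_unit_volume    = 150,  # um^3 per leaky CAP block per weekly check
    fp_removal_volume = 100,  # um^3 per tissue column per weekly check
    ## RNG
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all overrides to sim_config() must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(dots)] <- dots
  }
  cfg <- validate_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` object (or plain list with the same fields).
#' @export
validate_config <- function(config) {
  pos <- c("dt_flux", "dt_edema_days", "dt_occl_days", "mu_blood",
           "v_max_o2", "k_m_o2", "k_o2", "k_o2_wall", "alpha_o2", "o2_hyp",
           "k_syn", "k_dec", "k_vegf", "vegf_basal", "vegf_sat",
           "vegf_leak_thr", "vegf_half", "vel_scale", "hill_h",
           "a_mc", "cap_block_len", "base_thickness",
           "eps_d", "tol_ss", "fp_unit_volume")
  for (f in pos) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("sim_config field '", f, "' must be a positive number", call. = FALSE)
  }
  if (config$p_occ_max < 0 || config$p_occ_max > 1)
    stop("p_occ_max must lie in [0, 1]", call. = FALSE)
  if (config$mc_fraction <= 0 || config$mc_fraction >= 1)
    stop("mc_fraction must lie in (0, 1)", call. = FALSE)
  if (config$po2_inlet_scale <= 0 || config$po2_inlet_scale > 1)
    stop("po2_inlet_scale must lie in (0, 1]", call. = FALSE)
  if (config$p_art <= config$p_ven)
    stop("p_art must exceed p_ven", call. = FALSE)
  if (config$hill_h < 1)
    stop("hill_h must be >= 1", call. = FALSE)
  horizon_days <- config$horizon_weeks * 7
  if (horizon_days %% config$dt_edema_days != 0)
    stop("horizon must be a multiple of the edema check interval", call. = FALSE)
  ## explicit-Euler stability of the pairwise exchange updates is checked
  ## against the actual contact geometry in build_tissue()/steady-state setup;
  ## here we only guard the obvious k*dt scale.
  if (max(config$k_o2, config$k_o2_wall) * config$dt_flux > config$a_mc ||
      config$k_vegf * config$dt_flux > config$a_mc)
    stop("dt_flux too large for the contact-exchange coefficients", call. = FALSE)
  config
}

#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  clocks: dt_flux=%g s, edema every %g d, occlusion every %g d, horizon %d wk\n",
              x$dt_flux, x$dt_edema_days, x$dt_occl_days, x$horizon_weeks))
  cat(sprintf("  pressures: %g -> %g mmHg; PO2 art/FAZ: %g / %g mmHg\n",
              x$p_art, x$p_ven, x$po2_art, x$po2_faz))
  cat(sprintf("  O2: Vmax=%g mmHg/s, Km=%g, k=%g um/s; VEGF: ksyn=%g, kdec=%g, k=%g\n",
              x$v_max_o2, x$k_m_o2, x$k_o2, x$k_syn, x$k_dec, x$k_vegf))
  cat(sprintf("  occlusion: pmax=%g, Vhalf=%g, vscale=%g, h=%g; leak thr=%g\n",
              x$p_occ_max, x$vegf_half, x$vel_scale, x$hill_h, x$vegf_leak_thr))
  invisible(x)
}
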