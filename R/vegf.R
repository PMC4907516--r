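#' Update Mueller-cell hypoxia states
#'
#' A Mueller cell is hypoxic if and only if its oxygen tension is strictly
#' below the threshold `o2_hyp`; the transition is reversible (a
#' re-oxygenated MC returns to normal).
#'
#' @param tension converged per-cell oxygen tensions, mmHg.
#' @param tissue a `tissue_model`.
#' @param config a [sim_config()].
#' @return logical vector over all cells: `TRUE` for hypoxic MCs.
#' @export
update_mc_states <- function(tension, tissue, config) {
  tissue$cells$kind == "MC" & tension < config$o2_hyp
}

#' One VEGF synthesis step
#'
#' Hypoxic Mueller cells synthesize at rate
#' `k_syn * (1 - C/o2_hyp)_+ * (1 - V/vegf_sat)_+`, a linear ramp in oxygen
#' deficit with linear saturation in VEGF. In addition a small basal
#' production `k_dec * vegf_basal` in every decaying cell (CAP, MC, OT)
#' maintains the diabetic basal VEGF level as an exact fixed point of
#' synthesis-decay.
#'
#' @param vegf per-cell VEGF levels, A.U.
#' @param hypoxic logical vector from [update_mc_states()].
#' @param tension per-cell oxygen tensions, mmHg.
#' @inheritParams update_mc_states
#' @return updated VEGF vector.
#' @export
synthesize_step <- function(vegf, hypoxic, tension, tissue, config) {
  kinds <- tissue$cells$kind
  basal <- (kinds != "FAZ") * config$k_dec * config$vegf_basal
  drive <- numeric(length(vegf))
  drive[hypoxic] <- config$k_syn *
    pmax(0, 1 - tension[hypoxic] / config$o2_hyp) *
    pmax(0, 1 - vegf[hypoxic] / config$vegf_sat)
  vegf + (basal + drive) * config$dt_flux
}

#' One VEGF diffusion-plus-decay step
#'
#' Pairwise contact-surface exchange `k_vegf * A_ij * (V_i - V_j)` among CAP,
#' MC and OT cells, first-order decay `-k_dec * V` in the same cells, and the
#' FAZ pinned at zero (VEGF sink). VEGF is not transported by advection.
#'
#' @inheritParams synthesize_step
#' @return updated VEGF vector.
#' @export
diffuse_decay_step <- function(vegf, tissue, config) {
  pin <- which(tissue$cells$kind == "FAZ")
  vegf <- exchange_step(vegf, tissue$cells, tissue$contact, config$k_vegf,
                        config$dt_flux, pinned = pin,
                        pin_values = numeric(length(pin)))
  dec <- tissue$cells$kind != "FAZ"
  vegf[dec] <- pmax(0, vegf[dec] * (1 - config$k_dec * config$dt_flux))
  vegf[pin] <- 0
  vegf
}

#' Run the VEGF field to steady state
#'
#' Iterates synthesis, diffusion and decay with the same time step and
#' stopping rule as the oxygen field; follows immediately after the oxygen
#' steady state (the oxygen tensions and MC states are held fixed).
#'
#' @param vegf initial per-cell VEGF (warm start); defaults to the basal
#'   level everywhere.
#' @inheritParams synthesize_step
#' @param use_cpp run the compiled driver (default) or the R reference loop.
#' @return `list(vegf, iterations, converged)`.
#' @export
run_vegf_to_steady_state <- function(vegf = NULL, hypoxic, tension, tissue,
                                     config, use_cpp = TRUE,
                                     accelerate = use_cpp) {
  cells <- tissue$cells
  check_exchange_stability(cells, tissue$contact, config$k_vegf,
                           config$dt_flux, "VEGF")
  if (is.null(vegf)) vegf <- rep(config$vegf_basal, nrow(cells))
  pin <- cells$kind == "FAZ"
  vegf[pin] <- 0
  drive <- numeric(nrow(cells))
  drive[hypoxic] <- config$k_syn * pmax(0, 1 - tension[hypoxic] / config$o2_hyp)
  basal <- (cells$kind != "FAZ") * config$k_dec * config$vegf_basal
  if (accelerate)
    vegf <- vegf_direct_solve(tissue, config, drive, basal, V0 = vegf)

  if (use_cpp) {
    res <- vegf_ss_cpp(vegf, cells$volume, as.integer(which(pin) - 1L),
                       drive, basal,
                       as.integer(tissue$contact$i - 1L),
                       as.integer(tissue$contact$j - 1L),
                       config$k_vegf * tissue$contact$area,
                       config$k_dec, config$vegf_sat,
                       config$dt_flux, config$tol_ss,
                       as.integer(config$ss_window),
                       as.integer(config$ss_max_iter))
    return(list(vegf = as.numeric(res$vegf), iterations = res$iterations,
                converged = res$converged))
  }

  window <- 0L; it <- 0L
  while (it < config$ss_max_iter) {
    it <- it + 1L
    v_new <- synthesize_step(vegf, hypoxic, tension, tissue, config)
    v_new <- diffuse_decay_step(v_new, tissue, config)
    delta <- max(abs(v_new - vegf) / pmax(abs(vegf), 0.05))
    vegf <- v_new
    window <- if (delta < config$tol_ss) window + 1L else 0L
    if (window >= config$ss_window) break
  }
  if (window < config$ss_window)
    stop(sprintf("VEGF steady state not reached in %d iterations", it),
         call. = FALSE)
  list(vegf = vegf, iterations = it, converged = TRUE)
}

#' Per-segment VEGF level
#'
#' Mean VEGF over a segment's capillary blocks; the quantity that drives the
#' leaky transition and the occlusion probability (occlusion acts on whole
#' segments).
#'
#' @param vegf per-cell VEGF vector.
#' @param tissue a `tissue_model`.
#' @param network the `vascular_network`.
#' @return named numeric, one value per segment id.
#' @export
segment_vegf <- function(vegf, tissue, network) {
  cells <- tissue$cells
  cap <- !is.na(cells$segment_id)
  m <- tapply(vegf[cap], cells$segment_id[cap], mean)
  out <- stats::setNames(rep(NA_real_, nrow(network$segments)),
                         network$segments$id)
  out[names(m)] <- as.numeric(m)
  out
}

## direct sparse steady solve seeding the explicit VEGF iteration: Picard on
## the saturation term; diffusion + first-order decay + FAZ Dirichlet sink.
vegf_direct_solve <- function(tissue, config, drive, basal, V0 = NULL,
                              picard_iter = 12, damp = 0.5) {
  cells <- tissue$cells
  n <- nrow(cells)
  ke <- config$k_vegf * tissue$contact$area
  ci <- tissue$contact$i; cj <- tissue$contact$j
  faz <- which(cells$kind == "FAZ")
  Vc <- cells$volume
  ## effective decay of the discrete update V <- (V + s*dt + D*dt)*(1-k*dt)
  kd <- config$k_dec / (1 - config$k_dec * config$dt_flux)
  dec <- as.numeric(cells$kind != "FAZ") * kd
  V <- if (is.null(V0)) rep(config$vegf_basal, n) else pmax(V0, 0)
  for (it in seq_len(picard_iter)) {
    sat <- pmax(0, 1 - V / config$vegf_sat)
    ti <- c(ci, cj, ci, cj, seq_len(n))
    tj <- c(ci, cj, cj, ci, seq_len(n))
    tx <- c(ke, ke, -ke, -ke, dec * Vc)
    rhs <- (basal + drive * sat) * Vc
    drop <- ti %in% faz
    A <- Matrix::sparseMatrix(i = c(ti[!drop], faz), j = c(tj[!drop], faz),
                              x = c(tx[!drop], rep(1, length(faz))),
                              dims = c(n, n))
    rhs[faz] <- 0
    V_new <- pmax(as.numeric(Matrix::solve(A, rhs)), 0)
    step <- max(abs(V_new - V))
    ## damping suppresses the 2-cycle of the lagged saturation term when the
    ## field crosses vegf_sat
    V <- damp * V_new + (1 - damp) * V
    if (step < 1e-2 * max(V, 1)) break
  }
  V
}
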