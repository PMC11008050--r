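#' Population transfer function (f-I curve)
#'
#' Converts an input current into a firing rate through the sigmoidal
#' response `g (I - I_thr) / (1 - exp(-d g (I - I_thr)))` of the requested
#' population. The removable singularity at the threshold current is
#' evaluated as its limit `1/d` (6.25 Hz for the excitatory population,
#' about 11.494 Hz for the inhibitory one), so the function is continuous
#' and strictly increasing everywhere.
#'
#' @param I Input current, nA (vectorized).
#' @param population `"E"` or `"I"`.
#' @param params A [dmf_params()] object.
#' @return Firing rate(s), Hz.
#' @examples
#' transfer_rate(0.403, "E")  # 1/d_E = 6.25 Hz
#' @export
transfer_rate <- function(I, population = c("E", "I"), params = dmf_params()) {
  population <- match.arg(population)
  g <- if (population == "E") params$g_E else params$g_I
  thr <- if (population == "E") params$I_thr_E else params$I_thr_I
  d <- if (population == "E") params$d_E else params$d_I
  vapply(I, transfer_rate_cpp, numeric(1), g = g, Ithr = thr, d = d)
}

#' Population input currents
#'
#' Evaluates the excitatory and inhibitory input currents for a given
#' synaptic gating state: the excitatory current sums external drive, local
#' recurrence, the connectome-weighted long-range input scaled by the global
#' coupling `G`, and the local feedback inhibition `J_n S_n^I`; the
#' inhibitory current sums scaled external drive, local excitatory input,
#' and self-inhibition.
#'
#' @param S_E,S_I Per-region excitatory/inhibitory gating vectors in `[0,1]`.
#' @param connectome A [structural_connectome()] (or plain matrix).
#' @param fic Per-region FIC weights `J_n`, nA (a [fic_vector()] or numeric).
#' @param params A [dmf_params()] object.
#' @return List with numeric vectors `I_E` and `I_I`, nA.
#' @export
dmf_currents <- function(S_E, S_I, connectome, fic, params = dmf_params()) {
  C <- as_connectome_matrix(connectome)
  J <- as_fic_j(fic)
  n <- nrow(C)
  if (length(S_E) != n || length(S_I) != n || length(J) != n)
    stop("state/FIC length does not match the connectome (", n, " regions)")
  I_E <- params$W_E * params$I0 + params$W_plus * params$J_NMDA * S_E +
    params$G * params$J_NMDA * drop(C %*% S_E) - J * S_I
  I_I <- params$W_I * params$I0 + params$J_NMDA * S_E - S_I
  list(I_E = I_E, I_I = I_I)
}

#' Modulate feedback inhibition by regional atrophy
#'
#' Applies `J_n = J_n^0 (1 + sigma * alpha_n)` element-wise, where
#' `alpha_n` is the regional atrophy loading (positive meaning more
#' atrophy) and `sigma` is the scalar atrophy-coupling parameter: negative
#' `sigma` reduces inhibition in atrophied regions, `sigma = 0` leaves the
#' baseline untouched. Strongly negative products could drive a weight to
#' zero or below (runaway excitation), so modulated weights are floored at
#' `j_min` with a warning.
#'
#' @param fic Baseline FIC ([fic_vector()] or numeric `J^0`).
#' @param sigma Scalar atrophy-coupling parameter (dimensionless).
#' @param atrophy An [atrophy_map()] or numeric loading vector.
#' @param j_min Positive floor for the modulated weights, nA.
#' @return A [fic_vector()] with fields `J0` (baseline) and `J` (modulated).
#' @export
modulate_fic <- function(fic, sigma, atrophy, j_min = 0.01) {
  J0 <- as_fic_j(fic, baseline = TRUE)
  alpha <- as_atrophy_alpha(atrophy)
  if (length(alpha) != length(J0))
    stop("atrophy map length (", length(alpha),
         ") does not match FIC length (", length(J0), ")")
  J <- J0 * (1 + sigma * alpha)
  if (any(J < j_min)) {
    warning(sum(J < j_min), " modulated FIC weight(s) floored at ",
            j_min, " nA")
    J <- pmax(J, j_min)
  }
  fic_vector(J0 = J0, J = J)
}

#' Integrate the dynamic mean field model
#'
#' Euler-Maruyama integration of the gating equations with uncorrelated
#' Gaussian noise per node and population; gatings are clipped to `[0,1]`
#' after every step and the burn-in transient is discarded.
#'
#' @param params A [dmf_params()] object (carries `dt`, `t_total`, `t_burn`).
#' @param connectome A [structural_connectome()] or matrix.
#' @param fic A [fic_vector()] or numeric vector of effective weights `J_n`.
#' @param seed Integer seed; fixes the noise stream.
#' @param store_rates,store_gating Whether to keep the excitatory rate /
#'   gating time series (mean rates are always computed at full resolution).
#' @param store_every Keep every k-th post-burn sample in the stored series.
#' @param init Optional list with elements `S_E` and `S_I` giving the
#'   initial gating state (defaults to 0.1 everywhere). Warm starts are
#'   used by the FIC calibration to track the balanced branch.
#' @return A `dmf_simulation` object with `mean_rate` (Hz per region),
#'   `r_E_series` and optionally `S_E_series` (time x region matrices at
#'   resolution `dt * store_every`), `dt`, and `seed`.
#' @export
dmf_simulate <- function(params, connectome, fic, seed = 1L,
                         store_rates = TRUE, store_gating = FALSE,
                         store_every = 1L, init = NULL) {
  C <- as_connectome_matrix(connectome)
  J <- as_fic_j(fic)
  out <- with_seed(seed, dmf_integrate_cpp(C, J, unclass(params),
                                           store_rates = store_rates,
                                           store_gating = store_gating,
                                           store_every = as.integer(store_every),
                                           S_E0 = init$S_E, S_I0 = init$S_I))
  structure(list(mean_rate = out$mean_rate,
                 r_E_series = out$r_E_series,
                 S_E_series = out$S_E_series,
                 n_kept_steps = out$n_kept_steps,
                 final_state = list(S_E = out$S_E_final, S_I = out$S_I_final),
                 dt = params$dt * store_every,
                 params = params, seed = as.integer(seed)),
            class = "dmf_simulation")
}

#' @export
print.dmf_simulation <- function(x, ...) {
  cat("<dmf_simulation> ", length(x$mean_rate), " regions, ",
      x$n_kept_steps, " kept steps\n", sep = "")
  cat("  mean excitatory rate: ",
      sprintf("%.2f-%.2f Hz", min(x$mean_rate), max(x$mean_rate)), "\n",
      sep = "")
  invisible(x)
}

#' Calibrate baseline feedback inhibition control
#'
#' Tunes the per-region baseline inhibitory weight `J_n^0` so that the
#' long-run mean excitatory firing rate of every node falls in a
#' physiological band (3-4 Hz). The recursion adjusts each weight in
#' proportion to the node's rate error,
#' `J_n <- max(J_n + eps * (r_n - target_rate), j_min)`, with each sweep
#' verified by a short simulation; it stops when all nodes are inside
#' `band` and within `rate_tol` of the target, or after `max_iter` sweeps
#' (then the worst node and its rate are reported in a warning).
#'
#' @param params A [dmf_params()] object. Calibration runs use `t_check`
#'   seconds of simulation after a short transient, independent of
#'   `params$t_total`.
#' @param connectome A [structural_connectome()] or matrix.
#' @param target_rate Target mean excitatory rate, Hz.
#' @param band Acceptance band for node rates, Hz.
#' @param eps Learning rate of the recursion, nA per Hz of rate error.
#' @param err_clip Symmetric cap on the rate error entering the update, Hz.
#'   Disinhibited nodes can transiently fire two orders of magnitude above
#'   the target; without the cap the fixed-gain recursion overshoots across
#'   the network's excitation cliff and limit-cycles instead of converging.
#' @param j_min Positive floor for the weights, nA.
#' @param max_iter Maximum sweeps.
#' @param t_check Duration of each verification run, s.
#' @param t_confirm Duration of the longer confirmation run required
#'   before a sweep is accepted as converged, s (skipped when
#'   `t_confirm <= t_check`).
#' @param rate_tol Additional stop tolerance on `max |r - target|`, Hz. The
#'   default only requires the band; small values refine towards the target
#'   (useful for noise-free calibration).
#' @param seed Seed for the verification-run noise (sweep k uses a child
#'   seed derived from it).
#' @return A [fic_vector()] with attributes `converged`, `n_iter`,
#'   `rates` (final verification rates), and `state` (final gating state;
#'   downstream simulations warm-start from it so they sample the
#'   calibrated resting attractor).
#' @export
calibrate_fic <- function(params, connectome, target_rate = 3.44,
                          band = c(3, 4), eps = 0.005, err_clip = 10,
                          j_min = 0.01, max_iter = 200, t_check = 10,
                          t_confirm = 30, rate_tol = Inf, seed = 1L) {
  C <- as_connectome_matrix(connectome)
  n <- nrow(C)
  p_check <- params
  p_check$t_total <- t_check + 2
  p_check$t_burn <- 2
  # start above the decoupled solution in proportion to node strength
  J <- 1 + 0.75 * params$G * params$J_NMDA * rowSums(C)
  p_confirm <- params
  p_confirm$t_total <- t_confirm + 2
  p_confirm$t_burn <- 2
  rates <- rep(NA_real_, n)
  converged <- FALSE
  it <- 0
  state <- NULL
  while (it < max_iter) {
    it <- it + 1
    sim <- dmf_simulate(p_check, C, J, seed = derive_seed(seed, "fic", it),
                        store_rates = FALSE, init = state)
    state <- sim$final_state
    rates <- sim$mean_rate
    in_band <- all(rates >= band[1] & rates <= band[2]) &&
      max(abs(rates - target_rate)) <= rate_tol
    if (in_band && t_confirm > t_check) {
      # confirm over a longer window before accepting: short-window rate
      # estimates can look balanced while the state is drifting
      sim <- dmf_simulate(p_confirm, C, J,
                          seed = derive_seed(seed, "fic_confirm", it),
                          store_rates = FALSE, init = state)
      state <- sim$final_state
      rates <- sim$mean_rate
      in_band <- all(rates >= band[1] & rates <= band[2]) &&
        max(abs(rates - target_rate)) <= rate_tol
    }
    if (in_band) {
      converged <- TRUE
      break
    }
    err <- pmin(pmax(rates - target_rate, -err_clip), err_clip)
    J <- pmax(J + eps * err, j_min)
  }
  if (!converged) {
    worst <- which.max(abs(rates - target_rate))
    warning(sprintf(paste0("FIC calibration did not converge after %d sweeps; ",
                           "worst node %d at %.2f Hz"), max_iter, worst,
                    rates[worst]))
  }
  out <- fic_vector(J0 = J, J = J)
  attr(out, "converged") <- converged
  attr(out, "n_iter") <- it
  attr(out, "rates") <- rates
  attr(out, "state") <- state
  out
}
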