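#' Dynamic mean field model parameters
#'
#' Scalar constants of the two-population (excitatory/inhibitory) neural-mass
#' equations plus integration settings. Defaults are the standard values of
#' the reduced Wong-Wang model family: external current `I0 = 0.382` nA
#' scaled by `W_E = 1` (excitatory) and `W_I = 0.7` (inhibitory), local
#' excitatory recurrence `W_plus = 1.4`, NMDA coupling current
#' `J_NMDA = 0.15` nA, global coupling `G = 2.5`, f-I curve conductances
#' `g_E = g_I = 310` nC^-1 with thresholds `I_thr_E = 0.403` and
#' `I_thr_I = 0.288` nA and shape constants `d_E = 0.16`, `d_I = 0.087`,
#' synaptic time constants `tau_NMDA = 0.1` s and `tau_GABA = 0.01` s,
#' kinetic constant `gamma = 0.641`, and noise amplitude
#' `sigma_g = 0.01` nA.
#'
#' The fitted atrophy-coupling parameter is always called `sigma` elsewhere
#' in the package and is never aliased with the noise amplitude `sigma_g`.
#'
#' @param G Global coupling scaling the long-range excitatory input.
#' @param sigma_g Amplitude of the uncorrelated Gaussian noise, nA.
#' @param dt Integration step, s. Must be much smaller than `tau_GABA`.
#' @param t_total Simulated duration, s.
#' @param t_burn Discarded initial transient, s.
#' @param ... Overrides for any other constant listed above.
#' @return An object of class `dmf_params` (named list).
#' @examples
#' p <- dmf_params(t_total = 20)
#' p$G
#' @export
dmf_params <- function(G = 2.5, sigma_g = 0.01, dt = 1e-3,
                       t_total = 120, t_burn = 10, ...) {
  p <- list(
    I0 = 0.382, W_E = 1, W_I = 0.7, W_plus = 1.4, J_NMDA = 0.15,
    G = G, g_E = 310, g_I = 310, I_thr_E = 0.403, I_thr_I = 0.288,
    d_E = 0.16, d_I = 0.087, tau_NMDA = 0.1, tau_GABA = 0.01,
    gamma = 0.641, sigma_g = sigma_g, dt = dt,
    t_total = t_total, t_burn = t_burn
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown dmf parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(
    p$tau_NMDA > 0, p$tau_GABA > 0, p$dt > 0, p$t_total > p$t_burn,
    p$t_burn >= 0, p$dt <= p$tau_GABA / 5
  )
  structure(p, class = "dmf_params")
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Standard constants of the hemodynamic model converting neural activity
#' into BOLD signal: signal decay `kappa = 0.65` s^-1, flow-dependent
#' elimination `gamma_f = 0.41` s^-1, transit time `tau = 0.98` s, Grubb
#' exponent `alpha_g = 0.32`, resting oxygen extraction `rho = 0.34`,
#' resting venous volume `V0 = 0.02`, and output sampling interval
#' `TR = 2` s.
#'
#' @param TR Output sampling interval, s.
#' @param ... Overrides for any constant above.
#' @return An object of class `bw_params` (named list).
#' @export
bw_params <- function(TR = 2, ...) {
  p <- list(kappa = 0.65, gamma_f = 0.41, tau = 0.98, alpha_g = 0.32,
            rho = 0.34, V0 = 0.02, TR = TR)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown BW parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(all(unlist(p) > 0), p$alpha_g < 1, p$rho < 1)
  structure(p, class = "bw_params")
}

#' SSIM comparison settings
#'
#' Stabilization constants and sliding-window size for the structural
#' similarity index used to compare functional connectivity matrices.
#' The constants are used exactly as they appear in the similarity formula
#' (`c1 = 0.01`, `c2 = 0.03`, `c3 = 0.015`), not the luminance-scaled
#' variants of the image-processing literature.
#'
#' @param window Odd side length of the square sliding window.
#' @param c1,c2,c3 Stabilization constants of the three formula factors.
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(window = 7, c1 = 0.01, c2 = 0.03, c3 = 0.015) {
  stopifnot(window >= 1, window %% 2 == 1, c1 > 0, c2 > 0, c3 > 0)
  structure(list(window = as.integer(window), c1 = c1, c2 = c2, c3 = c3),
            class = "ssim_config")
}

#' Settings for Bayesian optimization of the atrophy-coupling parameter
#'
#' @param sigma_bounds Search interval for sigma. The default covers the
#'   control value 0 and strong inhibition loss while the post-modulation
#'   floor keeps every FIC weight positive.
#' @param n_calls Total objective evaluations per repetition (including the
#'   initial design).
#' @param n_init Size of the initial space-filling design.
#' @param n_sim_per_eval Simulations averaged per objective evaluation.
#' @param n_repetitions Independent optimization repetitions whose optima
#'   are averaged.
#' @param grid_n Resolution of the acquisition/posterior grid.
#' @param seed Master seed; all repetition and simulation seeds derive
#'   from it.
#' @param sim_seeds Optional explicit simulation seed vector shared by
#'   every repetition and every sigma evaluation (overrides
#'   `n_sim_per_eval`). Pairing these with the seed a synthetic target
#'   was generated from gives the matched-noise recovery protocol: the
#'   objective is then an exact self-match (zero) at the planted
#'   coupling, so the experiment isolates the optimizer from the FC
#'   sampling noise of finite scans.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(sigma_bounds = c(-1.5, 0.5), n_calls = 40,
                       n_init = 10, n_sim_per_eval = 3, n_repetitions = 100,
                       grid_n = 401, seed = 1L, sim_seeds = NULL) {
  stopifnot(length(sigma_bounds) == 2, all(is.finite(sigma_bounds)),
            sigma_bounds[1] < sigma_bounds[2],
            n_calls >= 1, n_init >= 2, n_calls >= n_init,
            n_sim_per_eval >= 1, n_repetitions >= 1, grid_n >= 10)
  structure(list(sigma_bounds = sigma_bounds, n_calls = as.integer(n_calls),
                 n_init = as.integer(n_init),
                 n_sim_per_eval = as.integer(n_sim_per_eval),
                 n_repetitions = as.integer(n_repetitions),
                 grid_n = as.integer(grid_n), seed = as.integer(seed),
                 sim_seeds = if (!is.null(sim_seeds)) as.integer(sim_seeds)),
            class = "fit_config")
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed: mixes a parent seed with a stage tag and an
# index, staying within the 32-bit integer range.
derive_seed <- function(seed, stage, k = 0L) {
  tag <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + tag * 1009 + k * 7919) %% 2147483647)
}
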