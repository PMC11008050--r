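#' Simulate a functional connectivity matrix at a given coupling
#'
#' One forward pass of the pipeline: modulate the calibrated baseline FIC
#' by `sigma` and the atrophy map, integrate the neural model, transform
#' to BOLD, and correlate. When the supplied FIC carries the calibration
#' end state (attribute `state`), simulations warm-start from it so they
#' sample the calibrated resting attractor rather than the integrator's
#' arbitrary cold-start basin.
#'
#' @param sigma Atrophy-coupling parameter.
#' @param connectome A [structural_connectome()].
#' @param atrophy An [atrophy_map()].
#' @param fic Calibrated baseline [fic_vector()].
#' @param params A [dmf_params()].
#' @param bw A [bw_params()].
#' @param seed Simulation seed.
#' @param neural_dt Resolution at which the excitatory rate series is
#'   stored and fed to the hemodynamics, s. The vascular response
#'   integrates over seconds, so 10 ms is ample; must be a multiple of
#'   `params$dt`.
#' @return An [fc_matrix()].
#' @export
simulate_fc <- function(sigma, connectome, atrophy, fic,
                        params = dmf_params(), bw = bw_params(), seed = 1L,
                        neural_dt = 0.01) {
  mod <- suppressWarnings(modulate_fic(fic, sigma, atrophy))
  every <- max(1L, as.integer(round(neural_dt / params$dt)))
  sim <- dmf_simulate(params, connectome, mod, seed = seed,
                      store_every = every, init = attr(fic, "state"))
  compute_fc(bold_from_rate(sim$r_E_series, bw, dt = sim$dt))
}

#' Model-fit objective at a given coupling
#'
#' The quantity minimized when fitting sigma: the mean, over
#' `n_sim_per_eval` independent simulation seeds, of the SSIM distance
#' `1 - SSIM` between the simulated FC at that sigma and the target FC.
#' The baseline FIC is calibrated once (at sigma = 0) and reused across
#' evaluations; it is not recalibrated per sigma, which would absorb the
#' atrophy effect being fitted. The evaluation is deterministic given
#' `(sigma, seeds)`.
#'
#' @param sigma Coupling value to evaluate.
#' @param target_fc Target [fc_matrix()].
#' @param connectome,atrophy,fic,params,bw As in [simulate_fc()].
#' @param seeds Integer vector of simulation seeds averaged over.
#' @param ssim_cfg An [ssim_config()].
#' @return Mean dissimilarity (scalar in `[0, 2]`).
#' @export
dmf_objective <- function(sigma, target_fc, connectome, atrophy, fic,
                          params = dmf_params(), bw = bw_params(),
                          seeds = 1L, ssim_cfg = ssim_config()) {
  vals <- vapply(seeds, function(s) {
    fc <- simulate_fc(sigma, connectome, atrophy, fic, params, bw, seed = s)
    fc_distance(fc, target_fc, ssim_cfg)
  }, numeric(1))
  mean(vals)
}

# Gaussian-process posterior (squared-exponential kernel, fixed
# data-scaled hyperparameters) evaluated on a grid. Returns mean and sd.
gp_posterior <- function(x, y, grid, lengthscale, nugget) {
  y0 <- mean(y)
  yc <- y - y0
  sf2 <- max(var(y), 1e-10)
  k <- function(a, b)
    sf2 * exp(-0.5 * outer(a, b, "-")^2 / lengthscale^2)
  K <- k(x, x) + diag(nugget * sf2 + 1e-10, length(x))
  Ks <- k(grid, x)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  mu <- y0 + drop(Ks %*% alpha)
  s2 <- pmax(sf2 - colSums(forwardsolve(t(L), t(Ks))^2), 0)
  list(mu = mu, sd = sqrt(s2))
}

# Expected improvement (minimization) of a GP posterior over a grid.
expected_improvement <- function(post, best) {
  z <- (best - post$mu) / pmax(post$sd, 1e-12)
  ei <- (best - post$mu) * pnorm(z) + post$sd * dnorm(z)
  ei[post$sd < 1e-12] <- 0
  ei
}

#' Fit the atrophy-coupling parameter to a target FC
#'
#' Minimizes the SSIM distance between simulated and target FC over
#' sigma with Bayesian optimization: a Gaussian-process surrogate
#' (squared-exponential kernel) with expected-improvement acquisition over
#' `cfg$sigma_bounds`, seeded from a space-filling initial design that
#' always includes both bounds and 0. Each repetition uses its own
#' simulation seeds (common random numbers across sigma values within a
#' repetition, so the objective is deterministic per repetition), and the
#' returned estimate per repetition is the better of the posterior-mean
#' minimizer and the best evaluated point. Repetition optima are averaged
#' into `sigma_mean`.
#'
#' @param target_fc Target [fc_matrix()].
#' @param connectome,atrophy,fic,params,bw As in [simulate_fc()].
#' @param cfg A [fit_config()].
#' @param ssim_cfg An [ssim_config()].
#' @return A `fic_fit` object: `per_rep` tibble (repetition, sigma_hat,
#'   objective), `sigma_mean`, `trace` (list of per-repetition evaluation
#'   tibbles), `config`.
#' @export
fit_sigma <- function(target_fc, connectome, atrophy, fic,
                      params = dmf_params(), bw = bw_params(),
                      cfg = fit_config(), ssim_cfg = ssim_config()) {
  lb <- cfg$sigma_bounds[1]
  ub <- cfg$sigma_bounds[2]
  grid <- seq(lb, ub, length.out = cfg$grid_n)
  ell <- 0.25 * (ub - lb)

  one_rep <- function(rep_i) {
    rep_seed <- derive_seed(cfg$seed, "fit_rep", rep_i)
    sim_seeds <- cfg$sim_seeds %||%
      derive_seed(rep_seed, "sim", seq_len(cfg$n_sim_per_eval))
    obj <- function(s) dmf_objective(s, target_fc, connectome, atrophy, fic,
                                     params, bw, seeds = sim_seeds,
                                     ssim_cfg = ssim_cfg)
    # initial design: bounds, control value, low-discrepancy interior
    init <- unique(c(lb, ub, if (lb < 0 && ub > 0) 0))
    n_fill <- max(0, cfg$n_init - length(init))
    if (n_fill > 0) {
      u <- with_seed(derive_seed(rep_seed, "init"),
                     (seq_len(n_fill) - runif(1)) / n_fill)
      init <- c(init, lb + u * (ub - lb))
    }
    x <- init
    y <- vapply(x, obj, numeric(1))
    while (length(x) < cfg$n_calls) {
      post <- gp_posterior(x, y, grid, ell, nugget = 1e-4)
      ei <- expected_improvement(post, min(y))
      # avoid re-evaluating an existing point
      ei[vapply(grid, function(g) any(abs(g - x) < 1e-9), logical(1))] <- -Inf
      x_new <- grid[which.max(ei)]
      x <- c(x, x_new)
      y <- c(y, obj(x_new))
    }
    post <- gp_posterior(x, y, grid, ell, nugget = 1e-4)
    s_pm <- grid[which.min(post$mu)]
    y_pm <- obj(s_pm)
    if (y_pm <= min(y)) {
      s_hat <- s_pm; y_hat <- y_pm
    } else {
      s_hat <- x[which.min(y)]; y_hat <- min(y)
    }
    list(sigma_hat = s_hat, objective = y_hat,
         trace = tibble::tibble(rep = rep_i, sigma = c(x, s_pm),
                                objective = c(y, y_pm)))
  }

  reps <- lapply(seq_len(cfg$n_repetitions), one_rep)
  per_rep <- tibble::tibble(
    rep = seq_len(cfg$n_repetitions),
    sigma_hat = vapply(reps, `[[`, numeric(1), "sigma_hat"),
    objective = vapply(reps, `[[`, numeric(1), "objective")
  )
  structure(list(per_rep = per_rep,
                 sigma_mean = mean(per_rep$sigma_hat),
                 objective_mean = mean(per_rep$objective),
                 trace = lapply(reps, `[[`, "trace"),
                 config = cfg),
            class = "fic_fit")
}

#' @export
print.fic_fit <- function(x, ...) {
  cat(sprintf("<fic_fit> %d repetition(s)\n", nrow(x$per_rep)))
  cat(sprintf("  sigma_hat: mean %.3f (sd %.3f), objective mean %.3f\n",
              x$sigma_mean, sd(x$per_rep$sigma_hat), x$objective_mean))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-repetition estimates of a sigma fit
#'
#' @param x A `fic_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per repetition: `rep`, `sigma_hat`,
#'   `objective`.
#' @export
tidy.fic_fit <- function(x, ...) x$per_rep

#' One-row summary of a sigma fit
#'
#' @param x A `fic_fit` object.
#' @param ... Unused.
#' @return Tibble with `sigma_mean`, `sigma_sd`, `objective_mean`,
#'   `n_repetitions`, `n_calls`.
#' @export
glance.fic_fit <- function(x, ...) {
  tibble::tibble(sigma_mean = x$sigma_mean,
                 sigma_sd = sd(x$per_rep$sigma_hat),
                 objective_mean = x$objective_mean,
                 n_repetitions = nrow(x$per_rep),
                 n_calls = x$config$n_calls)
}

#' Atrophy-specificity experiment
#'
#' Fits sigma against the same FC target under several atrophy maps
#' (typically the correct map, a map switched from another cohort, and a
#' randomly shuffled map) and compares the achieved goodness-of-fit
#' distributions with Welch two-sample tests, Benjamini-Hochberg corrected
#' across the comparison family. With meaningful atrophy the correct map
#' is expected to achieve the lowest SSIM distance.
#'
#' @param target_fc Target [fc_matrix()].
#' @param connectome A [structural_connectome()].
#' @param maps Named list of [atrophy_map()] objects (e.g. `correct`,
#'   `switched`, `shuffled`).
#' @param fic,params,bw,cfg,ssim_cfg As in [fit_sigma()].
#' @return An `atrophy_specificity` object: `fits` (named list of
#'   `fic_fit`), `objectives` (long tibble), `tests` (pairwise
#'   comparisons with `p_raw`/`p_adj`), `medians`.
#' @export
atrophy_specificity <- function(target_fc, connectome, maps, fic,
                                params = dmf_params(), bw = bw_params(),
                                cfg = fit_config(),
                                ssim_cfg = ssim_config()) {
  stopifnot(is.list(maps), length(maps) >= 2, !is.null(names(maps)))
  fits <- lapply(maps, function(m)
    fit_sigma(target_fc, connectome, m, fic, params, bw, cfg, ssim_cfg))
  objectives <- dplyr::bind_rows(lapply(names(fits), function(nm)
    tibble::tibble(map = nm, objective = fits[[nm]]$per_rep$objective)))
  samples <- split(objectives$objective, objectives$map)[names(maps)]
  pairs <- utils::combn(names(maps), 2, simplify = FALSE)
  tests <- ttests_fdr(samples, comparisons = pairs)
  medians <- vapply(samples, median, numeric(1))
  structure(list(fits = fits, objectives = objectives, tests = tests,
                 medians = medians),
            class = "atrophy_specificity")
}

#' @export
print.atrophy_specificity <- function(x, ...) {
  cat("<atrophy_specificity>\n  median 1-SSIM by map:\n")
  for (nm in names(x$medians))
    cat(sprintf("    %-10s %.4f\n", nm, x$medians[[nm]]))
  print(x$tests)
  invisible(x)
}

#' Shuffled copy of an atrophy map
#'
#' Seeded random permutation of the regional loadings, used as the
#' spatially meaningless control in the specificity experiment.
#'
#' @param atrophy An [atrophy_map()].
#' @param seed Permutation seed.
#' @param perm Optional explicit permutation (overrides `seed`).
#' @return An [atrophy_map()].
#' @export
shuffle_atrophy <- function(atrophy, seed = 1L, perm = NULL) {
  alpha <- as_atrophy_alpha(atrophy)
  if (is.null(perm))
    perm <- with_seed(derive_seed(seed, "shuffle"),
                      sample.int(length(alpha)))
  atrophy_map(alpha[perm], group = "shuffled")
}
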