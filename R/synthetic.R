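#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study: a DTI-like structural
#' connectome, group atrophy maps with spatially localized loading,
#' "empirical" FC targets produced by the forward model at a planted
#' coupling `sigma_true`, and cohorts carrying a planted linear
#' sigma-duration relation with a gender-specific slope offset.
#'
#' @param n_regions Number of regions (default 90, an AAL-like whole-brain
#'   parcellation).
#' @param connectome_density Fraction of possible edges present, in (0, 1].
#' @param atrophy_focus Integer indices of the regions carrying atrophy in
#'   patient maps (defaults to the first quarter of the regions).
#' @param atrophy_strength Mean loading (w-score magnitude) on the focus.
#' @param sigma_true Planted atrophy-coupling for patient groups
#'   (dimensionless; negative means inhibition loss).
#' @param ywd_slope Planted change of sigma per year with disease.
#' @param gender_effect Additive slope offset applied to female subjects.
#' @param noise_sd Observation noise added to off-diagonal FC entries.
#' @param seed Master seed; every generator output is a deterministic
#'   function of it.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_regions = 90, connectome_density = 0.3,
                         atrophy_focus = NULL, atrophy_strength = 0.5,
                         sigma_true = -0.3, ywd_slope = -0.02,
                         gender_effect = -0.01, noise_sd = 0.02,
                         seed = 1L) {
  stopifnot(n_regions >= 2, connectome_density > 0, connectome_density <= 1,
            atrophy_strength >= 0, noise_sd >= 0)
  if (is.null(atrophy_focus))
    atrophy_focus <- seq_len(max(1L, floor(n_regions / 4)))
  atrophy_focus <- as.integer(atrophy_focus)
  stopifnot(all(atrophy_focus >= 1), all(atrophy_focus <= n_regions))
  structure(list(n_regions = as.integer(n_regions),
                 connectome_density = connectome_density,
                 atrophy_focus = atrophy_focus,
                 atrophy_strength = atrophy_strength,
                 sigma_true = sigma_true, ywd_slope = ywd_slope,
                 gender_effect = gender_effect, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a DTI-like structural connectome
#'
#' Builds a connected weighted graph emulating a tractography-derived
#' coupling matrix: an Erdős–Rényi backbone at the requested density
#' (augmented by a random spanning tree so the graph stays connected),
#' distance-decaying heavy-tailed (log-normal) weights, and a modular
#' overlay boosting within-community edges. The matrix is symmetric,
#' nonnegative, zero-diagonal, and rescaled so its maximum entry equals
#' 0.2 — the normalization under which a global coupling of `G = 2.5`
#' keeps the model in its physiological operating regime. The log-normal
#' weight spread mirrors empirical fiber-count distributions and keeps the
#' spectral radius near the maximum entry, which is what makes the
#' calibrated balanced state dynamically stable at that coupling.
#'
#' @param cfg A [synth_config()].
#' @return A [structural_connectome()]. Achieved edge density is within
#'   10\% of `cfg$connectome_density` (an error is raised if the density
#'   is too low to keep `n` regions connected).
#' @export
gen_connectome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_regions
  n_pairs <- n * (n - 1) / 2
  n_edges <- round(cfg$connectome_density * n_pairs)
  if (n_edges < n - 1)
    stop("requested density ", cfg$connectome_density, " leaves fewer edges (",
         n_edges, ") than the ", n - 1, " needed to keep ", n,
         " regions connected")
  with_seed(derive_seed(cfg$seed, "connectome"), {
    # ring coordinates give a simple distance structure
    theta <- 2 * pi * (seq_len(n) - 1) / n
    xy <- cbind(cos(theta), sin(theta))
    D <- as.matrix(stats::dist(xy))
    module <- rep(seq_len(5), each = ceiling(n / 5), length.out = n)

    iu <- which(upper.tri(D))
    # random spanning tree over a random permutation keeps connectivity
    perm <- sample.int(n)
    tree <- cbind(perm[-n], perm[-1])
    tree_idx <- (pmax(tree[, 1], tree[, 2]) - 1) * n +
      pmin(tree[, 1], tree[, 2])
    pool <- setdiff(iu, tree_idx)
    extra <- sample(pool, max(0, n_edges - length(tree_idx)))
    sel <- c(tree_idx, extra)

    C <- matrix(0, n, n)
    w <- exp(-D[sel] / 1.5) * exp(rnorm(length(sel), 0, 0.9))
    same_mod <- module[(sel - 1) %% n + 1] == module[(sel - 1) %/% n + 1]
    w[same_mod] <- w[same_mod] * 12
    C[sel] <- w
    C <- C + t(C)
    C <- C / max(C) * 0.2
    # sharpen the weight tail until the spectral radius sits just above
    # the maximum entry: the balanced state at G = 2.5 is only stable in
    # that regime, and raw draws occasionally land above it
    C0 <- C / 0.2
    lam <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    p_exp <- 1
    while (lam > 0.22 && p_exp < 6) {
      p_exp <- p_exp + 0.1
      C <- C0^p_exp * 0.2
      lam <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    }
    structural_connectome(C)
  })
}

#' Generate a group atrophy map
#'
#' Healthy controls define the w-score reference, so their map is exactly
#' zero. Patient maps carry loadings centred on `atrophy_strength` over
#' the focus regions (with modest spread) and near-zero residual loadings
#' elsewhere, stored in the positive-means-more-atrophy convention.
#'
#' @param cfg A [synth_config()].
#' @param group `"HC"`, `"AD"`, or `"bvFTD"`. The two patient groups use
#'   complementary halves of `cfg$atrophy_focus` plus a shared core, so
#'   their maps overlap only partially.
#' @param focus Optional explicit focus indices overriding the
#'   group-specific split.
#' @return An [atrophy_map()].
#' @export
gen_atrophy_map <- function(cfg, group = c("HC", "AD", "bvFTD"),
                            focus = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  group <- match.arg(group)
  n <- cfg$n_regions
  if (group == "HC")
    return(atrophy_map(rep(0, n), group = "HC"))
  if (is.null(focus)) {
    f <- cfg$atrophy_focus
    half <- seq_len(ceiling(length(f) / 2))
    focus <- if (group == "AD") f[half] else f[-half[-length(half)]]
  }
  with_seed(derive_seed(cfg$seed, paste0("atrophy_", group)), {
    alpha <- abs(rnorm(n, 0, 0.03))
    alpha[focus] <- pmax(rnorm(length(focus), cfg$atrophy_strength,
                               0.1 * max(cfg$atrophy_strength, 1e-8)), 0)
    atrophy_map(alpha, group = group)
  })
}

#' Generate a synthetic cohort table
#'
#' Builds a subject table crossed over group (HC, AD, bvFTD), site (HIC,
#' Latam), and gender (F, M). Healthy controls have zero years-with-disease
#' and zero planted coupling; each patient's hidden ground truth follows
#' `sigma_true(subject) = sigma0 + ywd_slope * ywd`, with an additional
#' `gender_effect * ywd` for female subjects, where `sigma0 =
#' cfg$sigma_true` is the group baseline at diagnosis. Patient durations
#' are drawn uniformly on 1 to 12 years.
#'
#' @param cfg A [synth_config()].
#' @param n_per_cell Subjects per group x site x gender cell; either a
#'   single count or a named vector with entries `HC`, `AD`, `bvFTD`
#'   (per-group counts, split over site x gender cells).
#' @return A tibble with columns `subject_id`, `group`, `site`, `gender`,
#'   `ywd`, and `sigma_true`.
#' @export
gen_cohort <- function(cfg, n_per_cell = 5) {
  stopifnot(inherits(cfg, "synth_config"), all(n_per_cell >= 1))
  groups <- c("HC", "AD", "bvFTD")
  if (!is.null(names(n_per_cell))) {
    stopifnot(all(groups %in% names(n_per_cell)))
    counts <- n_per_cell[groups]
  } else {
    counts <- setNames(rep(n_per_cell[1], 3), groups)
  }
  with_seed(derive_seed(cfg$seed, "cohort"), {
    rows <- lapply(groups, function(g) {
      cells <- expand.grid(site = c("HIC", "Latam"), gender = c("F", "M"),
                           stringsAsFactors = FALSE)
      cells <- cells[rep(seq_len(nrow(cells)), each = counts[[g]]), ]
      k <- nrow(cells)
      ywd <- if (g == "HC") rep(0, k) else runif(k, 1, 12)
      slope <- cfg$ywd_slope + ifelse(cells$gender == "F",
                                      cfg$gender_effect, 0)
      sigma <- if (g == "HC") rep(0, k) else cfg$sigma_true + slope * ywd
      tibble::tibble(group = g, site = cells$site, gender = cells$gender,
                     ywd = ywd, sigma_true = sigma)
    })
    out <- dplyr::bind_rows(rows)
    out$subject_id <- sprintf("S%04d", seq_len(nrow(out)))
    out[, c("subject_id", "group", "site", "gender", "ywd", "sigma_true")]
  })
}

#' Generate a synthetic "empirical" FC target
#'
#' Runs the full forward model at a planted coupling: baseline FIC
#' calibration (unless a calibrated [fic_vector()] is supplied), atrophy
#' modulation at `sigma_true`, stochastic integration, Balloon-Windkessel
#' BOLD transformation, Pearson FC — then adds observation noise of
#' standard deviation `cfg$noise_sd` to the off-diagonal entries
#' (resymmetrized; diagonal reset to 1).
#'
#' @param cfg A [synth_config()].
#' @param connectome A [structural_connectome()].
#' @param atrophy An [atrophy_map()].
#' @param sigma_true Planted coupling (defaults to `cfg$sigma_true`).
#' @param params A [dmf_params()].
#' @param bw A [bw_params()].
#' @param fic Optional pre-calibrated baseline [fic_vector()]; when absent
#'   the baseline is calibrated from scratch.
#' @param seed Seed for the simulation noise and the observation noise.
#' @return An [fc_matrix()] carrying the simulation seed it was generated
#'   from as attribute `sim_seed` (see [fit_config()]'s `sim_seeds`).
#' @export
gen_empirical_fc <- function(cfg, connectome, atrophy,
                             sigma_true = cfg$sigma_true,
                             params = dmf_params(), bw = bw_params(),
                             fic = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(fic))
    fic <- calibrate_fic(params, connectome,
                         seed = derive_seed(seed, "fic_target"))
  sim_seed <- derive_seed(seed, "fc_target")
  fc <- simulate_fc(sigma_true, connectome, atrophy, fic, params, bw,
                    seed = sim_seed)
  v <- as_fc_values(fc)
  if (cfg$noise_sd > 0) {
    v <- with_seed(derive_seed(seed, "fc_noise"), {
      E <- matrix(rnorm(length(v), 0, cfg$noise_sd), nrow(v))
      E <- (E + t(E)) / 2
      v + E
    })
    v <- pmin(pmax(v, -1), 1)
    diag(v) <- 1
  }
  out <- fc_matrix(v)
  # record the simulation seed so recovery experiments can pair the
  # fitter's simulations with the target's noise realization
  attr(out, "sim_seed") <- sim_seed
  out
}

#' Synthetic resting-state network masks
#'
#' Reads the packaged synthetic RSN membership fixture: five networks
#' (VN, SN, MN, EXEC, DMN) as region-index sets over a 90-region
#' parcellation. These are synthetic stand-ins — real atlas-derived masks
#' can be supplied in the same two-column text format (network, 0-based
#' region index) via [read_rsn_masks()].
#'
#' @param path Optional path to a mask file; defaults to the packaged
#'   synthetic fixture.
#' @return Named list of integer vectors (1-based region indices).
#' @export
gen_rsn_masks <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rsn_masks_synthetic.txt",
                        package = "dmfic")
  read_rsn_masks(path)
}
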