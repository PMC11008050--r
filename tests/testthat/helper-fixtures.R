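# Shared fixtures, built once per test run and cached. Building the
# 90-region calibrated model takes ~10 s; every test that needs it reuses
# the same object.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small 24-region model for unit tests.
small_model <- function() {
  fixture("small_model", function() {
    cfg <- synth_config(n_regions = 24, seed = 5, noise_sd = 0)
    sc <- gen_connectome(cfg)
    fic <- calibrate_fic(dmf_params(), sc, seed = 2)
    list(cfg = cfg, sc = sc, fic = fic)
  })
}

# Full-size 90-region calibrated model for acceptance-level tests.
full_model <- function() {
  fixture("full_model", function() {
    cfg <- synth_config(seed = 3, noise_sd = 0)
    sc <- gen_connectome(cfg)
    fic <- calibrate_fic(dmf_params(), sc, seed = 11)
    list(cfg = cfg, sc = sc, fic = fic)
  })
}

# Breadth-first search connectivity check on a weighted adjacency matrix.
is_connected <- function(C) {
  n <- nrow(C)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(C[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Deterministic fixed point of the noise-free decoupled node (G = 0) for a
# given FIC weight: damped fixed-point iteration on the gating equations.
decoupled_rate <- function(J, params = dmf_params(G = 0, sigma_g = 0)) {
  S_E <- 0.1
  S_I <- 0.05
  for (i in 1:5000) {
    I_E <- params$W_E * params$I0 + params$W_plus * params$J_NMDA * S_E -
      J * S_I
    I_I <- params$W_I * params$I0 + params$J_NMDA * S_E - S_I
    r_E <- transfer_rate(I_E, "E", params)
    r_I <- transfer_rate(I_I, "I", params)
    g <- params$gamma * params$tau_NMDA * r_E
    S_E <- 0.9 * S_E + 0.1 * g / (1 + g)
    S_I <- 0.9 * S_I + 0.1 * params$tau_GABA * r_I
  }
  I_E <- params$W_E * params$I0 + params$W_plus * params$J_NMDA * S_E -
    J * S_I
  transfer_rate(I_E, "E", params)
}
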