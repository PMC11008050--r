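test_that("transfer function hits its analytic limits", {
  p <- dmf_params()
  # removable singularity at the threshold current: limit 1/d
  expect_equal(transfer_rate(0.403, "E", p), 1 / 0.16)
  expect_equal(transfer_rate(0.288, "I", p), 1 / 0.087, tolerance = 1e-9)
  # direct scalar evaluation away from the threshold
  y <- 310 * (0.5 - 0.403)
  expect_equal(transfer_rate(0.5, "E", p), y / (1 - exp(-0.16 * y)))
  expect_equal(transfer_rate(0.5, "E", p), 30.3168, tolerance = 1e-4)
  # exponential dominance far below threshold
  expect_lt(transfer_rate(-10, "E", p), 1e-10)
  expect_gte(transfer_rate(-10, "E", p), 0)
})

test_that("transfer function is continuous and strictly increasing across the threshold", {
  p <- dmf_params()
  I <- seq(0.3, 0.5, length.out = 2001)  # spans I_thr_E = 0.403
  r <- transfer_rate(I, "E", p)
  expect_true(all(diff(r) > 0))
  expect_true(all(is.finite(r)))
  expect_lt(max(abs(diff(r))), 0.1)  # no jump at the singularity
})

test_that("currents match a naive per-afferent loop oracle", {
  p <- dmf_params()
  set.seed(42)
  for (k in 1:5) {
    n <- 5
    A <- matrix(runif(n * n), n, n)
    C <- (A + t(A)) / 2
    diag(C) <- 0
    S_E <- runif(n)
    S_I <- runif(n)
    J <- runif(n, 0.5, 2)
    got <- dmf_currents(S_E, S_I, C, J, p)
    # independently coded double loop over afferents
    I_E <- I_I <- numeric(n)
    for (i in seq_len(n)) {
      lr <- 0
      for (j in seq_len(n)) lr <- lr + C[i, j] * S_E[j]
      I_E[i] <- p$W_E * p$I0 + p$W_plus * p$J_NMDA * S_E[i] +
        p$G * p$J_NMDA * lr - J[i] * S_I[i]
      I_I[i] <- p$W_I * p$I0 + p$J_NMDA * S_E[i] - S_I[i]
    }
    expect_equal(got$I_E, I_E, tolerance = 1e-12)
    expect_equal(got$I_I, I_I, tolerance = 1e-12)
  }
})

test_that("currents reduce to external drive and decouple at G = 0", {
  p <- dmf_params()
  C <- matrix(0.1, 3, 3); diag(C) <- 0
  out <- dmf_currents(rep(0, 3), rep(0, 3), C, rep(1, 3), p)
  expect_equal(out$I_E, rep(0.382, 3))
  expect_equal(out$I_I, rep(0.7 * 0.382, 3))

  p0 <- dmf_params(G = 0)
  s1 <- dmf_currents(c(0.1, 0.9, 0.1), rep(0.1, 3), C, rep(1, 3), p0)
  s2 <- dmf_currents(c(0.1, 0.2, 0.1), rep(0.1, 3), C, rep(1, 3), p0)
  expect_equal(s1$I_E[1], s2$I_E[1])  # other regions' gating is irrelevant
})

test_that("integrator respects gating bounds and is seed-deterministic", {
  m <- small_model()
  p <- dmf_params(t_total = 8, t_burn = 1)
  s1 <- dmf_simulate(p, m$sc, m$fic, seed = 7, store_gating = TRUE)
  s2 <- dmf_simulate(p, m$sc, m$fic, seed = 7, store_gating = TRUE)
  expect_identical(s1$r_E_series, s2$r_E_series)
  expect_true(all(s1$S_E_series >= 0 & s1$S_E_series <= 1))
  expect_true(all(s1$mean_rate >= 0))
  expect_equal(nrow(s1$r_E_series), round((8 - 1) / p$dt))
  s3 <- dmf_simulate(p, m$sc, m$fic, seed = 8)
  expect_false(identical(s1$r_E_series, s3$r_E_series))
})

test_that("noise-free dynamics settle onto an equilibrium of the drift field", {
  m <- small_model()
  p <- dmf_params(sigma_g = 0, t_total = 60, t_burn = 5)
  sim <- dmf_simulate(p, m$sc, m$fic, seed = 1, store_rates = FALSE,
                      init = attr(m$fic, "state"))
  drift <- dmfic:::dmf_drift_cpp(m$sc$C, m$fic$J, unclass(p),
                                 sim$final_state$S_E, sim$final_state$S_I)
  expect_lt(sqrt(sum(drift^2)), 1e-8)
  # an equilibrium initial state stays put
  sim2 <- dmf_simulate(dmf_params(sigma_g = 0, t_total = 2, t_burn = 0),
                       m$sc, m$fic, seed = 1, init = sim$final_state)
  expect_lt(max(abs(sim2$final_state$S_E - sim$final_state$S_E)), 1e-8)
  expect_lt(diff(range(sim2$r_E_series[, 1])), 1e-8)
})

test_that("halving the integration step barely moves the mean rates", {
  m <- small_model()
  pA <- dmf_params(sigma_g = 0, t_total = 30, t_burn = 5)
  pB <- dmf_params(sigma_g = 0, t_total = 30, t_burn = 5, dt = 5e-4)
  sA <- dmf_simulate(pA, m$sc, m$fic, seed = 1, store_rates = FALSE)
  sB <- dmf_simulate(pB, m$sc, m$fic, seed = 1, store_rates = FALSE)
  expect_lt(max(abs(sA$mean_rate - sB$mean_rate) / sB$mean_rate), 0.02)
})

test_that("atrophy modulation follows J = J0 (1 + sigma alpha) with a positive floor", {
  J0 <- c(1.5, 1.0, 2.0)
  expect_equal(modulate_fic(J0, 0, c(1, 1, 1))$J, J0)
  expect_equal(modulate_fic(J0, -0.7, c(0, 0, 0))$J, J0)
  expect_equal(modulate_fic(1.5, -0.4, 0.5)$J, 1.2)
  expect_warning(out <- modulate_fic(1, -2, 1), "floored")
  expect_equal(out$J, 0.01)
  expect_identical(out$J0, 1)  # baseline untouched by modulation
})

test_that("decoupled-node calibration matches a bisection oracle", {
  C1 <- matrix(0, 1, 1)
  p <- dmf_params(G = 0, sigma_g = 0)
  # oracle: bisection on the scalar steady state (rate decreasing in J)
  lo <- 0.2; hi <- 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (decoupled_rate(mid, p) > 3.44) lo <- mid else hi <- mid
  }
  J_oracle <- (lo + hi) / 2
  fic <- calibrate_fic(p, C1, rate_tol = 5e-4, seed = 1)
  expect_true(attr(fic, "converged"))
  expect_lt(abs(fic$J - J_oracle), 1e-3)
  expect_true(all(fic$J > 0))
})

test_that("a stronger connectome never needs much less inhibition", {
  m <- small_model()
  p <- dmf_params(sigma_g = 0)
  f1 <- suppressWarnings(calibrate_fic(p, m$sc$C, seed = 2))
  f2 <- suppressWarnings(calibrate_fic(p, m$sc$C * 1.5, seed = 2))
  expect_gt(mean(f2$J), mean(f1$J))
  expect_true(all(f2$J > f1$J - 0.05))
})

test_that("small-network calibration lands every node in the physiological band", {
  m <- small_model()
  expect_true(attr(m$fic, "converged"))
  ver <- dmf_simulate(dmf_params(t_total = 40, t_burn = 5), m$sc, m$fic,
                      seed = 77, store_rates = FALSE,
                      init = attr(m$fic, "state"))
  expect_true(all(ver$mean_rate >= 3 & ver$mean_rate <= 4))
})
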