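test_that("generated connectome satisfies its structural contract", {
  cfg <- synth_config(n_regions = 40, connectome_density = 0.3, seed = 12)
  sc <- gen_connectome(cfg)
  C <- sc$C
  expect_equal(dim(C), c(40, 40))
  expect_true(all(diag(C) == 0))
  expect_true(all(C >= 0))
  expect_equal(C, t(C))
  expect_equal(max(C), 0.2)
  dens <- mean(C[upper.tri(C)] > 0)
  expect_lt(abs(dens - 0.3) / 0.3, 0.1)
  expect_true(is_connected(C))
})

test_that("connectome generation is seed-deterministic and rejects infeasible density", {
  cfg <- synth_config(n_regions = 30, seed = 4)
  expect_identical(gen_connectome(cfg)$C, gen_connectome(cfg)$C)
  cfg2 <- synth_config(n_regions = 30, seed = 5)
  expect_false(identical(gen_connectome(cfg)$C, gen_connectome(cfg2)$C))
  tiny <- synth_config(n_regions = 50, connectome_density = 0.01, seed = 1)
  expect_error(gen_connectome(tiny), "connected")
})

test_that("atrophy maps follow the w-score conventions", {
  cfg <- synth_config(n_regions = 60, atrophy_strength = 1.5, seed = 8)
  hc <- gen_atrophy_map(cfg, "HC")
  expect_identical(hc$alpha, rep(0, 60))

  ad <- gen_atrophy_map(cfg, "AD", focus = 1:10)
  expect_lt(abs(mean(ad$alpha[1:10]) - 1.5), 0.3)
  expect_lt(max(ad$alpha[-(1:10)]), 0.2)
  expect_true(all(ad$alpha >= 0))  # positive-is-atrophy convention

  # disjoint foci give essentially uncorrelated maps
  a1 <- gen_atrophy_map(cfg, "AD", focus = 1:10)
  a2 <- gen_atrophy_map(cfg, "bvFTD", focus = 31:40)
  expect_lt(abs(cor(a1$alpha, a2$alpha)), 0.2)
})

test_that("cohort carries the planted sigma-duration relation", {
  cfg <- synth_config(seed = 21, sigma_true = -0.2, ywd_slope = -0.02,
                      gender_effect = -0.01)
  co <- gen_cohort(cfg, n_per_cell = 10)
  expect_false(any(duplicated(co$subject_id)))
  hc <- co[co$group == "HC", ]
  expect_true(all(hc$ywd == 0))
  expect_true(all(hc$sigma_true == 0))
  expect_true(all(co$ywd >= 0 & co$ywd <= 12))

  # male patients carry exactly the planted slope; OLS recovers it
  pat <- co[co$group != "HC" & co$gender == "M", ]
  fit <- lm(sigma_true ~ ywd, data = pat)
  # noise-free cohort: the fit is exact, so the SE is ~0 and the warning
  # from summary.lm about a perfect fit is expected
  se <- suppressWarnings(summary(fit))$coefficients["ywd", "Std. Error"]
  expect_lt(abs(coef(fit)[["ywd"]] - (-0.02)), 2 * se + 1e-10)
  # female patients carry the additional gender slope offset
  f <- co[co$group != "HC" & co$gender == "F", ]
  expect_equal(unname(coef(lm(sigma_true ~ ywd, data = f))["ywd"]),
               -0.03, tolerance = 1e-8)
})

test_that("zero planted slope makes sigma constant across duration", {
  cfg <- synth_config(seed = 2, sigma_true = -0.3, ywd_slope = 0,
                      gender_effect = 0)
  co <- gen_cohort(cfg, 5)
  pat <- co[co$group != "HC", ]
  expect_equal(unique(pat$sigma_true), -0.3)
})

test_that("synthetic FC targets are valid correlation-like matrices", {
  m <- small_model()
  p <- dmf_params(t_total = 30)
  fc1 <- gen_empirical_fc(m$cfg, m$sc, gen_atrophy_map(m$cfg, "AD"),
                          sigma_true = -0.3, params = p, fic = m$fic,
                          seed = 9)
  fc2 <- gen_empirical_fc(m$cfg, m$sc, gen_atrophy_map(m$cfg, "AD"),
                          sigma_true = -0.3, params = p, fic = m$fic,
                          seed = 9)
  expect_identical(fc1$values, fc2$values)  # noise-free, same seed
  expect_true(all(diag(fc1$values) == 1))
  expect_equal(fc1$values, t(fc1$values))
  expect_true(all(abs(fc1$values) <= 1))

  cfgn <- synth_config(n_regions = 24, seed = 5, noise_sd = 0.05)
  fcn <- gen_empirical_fc(cfgn, m$sc, gen_atrophy_map(m$cfg, "AD"),
                          sigma_true = -0.3, params = p, fic = m$fic,
                          seed = 9)
  expect_true(all(diag(fcn$values) == 1))
  expect_equal(fcn$values, t(fcn$values))
  expect_false(identical(fcn$values, fc1$values))
})

test_that("strong inhibition loss moves group FC further than replicate noise", {
  # the signal the sigma fitter exploits, at full model size: run-averaged
  # (group-level) FC at sigma = -0.5 with focal atrophy is further from the
  # sigma = 0 group FC than an independent sigma = 0 replicate is
  m <- full_model()
  am <- gen_atrophy_map(m$cfg, "AD", focus = 1:22)
  p <- dmf_params()
  avg_fc <- function(sig, seeds) {
    M <- 0
    for (s in seeds)
      M <- M + simulate_fc(sig, m$sc, am, m$fic, p, seed = s)$values
    fc_matrix(M / length(seeds))
  }
  ref <- avg_fc(0, 301:306)
  rep2 <- avg_fc(0, 311:316)
  alt <- avg_fc(-0.5, 321:326)
  expect_gt(fc_distance(ref, alt), fc_distance(ref, rep2))
})

test_that("rsn mask fixture matches the packaged parcellation", {
  masks <- gen_rsn_masks()
  expect_named(masks)
  expect_setequal(names(masks), c("VN", "SN", "MN", "EXEC", "DMN"))
  expect_true(all(unlist(masks) >= 1 & unlist(masks) <= 90))
  expect_true(all(lengths(masks) > 0))
})
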