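fake_map <- function(M) structure(list(rho = M, ywd = 1:3, n_runs = 1),
                                  class = "progression_map")

test_that("progression map equals a hand-rolled rank-correlation loop", {
  m <- small_model()
  am <- gen_atrophy_map(m$cfg, "AD")
  p <- dmf_params(t_total = 16, t_burn = 4)
  ywd <- c(2, 5, 8)
  sig <- setNames(-0.05 * ywd, ywd)
  pm <- fc_vs_ywd(sig, m$sc, am, m$fic, p, bw_params(), n_runs = 2, seed = 4)

  # oracle: regenerate the same FC matrices and loop edge by edge
  n <- 24
  acc <- matrix(0, n, n)
  for (r in 1:2) {
    fcs <- lapply(seq_along(ywd), function(t)
      simulate_fc(sig[t], m$sc, am, m$fic, p, bw_params(),
                  seed = dmfic:::derive_seed(4, "prog", r * 1000 + t))$values)
    rho <- matrix(0, n, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        e <- vapply(fcs, function(f) f[i, j], numeric(1))
        rho[i, j] <- rho[j, i] <-
          if (sd(e) == 0) 0 else cor(e, ywd, method = "spearman")
      }
    }
    acc <- acc + rho
  }
  expect_equal(pm$rho, acc / 2, tolerance = 1e-12)
  expect_equal(pm$rho, t(pm$rho))
  expect_true(all(abs(pm$rho) <= 1 + 1e-12))
})

test_that("run-averaged-FC ordering is available behind its flag", {
  m <- small_model()
  am <- gen_atrophy_map(m$cfg, "AD")
  p <- dmf_params(t_total = 14, t_burn = 4)
  sig <- setNames(c(-0.1, -0.3, -0.5), c(2, 6, 10))
  pm1 <- fc_vs_ywd(sig, m$sc, am, m$fic, p, bw_params(), n_runs = 2,
                   seed = 11)
  pm2 <- fc_vs_ywd(sig, m$sc, am, m$fic, p, bw_params(), n_runs = 2,
                   seed = 11, average_fc_first = TRUE)
  expect_equal(dim(pm2$rho), dim(pm1$rho))
  expect_false(identical(pm1$rho, pm2$rho))
  # single run: the two orderings coincide
  pm3 <- fc_vs_ywd(sig, m$sc, am, m$fic, p, bw_params(), n_runs = 1,
                   seed = 11)
  pm4 <- fc_vs_ywd(sig, m$sc, am, m$fic, p, bw_params(), n_runs = 1,
                   seed = 11, average_fc_first = TRUE)
  expect_equal(pm3$rho, pm4$rho)
})

test_that("constant sigma leaves no systematic duration trend", {
  m <- small_model()
  am <- gen_atrophy_map(m$cfg, "AD")
  p <- dmf_params(t_total = 14, t_burn = 4)
  pm <- fc_vs_ywd(setNames(c(-0.2, -0.2, -0.2), c(1, 5, 9)), m$sc, am,
                  m$fic, p, bw_params(), n_runs = 12, seed = 6)
  v <- pm$rho[upper.tri(pm$rho)]
  expect_lt(abs(mean(v)), 0.1)   # no signed trend on average
  expect_lt(mean(abs(v)), 0.5)   # individual edges shrink with averaging
})

test_that("sign-restricted node scores follow the incidence arithmetic", {
  M <- matrix(0, 4, 4)
  expect_equal(node_scores(fake_map(M), "positive"), rep(0, 4))

  M[1, 2] <- M[2, 1] <- 0.5
  s <- node_scores(fake_map(M), "positive")
  expect_equal(s, c(0.5 / 3, 0.5 / 3, 0, 0))
  expect_equal(node_scores(fake_map(M), "negative"), rep(0, 4))

  # fixed 4-node map, hand computation with mixed signs
  M2 <- matrix(0, 4, 4)
  M2[1, 2] <- M2[2, 1] <- 0.6
  M2[1, 3] <- M2[3, 1] <- -0.3
  M2[3, 4] <- M2[4, 3] <- -0.9
  expect_equal(node_scores(fake_map(M2), "positive"), c(0.2, 0.2, 0, 0))
  expect_equal(node_scores(fake_map(M2), "negative"),
               c(-0.1, 0, -1.2 / 3, -0.3))
})

test_that("edge thresholding keeps the most extreme fraction with fixed ties", {
  set.seed(8)
  A <- matrix(rnorm(90 * 90), 90); M <- (A + t(A)) / 2; diag(M) <- 0
  pm <- fake_map(M)
  expect_equal(nrow(threshold_edges(pm, 1)), 90 * 89 / 2)  # 4005 edges
  top <- threshold_edges(pm, 0.05, "negative")
  expect_equal(nrow(top), floor(0.05 * 4005))  # 200 edges
  expect_equal(nrow(top), 200)
  expect_true(all(top$rho <= sort(M[upper.tri(M)])[201]))

  # duplicate values at the cut resolve deterministically
  M3 <- matrix(0, 4, 4)
  M3[upper.tri(M3)] <- c(1, 1, 1, 0.5, 0.5, 0.2)
  M3 <- M3 + t(M3)
  t1 <- threshold_edges(fake_map(M3), 0.5, "positive")
  t2 <- threshold_edges(fake_map(M3), 0.5, "positive")
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 3)
})

test_that("RSN overlap reproduces the Jaccard arithmetic", {
  scores <- c(5, 4, 3, 0, 0, 0, 0, 0, 0, 0)
  masks <- list(A = c(2, 3, 4), B = c(8, 9, 10))
  ov <- rsn_overlap(scores, masks, "positive")
  expect_equal(ov$jaccard[ov$network == "A"], 2 / 4)  # top {1,2,3} vs {2,3,4}
  expect_equal(ov$jaccard[ov$network == "B"], 0)      # disjoint

  ind <- rep(0, 10); ind[c(2, 3, 4)] <- 1
  ov2 <- rsn_overlap(ind, list(A = c(2, 3, 4)), "positive")
  expect_equal(ov2$jaccard, 1)                        # exact indicator

  expect_error(rsn_overlap(scores, list(A = 1:11), "positive"), "members")
  expect_true(all(ov$jaccard >= 0 & ov$jaccard <= 1))
})
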