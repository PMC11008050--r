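test_that("w-scores standardize against the control distribution", {
  controls <- rbind(c(10, 5), c(12, 6), c(14, 7), c(12, 6))
  m <- colMeans(controls)
  s <- apply(controls, 2, sd)
  expect_equal(w_scores(m, controls), c(0, 0))
  expect_equal(w_scores(m + s, controls), c(1, 1))
  # 4-subject toy table against hand arithmetic
  x <- c(15, 8)
  expect_equal(w_scores(x, controls), (x - m) / s)
  # the controls' own w-scores have mean 0 and SD 1
  wc <- w_scores(controls, controls)
  expect_equal(colMeans(wc), c(0, 0))
  expect_equal(apply(wc, 2, sd), c(1, 1))
  expect_error(w_scores(c(1, 1), rbind(c(1, 2), c(1, 3))), "zero control SD")
  expect_error(w_scores(c(1, 2), matrix(1:2, 1)), "at least 2")
})

test_that("regression matches closed-form OLS on a fixed dataset", {
  x <- c(1, 2, 4, 5, 7, 9)
  y <- c(2.1, 1.7, 1.2, 1.4, 0.6, 0.2)
  r <- regress(y, x)
  # closed-form slope and correlation
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sum((x - mean(x))^2)
  R <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$slope, slope)
  expect_equal(r$R, R)
  expect_equal(r$R2, R^2)
  expect_equal(r$eta_p2, R^2)  # simple regression: np2 equals R2
  expect_equal(r$intercept, mean(y) - slope * mean(x))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$R, R)
})

test_that("regression recognizes exact and null relationships", {
  x <- 1:10
  # exact fit: the perfect-fit warning from the underlying lm is expected
  r <- suppressWarnings(regress(10 - 2 * x, x))
  expect_equal(r$R, -1)
  expect_equal(r$R2, 1)
  expect_error(regress(rnorm(5), rep(1, 5)), "constant")
  # planted null: |R| stays small at n = 1000
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    abs(regress(rnorm(1000), rnorm(1000))$R) < 0.1
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("ancova detects a planted factor effect and respects the null", {
  # power: additive offset 1.0 at noise SD 0.1
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    g <- rep(c("F", "M"), each = 30)
    x <- runif(60, 0, 10)
    y <- 0.1 * x + ifelse(g == "F", 1, 0) + rnorm(60, 0, 0.1)
    ancova(y, g, x)$p[1] < 0.001
  }, logical(1))
  expect_gte(sum(hits), 29)

  # null: factor p roughly uniform (mean ~0.5, no excess small p)
  ps <- vapply(1:200, function(s) {
    set.seed(1e5 + s)
    g <- rep(c("F", "M"), each = 15)
    x <- runif(30)
    ancova(rnorm(30), g, x)$p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)

  # orthogonal zero-slope covariate explains nothing
  g <- rep(c("F", "M"), each = 20)
  x <- rep(seq(-1, 1, length.out = 20), 2)     # balanced across levels
  set.seed(3)
  y <- ifelse(g == "F", 1, 0) + rnorm(40, 0, 0.05)
  a <- ancova(y, g, x)
  expect_lt(a$eta_p2[a$term == "covariate"], 0.1)
})

test_that("ancova agrees with car's Type-II table", {
  set.seed(11)
  g <- rep(c("a", "b"), each = 12)
  x <- rnorm(24)
  y <- rnorm(24) + 0.5 * x
  mine <- ancova(y, g, x)
  ref <- car::Anova(lm(y ~ factor(g) + x), type = 2)
  expect_equal(mine$F, ref[1:2, "F value"], ignore_attr = TRUE)
  expect_equal(mine$p, ref[1:2, "Pr(>F)"], ignore_attr = TRUE)
  expect_error(ancova(y, rep("a", 24), x), "levels")
  # normality check on the residuals rides along
  expect_equal(attr(mine, "shapiro_p"),
               shapiro.test(residuals(lm(y ~ factor(g) + x)))$p.value)
})

test_that("mean-centered Levene matches direct evaluation and car", {
  g1 <- c(1, 2, 3); g2 <- c(1, 5, 9)
  lv <- levene(list(g1, g2))
  # direct arithmetic on Z = |y - group mean|
  z1 <- abs(g1 - 2); z2 <- abs(g2 - 5)
  z <- c(z1, z2); f <- factor(rep(1:2, each = 3))
  ssb <- 3 * (mean(z1) - mean(z))^2 + 3 * (mean(z2) - mean(z))^2
  ssw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  W <- (ssb / 1) / (ssw / 4)
  expect_equal(lv$statistic, W)
  ref <- car::leveneTest(c(g1, g2), f, center = mean)
  expect_equal(lv$statistic, ref[1, "F value"])
  expect_equal(lv$p_raw, ref[1, "Pr(>F)"])
})

test_that("Levene has power against spread differences and a clean null", {
  ident <- levene(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_raw, 1)
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    a <- rnorm(50)
    b <- mean(a) + 3 * (a - mean(a))   # same sample scaled x3 about its mean
    levene(list(a, b))$p_raw < 0.05
  }, logical(1))
  expect_gte(sum(hits), 27)
})

test_that("pairwise Welch tests carry a monotone BH adjustment", {
  set.seed(2)
  samples <- list(a = rnorm(20), b = rnorm(20, 2), c = rnorm(20, 0.1),
                  d = rnorm(20, 4))
  out <- ttests_fdr(samples)
  expect_equal(nrow(out), 6)
  expect_true(all(out$p_adj >= out$p_raw - 1e-12))
  expect_true(all(out$p_adj <= 1))
  ord <- order(out$p_raw)
  expect_true(all(diff(out$p_adj[ord]) >= -1e-12))
  expect_equal(out$p_adj, p.adjust(out$p_raw, "BH"))

  one <- ttests_fdr(samples, comparisons = list(c("a", "b")))
  expect_equal(one$p_adj, one$p_raw)  # single comparison: no correction

  same <- ttests_fdr(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$p_raw, 1)
})

test_that("Cohen's d matches hand computation and its invariances", {
  a <- c(1, 2, 3, 4)
  b <- c(3, 4, 5, 6)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_equal(cohens_d(a, a), 0)
  expect_equal(cohens_d(a + sp, a), 1)
  # invariance under common shift and positive scaling
  expect_equal(cohens_d(5 + 2 * a, 5 + 2 * b), cohens_d(a, b))
  expect_error(cohens_d(c(1, 1), c(2, 2)), "pooled SD")
})
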