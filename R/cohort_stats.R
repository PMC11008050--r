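#' Standardize regional measures against healthy controls (w-scores)
#'
#' `w = (x - mean_HC) / sd_HC` per region: the control group's own
#' w-scores have mean 0 and SD 1 (sample SD convention throughout).
#'
#' @param values Numeric vector (one subject) or subject x region matrix.
#' @param control_values Matrix (or vector) of the same regional layout
#'   for the healthy controls, with at least 2 rows.
#' @return w-scores with the shape of `values`.
#' @export
w_scores <- function(values, control_values) {
  cv <- if (is.matrix(control_values)) control_values
        else matrix(control_values, ncol = 1)
  if (nrow(cv) < 2) stop("need at least 2 controls")
  m <- colMeans(cv)
  s <- apply(cv, 2, sd)
  if (any(s == 0))
    stop("zero control SD in region(s): ",
         paste(which(s == 0), collapse = ", "))
  if (is.matrix(values)) {
    if (ncol(values) != length(m)) stop("region count mismatch")
    sweep(sweep(values, 2, m), 2, s, "/")
  } else {
    if (length(values) != length(m)) stop("region count mismatch")
    (values - m) / s
  }
}

# Partial eta squared from effect and error sums of squares.
eta_p2 <- function(ss_effect, ss_error) ss_effect / (ss_effect + ss_error)

#' Linear regression of fitted sigma on disease duration
#'
#' Ordinary least squares of `y` on `x`, reported the way the sigma-YWD
#' associations are: signed Pearson correlation `R`, its p-value, `R2`,
#' partial eta squared `SS_effect / (SS_effect + SS_residual)`, slope and
#' intercept.
#'
#' @param y Response (e.g. fitted sigma per subject or stratum).
#' @param x Covariate (e.g. years with disease).
#' @return A `sigma_regression` object (also a one-row tibble via
#'   [tidy()]).
#' @export
regress <- function(y, x) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0) stop("covariate is constant")
  fit <- lm(y ~ x)
  a <- anova(fit)
  ct <- stats::cor.test(x, y)
  out <- list(R = unname(ct$estimate), p = ct$p.value,
              R2 = summary(fit)$r.squared,
              eta_p2 = eta_p2(a["x", "Sum Sq"], a["Residuals", "Sum Sq"]),
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              n = length(x), fit = fit)
  structure(out, class = "sigma_regression")
}

#' @export
print.sigma_regression <- function(x, ...) {
  cat(sprintf("<sigma_regression> n = %d: R = %.3f, p = %.4g, R2 = %.3f, np2 = %.3f\n",
              x$n, x$R, x$p, x$R2, x$eta_p2))
  invisible(x)
}

#' @rdname regress
#' @param x A `sigma_regression` object.
#' @param ... Unused.
#' @export
tidy.sigma_regression <- function(x, ...) {
  tibble::tibble(R = x$R, p = x$p, R2 = x$R2, eta_p2 = x$eta_p2,
                 slope = x$slope, intercept = x$intercept, n = x$n)
}

#' Analysis of covariance for a factor plus a covariate
#'
#' Fits `y ~ factor + covariate` and reports Type-II F tests with partial
#' eta squared per term, as used to compare fitted sigma values between
#' genders while adjusting for disease duration.
#'
#' @param y Response.
#' @param factor Grouping factor (at least 2 levels, each with at least 2
#'   observations).
#' @param covariate Numeric covariate.
#' @return Tibble with one row per term: `term`, `df`, `F`, `p`, `eta_p2`.
#'   The Shapiro-Wilk p-value of the model residuals (the basic normality
#'   check preceding an ANCOVA) is attached as attribute `shapiro_p`.
#' @export
ancova <- function(y, factor, covariate) {
  factor <- as.factor(factor)
  if (nlevels(droplevels(factor)) < 2) stop("factor needs >= 2 levels")
  if (any(table(droplevels(factor)) < 2))
    stop("each factor level needs >= 2 observations")
  dat <- data.frame(y = y, f = droplevels(factor), x = covariate)
  fit <- lm(y ~ f + x, data = dat)
  a2 <- car::Anova(fit, type = 2)
  ss_err <- a2["Residuals", "Sum Sq"]
  terms <- setdiff(rownames(a2), "Residuals")
  out <- tibble::tibble(
    term = ifelse(terms == "f", "factor", "covariate"),
    df = a2[terms, "Df"],
    F = a2[terms, "F value"],
    p = a2[terms, "Pr(>F)"],
    eta_p2 = eta_p2(a2[terms, "Sum Sq"], ss_err)
  )
  res <- stats::residuals(fit)
  if (length(res) >= 3 && length(res) <= 5000 && sd(res) > 0)
    attr(out, "shapiro_p") <- stats::shapiro.test(res)$p.value
  out
}

#' Levene test for homogeneity of variance
#'
#' Classical (mean-centered) Levene test: a one-way ANOVA F statistic on
#' the absolute deviations `|y_ij - mean_i|`, sensitive to spread
#' differences between groups (e.g. higher sigma spread in one cohort).
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `test_result` tibble row: `statistic`, `df1`, `df2`, `p_raw`,
#'   `method`.
#' @export
levene <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 observations")
  z <- lapply(groups, function(g) abs(g - mean(g)))
  y <- unlist(z)
  f <- factor(rep(seq_along(z), lengths(z)))
  if (sd(y) == 0) {
    # identical spread in every group: no evidence against homogeneity
    return(tibble::tibble(statistic = 0, df1 = length(groups) - 1,
                          df2 = length(y) - length(groups), p_raw = 1,
                          method = "levene-mean"))
  }
  a <- anova(lm(y ~ f))
  tibble::tibble(statistic = a["f", "F value"], df1 = a["f", "Df"],
                 df2 = a["Residuals", "Df"], p_raw = a["f", "Pr(>F)"],
                 method = "levene-mean")
}

#' Pairwise Welch t-tests with Benjamini-Hochberg correction
#'
#' Welch two-sample t-test for each requested pair of samples, with the
#' p-values adjusted by the Benjamini-Hochberg step-up procedure across
#' the whole comparison family.
#'
#' @param samples Named list of numeric vectors.
#' @param comparisons List of length-2 character vectors naming the pairs
#'   to compare; defaults to all pairs.
#' @return Tibble with `group1`, `group2`, `statistic`, `df`, `p_raw`,
#'   `p_adj`, `method`.
#' @export
ttests_fdr <- function(samples, comparisons = NULL) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  if (any(lengths(samples) < 2)) stop("each sample needs >= 2 observations")
  if (is.null(comparisons))
    comparisons <- utils::combn(names(samples), 2, simplify = FALSE)
  rows <- lapply(comparisons, function(pr) {
    a <- samples[[pr[1]]]; b <- samples[[pr[2]]]
    if (sd(a) == 0 && sd(b) == 0) {
      # degenerate: identical constant samples carry no evidence
      tt <- list(statistic = c(t = 0), parameter = c(df = length(a) +
                                                       length(b) - 2),
                 p.value = 1)
    } else {
      tt <- t.test(a, b)
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_raw = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out$method <- "welch-bh"
  out
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled SD weighted by `n - 1` per sample.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return Scalar effect size.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(0)
    stop("zero pooled SD with unequal means")
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}
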