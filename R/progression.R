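#' Model-predicted FC change with disease duration
#'
#' For each of `n_runs` independent runs, simulates an FC matrix at the
#' optimal sigma of every disease-duration (YWD) level, computes the
#' Spearman rank correlation of each FC entry with YWD within the run,
#' and averages the edge-wise correlations over runs. Edges constant
#' across levels within a run get correlation 0 (with a warning).
#'
#' @param sigma_by_ywd Named numeric vector or two-column data frame
#'   (`ywd`, `sigma`) mapping at least 3 duration levels to couplings.
#' @param connectome A [structural_connectome()].
#' @param atrophy An [atrophy_map()].
#' @param fic Calibrated baseline [fic_vector()].
#' @param params,bw Model parameter objects.
#' @param n_runs Simulation runs averaged over.
#' @param seed Master seed (run r, level t uses a derived seed).
#' @param average_fc_first If `TRUE`, FC matrices are averaged across
#'   runs per duration level first and a single Spearman correlation is
#'   computed per edge, instead of the default
#'   correlate-within-run-then-average order.
#' @return A `progression_map` object: `rho` (region x region mean
#'   Spearman correlation, diagonal 0), `ywd`, `n_runs`.
#' @export
fc_vs_ywd <- function(sigma_by_ywd, connectome, atrophy, fic,
                      params = dmf_params(), bw = bw_params(),
                      n_runs = 10, seed = 1L, average_fc_first = FALSE) {
  if (is.data.frame(sigma_by_ywd)) {
    ywd <- sigma_by_ywd$ywd
    sig <- sigma_by_ywd$sigma
  } else {
    ywd <- as.numeric(names(sigma_by_ywd))
    sig <- as.numeric(sigma_by_ywd)
  }
  if (length(ywd) < 3 || anyNA(ywd)) stop("need >= 3 named YWD levels")
  stopifnot(all(is.finite(sig)))
  n <- nrow(as_connectome_matrix(connectome))
  iu <- upper.tri(matrix(0, n, n))
  L <- length(ywd)
  ywd_rank <- rank(ywd)

  run_edges <- function(r) {
    vapply(seq_len(L), function(t) {
      fc <- simulate_fc(sig[t], connectome, atrophy, fic, params, bw,
                        seed = derive_seed(seed, "prog", r * 1000 + t))
      as_fc_values(fc)[iu]
    }, numeric(sum(iu)))
  }
  warned <- FALSE
  if (average_fc_first) {
    edges <- 0
    for (r in seq_len(n_runs)) edges <- edges + run_edges(r)
    rho_mean <- edgewise_spearman(edges / n_runs, ywd_rank)
    warned <- attr(rho_mean, "n_constant") > 0
  } else {
    acc <- 0
    for (r in seq_len(n_runs)) {
      rho <- edgewise_spearman(run_edges(r), ywd_rank)
      if (attr(rho, "n_constant") > 0) warned <- TRUE
      acc <- acc + rho
    }
    rho_mean <- acc / n_runs
  }
  if (warned)
    warning("constant FC edges across YWD levels; their correlation was set to 0")
  M <- matrix(0, n, n)
  M[iu] <- rho_mean
  M <- M + t(M)
  structure(list(rho = M, ywd = ywd, n_runs = n_runs),
            class = "progression_map")
}

# Row-wise Spearman correlation of an edges x levels matrix against a
# rank vector; constant rows get 0 (counted in attribute n_constant).
edgewise_spearman <- function(edges, ywd_rank) {
  R <- t(apply(edges, 1, rank))
  rc <- ywd_rank - mean(ywd_rank)
  Rc <- R - rowMeans(R)
  denom <- sqrt(rowSums(Rc^2) * sum(rc^2))
  num <- drop(Rc %*% rc)
  out <- ifelse(denom > 0, num / denom, 0)
  attr(out, "n_constant") <- sum(denom == 0)
  out
}

#' @export
print.progression_map <- function(x, ...) {
  v <- x$rho[upper.tri(x$rho)]
  cat(sprintf("<progression_map> %d regions, %d YWD levels, %d runs\n",
              nrow(x$rho), length(x$ywd), x$n_runs))
  cat(sprintf("  edge rho range [%.2f, %.2f]\n", min(v), max(v)))
  invisible(x)
}

#' Sign-restricted node scores of a progression map
#'
#' Per region, the mean over incident edges of the Spearman correlation
#' restricted to the requested sign; edges of the opposite sign contribute
#' 0 to the mean (they are not dropped from the denominator).
#'
#' @param map A `progression_map`.
#' @param sign `"positive"` or `"negative"`.
#' @return Numeric per-region score (nonnegative for `"positive"`,
#'   nonpositive for `"negative"`).
#' @export
node_scores <- function(map, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  M <- map$rho
  keep <- if (sign == "positive") M > 0 else M < 0
  Mk <- M * keep
  diag(Mk) <- 0
  rowSums(Mk) / (nrow(M) - 1)
}

#' Most extreme progression edges
#'
#' The `floor(fraction * n_edges)` undirected edges with the most extreme
#' correlation of the requested sign; ties broken by the fixed row-major
#' edge ordering.
#'
#' @param map A `progression_map`.
#' @param fraction Fraction of edges to keep, in (0, 1].
#' @param sign `"positive"` (largest rho) or `"negative"` (most negative).
#' @return Tibble `i`, `j`, `rho`, ordered by extremity.
#' @export
threshold_edges <- function(map, fraction = 0.05,
                            sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(fraction > 0, fraction <= 1)
  M <- map$rho
  n <- nrow(M)
  iu <- which(upper.tri(M), arr.ind = TRUE)
  rho <- M[upper.tri(M)]
  k <- floor(fraction * nrow(iu))
  key <- if (sign == "positive") -rho else rho
  ord <- order(key, seq_along(rho))   # fixed ordering breaks ties
  sel <- ord[seq_len(k)]
  tibble::tibble(i = iu[sel, 1], j = iu[sel, 2], rho = rho[sel])
}

#' Overlap between progression scores and resting-state networks
#'
#' For each network with k member regions, binarizes the score vector by
#' taking its top-k regions (most positive scores for `sign =
#' "positive"`, most negative for `"negative"`) and reports the Jaccard
#' index `|intersection| / |union|` against the network's member set.
#'
#' @param scores Per-region scores (from [node_scores()]).
#' @param masks Named list of integer index vectors (from
#'   [gen_rsn_masks()] or [read_rsn_masks()]).
#' @param sign Which extreme of the scores to binarize.
#' @return Tibble `network`, `k`, `jaccard`.
#' @export
rsn_overlap <- function(scores, masks, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(is.list(masks), !is.null(names(masks)), lengths(masks) > 0)
  n <- length(scores)
  key <- if (sign == "positive") -scores else scores
  ord <- order(key, seq_len(n))
  rows <- lapply(names(masks), function(nm) {
    mask <- masks[[nm]]
    k <- length(mask)
    if (k > n) stop("mask ", nm, " has more members than regions")
    top <- ord[seq_len(k)]
    jac <- length(intersect(top, mask)) / length(union(top, mask))
    tibble::tibble(network = nm, k = k, jaccard = jac)
  })
  dplyr::bind_rows(rows)
}
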