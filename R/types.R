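#' Structural connectome
#'
#' Wraps a square, symmetric, nonnegative coupling matrix with zero
#' diagonal (the `C_np` weights scaling long-range excitatory input).
#'
#' @param C Numeric matrix of coupling weights.
#' @param labels Optional region names.
#' @return A `structural_connectome` object.
#' @export
structural_connectome <- function(C, labels = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("connectome must be square")
  if (any(!is.finite(C))) stop("connectome contains non-finite entries")
  if (any(C < 0)) stop("connectome weights must be nonnegative")
  if (max(abs(C - t(C))) > 1e-10 * max(1, max(abs(C))))
    stop("connectome must be symmetric")
  if (any(diag(C) != 0)) stop("connectome diagonal must be zero")
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(C)))
  dimnames(C) <- list(labels, labels)
  structure(list(C = C, labels = labels), class = "structural_connectome")
}

as_connectome_matrix <- function(x) {
  if (inherits(x, "structural_connectome")) x$C else as.matrix(x)
}

#' @export
print.structural_connectome <- function(x, ...) {
  C <- x$C
  n <- nrow(C)
  dens <- mean(C[upper.tri(C)] > 0)
  cat(sprintf("<structural_connectome> %d regions, density %.2f, max %.3g\n",
              n, dens, max(C)))
  invisible(x)
}

#' Regional atrophy map
#'
#' Per-region atrophy loadings `alpha_n`, stored with positive values
#' meaning greater atrophy (sign-flipped volumetric w-scores), so that a
#' negative coupling `sigma` reduces feedback inhibition in atrophied
#' regions.
#'
#' @param alpha Numeric loading vector.
#' @param convention Sign convention flag; only `"positive-is-atrophy"` is
#'   produced by this package.
#' @param group Optional group label the map belongs to.
#' @return An `atrophy_map` object.
#' @export
atrophy_map <- function(alpha, convention = "positive-is-atrophy",
                        group = NULL) {
  stopifnot(is.numeric(alpha), all(is.finite(alpha)))
  structure(list(alpha = as.numeric(alpha), convention = convention,
                 group = group), class = "atrophy_map")
}

as_atrophy_alpha <- function(x) {
  if (inherits(x, "atrophy_map")) x$alpha else as.numeric(x)
}

#' @export
print.atrophy_map <- function(x, ...) {
  cat(sprintf("<atrophy_map> %d regions (%s)%s; mean |alpha| = %.3f\n",
              length(x$alpha), x$convention,
              if (is.null(x$group)) "" else paste0(", group ", x$group),
              mean(abs(x$alpha))))
  invisible(x)
}

#' Feedback inhibition control vector
#'
#' Per-region inhibitory-to-excitatory weights: the calibrated baseline
#' `J0` and the effective `J` after atrophy modulation (equal to `J0`
#' before modulation).
#'
#' @param J0 Baseline weights, nA (all positive).
#' @param J Effective weights, nA; defaults to `J0`.
#' @return A `fic_vector` object.
#' @export
fic_vector <- function(J0, J = J0) {
  stopifnot(is.numeric(J0), all(J0 > 0), length(J) == length(J0),
            all(J > 0))
  structure(list(J0 = as.numeric(J0), J = as.numeric(J)),
            class = "fic_vector")
}

# Effective (or baseline) weights from a fic_vector or plain numeric.
as_fic_j <- function(x, baseline = FALSE) {
  if (inherits(x, "fic_vector")) {
    if (baseline) x$J0 else x$J
  } else {
    as.numeric(x)
  }
}

#' @export
print.fic_vector <- function(x, ...) {
  cat(sprintf("<fic_vector> %d regions; J in [%.3f, %.3f] nA\n",
              length(x$J), min(x$J), max(x$J)))
  if (!is.null(attr(x, "converged")))
    cat(sprintf("  calibration: %s after %d sweep(s)\n",
                if (attr(x, "converged")) "converged" else "NOT converged",
                attr(x, "n_iter")))
  invisible(x)
}

#' Functional connectivity matrix
#'
#' Region-by-region Pearson correlation matrix (empirical or simulated):
#' symmetric, unit diagonal, entries in `[-1, 1]` (up to observation noise
#' added by the synthetic generator, which is clipped back to the valid
#' range).
#'
#' @param values Square numeric matrix.
#' @param labels Optional region names.
#' @return An `fc_matrix` object.
#' @export
fc_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("FC matrix must be square")
  if (any(!is.finite(values))) stop("FC matrix contains non-finite entries")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels), class = "fc_matrix")
}

as_fc_values <- function(x) {
  if (inherits(x, "fc_matrix")) x$values else as.matrix(x)
}

#' @export
print.fc_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("<fc_matrix> %d regions; off-diagonal range [%.2f, %.2f]\n",
              nrow(x$values), min(v), max(v)))
  invisible(x)
}
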