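#' Functional connectivity from BOLD
#'
#' Pearson correlation across time for every region pair. Regions with
#' zero temporal variance get zero correlation with everything (with a
#' warning) rather than NA; the diagonal is 1.
#'
#' @param bold A `bold_timeseries` (from [bold_from_rate()]) or a
#'   region x time numeric matrix.
#' @param bandpass Optional length-2 frequency band in Hz (e.g.
#'   `c(0.008, 0.09)`): each region's series is filtered with a
#'   zero-phase 2nd-order Butterworth filter before correlating. Off by
#'   default. Requires a `bold_timeseries` (the sampling rate comes from
#'   its TR) unless `TR` is given.
#' @param TR Sampling interval of `bold` in seconds, needed only when
#'   `bandpass` is used with a plain matrix.
#' @return An [fc_matrix()].
#' @export
compute_fc <- function(bold, bandpass = NULL, TR = NULL) {
  sig <- if (inherits(bold, "bold_timeseries")) bold$signal else as.matrix(bold)
  if (ncol(sig) < 2) stop("need at least 2 time points to compute FC")
  if (!is.null(bandpass)) {
    stopifnot(length(bandpass) == 2, bandpass[1] < bandpass[2])
    if (is.null(TR)) {
      if (!inherits(bold, "bold_timeseries"))
        stop("bandpass filtering needs TR (or a bold_timeseries input)")
      TR <- bold$TR
    }
    nyq <- 0.5 / TR
    wl <- pmin(pmax(bandpass / nyq, 1e-6), 0.999)
    bf <- signal::butter(2, wl, type = "pass")
    sig <- t(apply(sig, 1, function(v) signal::filtfilt(bf, v)))
  }
  sds <- apply(sig, 1, sd)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " region(s) with zero variance; FC entries set to 0")
  V <- suppressWarnings(cor(t(sig)))
  V[!is.finite(V)] <- 0
  diag(V) <- 1
  fc_matrix(V)
}

# Padded 2-D integral image (summed-area table).
integral2 <- function(M) {
  P <- matrix(0, nrow(M) + 1, ncol(M) + 1)
  P[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum) |> t()
  P
}

# Sliding-window sums of M for a w x w uniform window, via the integral
# image: returns an (n-w+1) x (n-w+1) matrix of window sums.
window_sums <- function(M, w) {
  P <- integral2(M)
  n1 <- nrow(M) - w + 1
  n2 <- ncol(M) - w + 1
  i <- seq_len(n1)
  j <- seq_len(n2)
  P[i + w, j + w, drop = FALSE] - P[i, j + w, drop = FALSE] -
    P[i + w, j, drop = FALSE] + P[i, j, drop = FALSE]
}

#' Structural similarity between two matrices
#'
#' Mean structural similarity (SSIM) over all positions of a square
#' sliding window. For local means `mu`, standard deviations `sigma`, and
#' covariance `sigma_xy` of the two windows, each position scores
#' \deqn{\frac{2\mu_x\mu_y + 0.01}{\mu_x^2+\mu_y^2+0.01}\cdot
#'       \frac{2\sigma_x\sigma_y + 0.03}{\sigma_x^2+\sigma_y^2+0.03}\cdot
#'       \frac{\sigma_{xy} + 0.015}{\sigma_x\sigma_y + 0.015},}
#' and the score is averaged over positions. The full matrix is treated
#' as an image (diagonal included). `fc_ssim(x, x)` is exactly 1, and the
#' measure simultaneously penalizes mean offsets (Euclidean-like) and
#' decorrelation.
#'
#' @param x,y Same-shape matrices ([fc_matrix()] or plain).
#' @param cfg An [ssim_config()] (window size and stabilization constants).
#' @return Scalar similarity.
#' @export
fc_ssim <- function(x, y, cfg = ssim_config()) {
  X <- as_fc_values(x)
  Y <- as_fc_values(y)
  if (!all(dim(X) == dim(Y))) stop("matrices must have the same shape")
  w <- min(cfg$window, dim(X))
  nw <- w * w
  sx <- window_sums(X, w);  sy <- window_sums(Y, w)
  sxx <- window_sums(X * X, w); syy <- window_sums(Y * Y, w)
  sxy <- window_sums(X * Y, w)
  mx <- sx / nw; my <- sy / nw
  # sample (n-1) normalization, the convention of windowed SSIM
  vx <- pmax((sxx - nw * mx^2) / (nw - 1), 0)
  vy <- pmax((syy - nw * my^2) / (nw - 1), 0)
  cxy <- (sxy - nw * mx * my) / (nw - 1)
  sdx <- sqrt(vx); sdy <- sqrt(vy)
  s <- ((2 * mx * my + cfg$c1) / (mx^2 + my^2 + cfg$c1)) *
    ((2 * sdx * sdy + cfg$c2) / (vx + vy + cfg$c2)) *
    ((cxy + cfg$c3) / (sdx * sdy + cfg$c3))
  mean(s)
}

#' SSIM-based distance between FC matrices
#'
#' The model-fit distance `1 - SSIM(x, y)`: 0 for identical matrices,
#' symmetric in its arguments, and increasing under both additive offsets
#' and decorrelation of the compared matrices.
#'
#' @inheritParams fc_ssim
#' @return Scalar dissimilarity.
#' @export
fc_distance <- function(x, y, cfg = ssim_config()) {
  1 - fc_ssim(x, y, cfg)
}
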