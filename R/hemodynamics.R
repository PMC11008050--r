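#' BOLD signal from excitatory firing rates
#'
#' Transforms excitatory rate time series into BOLD signals through the
#' Balloon-Windkessel hemodynamic model. Per region, the vasodilatory
#' signal, inflow, venous volume, and deoxyhemoglobin content obey
#' \deqn{\dot z = x - \kappa z - \gamma_f (f - 1), \quad \dot f = z,}
#' \deqn{\tau \dot v = f - v^{1/\alpha}, \quad
#'       \tau \dot q = f E(f)/\rho - v^{1/\alpha} q / v,}
#' with oxygen extraction `E(f) = 1 - (1 - rho)^(1/f)`, and the BOLD
#' signal is `V0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v))` with `k1 = 7 rho`,
#' `k2 = 2`, `k3 = 2 rho - 0.2`. The neural drive `x` is the z-scored
#' excitatory rate of each region scaled by 0.5, which keeps the
#' hemodynamics in their near-linear regime; regions with zero rate
#' variance contribute zero drive (and therefore zero-variance BOLD).
#' The output is decimated to the scanner sampling interval `TR`.
#'
#' @param r_E_series Time x region matrix of excitatory rates, Hz, at
#'   resolution `dt` (e.g. `$r_E_series` of a [dmf_simulate()] result).
#' @param bw A [bw_params()].
#' @param dt Time step of `r_E_series`, s.
#' @param drive_scale Scaling applied to the z-scored drive.
#' @return A `bold_timeseries` object: `signal` (region x time matrix) and
#'   `TR`. The series length is `floor(n_steps * dt / TR)`.
#' @export
bold_from_rate <- function(r_E_series, bw = bw_params(), dt,
                           drive_scale = 0.5) {
  r_E_series <- as.matrix(r_E_series)
  stopifnot(all(is.finite(r_E_series)), dt > 0, bw$TR >= dt)
  x <- apply(r_E_series, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else drive_scale * (col - mean(col)) / s
  })
  every <- tr_decimation(dt, bw$TR)
  sig <- bw_bold_cpp(x, unclass(bw), dt, every)
  structure(list(signal = t(sig), TR = bw$TR),
            class = "bold_timeseries")
}

#' @export
print.bold_timeseries <- function(x, ...) {
  cat(sprintf("<bold_timeseries> %d regions x %d samples, TR = %g s\n",
              nrow(x$signal), ncol(x$signal), x$TR))
  invisible(x)
}

# Decimation factor from dt to TR, warning when TR is not a near-multiple.
tr_decimation <- function(dt, TR) {
  ratio <- TR / dt
  every <- round(ratio)
  if (abs(ratio - every) > 1e-6 * ratio)
    warning(sprintf("TR = %g s is not a multiple of dt = %g s; using every %d-th sample",
                    TR, dt, every))
  as.integer(max(1, every))
}

#' Write a BOLD time series to CSV
#'
#' Region x time CSV with the sampling interval recorded in a comment
#' header; read back with [read_matrix()].
#'
#' @param bold A `bold_timeseries`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path) {
  stopifnot(inherits(bold, "bold_timeseries"))
  write_matrix(bold$signal, path,
               header = sprintf("BOLD region x time, TR = %g s", bold$TR))
}

#' Decimate a signal to scanner resolution
#'
#' Keeps every `floor(TR/dt)`-th sample of a time x region (or plain
#' vector) signal, i.e. samples at `TR, 2 TR, ...` relative to the start
#' of the series.
#'
#' @param signal Time x region matrix or numeric vector.
#' @param dt Sampling step of `signal`, s.
#' @param TR Target sampling interval, s (must be `>= dt`).
#' @return The decimated signal in the same orientation.
#' @export
resample_to_tr <- function(signal, dt, TR) {
  stopifnot(TR >= dt)
  every <- tr_decimation(dt, TR)
  pick <- function(n) if (n < every) integer(0) else seq(every, n, by = every)
  if (is.matrix(signal)) {
    signal[pick(nrow(signal)), , drop = FALSE]
  } else {
    signal[pick(length(signal))]
  }
}
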