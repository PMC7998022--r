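# Row scaling, zero-phase band-pass filtering, and temporal upsampling --
# the conditioning steps every carpet-plot pipeline applies before delay
# estimation and sorting.

#' Z-score every voxel row
#'
#' Demeans each row and divides by its standard deviation, so that all rows
#' share a common intensity scale. Rows with zero variance cannot be scaled;
#' they are left at zero and reported in the `zero_variance` attribute.
#'
#' @param matrix A [voxel_matrix()].
#' @return The scaled [voxel_matrix()] with `scaled = TRUE`. Attribute
#'   `zero_variance` holds the voxel ids of any constant rows.
#' @export
scale_demean <- function(matrix) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  m <- matrix$data
  mu <- rowMeans(m)
  centered <- m - mu
  s <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  flat <- s < .Machine$double.eps^0.5
  if (all(flat)) stop("all rows are constant; nothing to scale")
  s[flat] <- 1
  out <- centered / s
  out[flat, ] <- 0
  res <- voxel_matrix(out, matrix$dt, matrix$voxel_ids, scaled = TRUE,
                      coords = matrix$coords)
  attr(res, "zero_variance") <- matrix$voxel_ids[flat]
  res
}

butter_coefs <- function(low_hz, high_hz, dt, order) {
  fs <- 1 / dt
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf(
      "band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
      low_hz, high_hz, nyq))
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

# Forward-backward application of an ARMA filter with reflective padding
# (>= 3 filter lengths, extended to one period of the low cutoff where the
# record allows) so that startup transients do not leak into the output.
filtfilt_refl <- function(filt, x, pad) {
  n <- length(x)
  np <- min(n - 1L, pad)
  xp <- reflect_pad(x, np)
  y <- as.numeric(signal::filter(filt, xp))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[seq(np + 1L, np + n)]
}

#' Zero-lag Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass filter forward and backward
#' (zero phase lag, squared magnitude response). Boundary transients are
#' suppressed by reflective padding before filtering.
#'
#' @param series Numeric vector (a single timeseries) or a [voxel_matrix()]
#'   whose rows are filtered independently.
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < Nyquist`.
#' @param dt Sampling interval in seconds (taken from the object for a
#'   [voxel_matrix()]).
#' @param order Filter order per band edge (default 4, the convention used
#'   for sLFO isolation).
#' @return Filtered object of the same type as `series`.
#' @export
bandpass <- function(series, low_hz, high_hz, dt = NULL, order = 4) {
  if (inherits(series, "voxel_matrix")) {
    out <- series
    out$data <- t(apply(series$data, 1L, bandpass, low_hz = low_hz,
                        high_hz = high_hz, dt = series$dt, order = order))
    return(out)
  }
  if (is.null(dt)) stop("`dt` is required for a plain numeric series")
  bf <- butter_coefs(low_hz, high_hz, dt, order)
  pad <- max(3L * length(bf$b) * 10L, ceiling(1 / (low_hz * dt)))
  filtfilt_refl(bf, as.numeric(series), pad)
}

#' Upsample a timeseries by cubic-spline interpolation
#'
#' Interpolates onto a finer uniform grid starting at time 0. Used to read
#' off sub-TR delays: resting-state rows are taken to 0.072 s and
#' CO2-challenge rows to 0.1 s before cross-correlation.
#'
#' @param series Numeric vector, or a [voxel_matrix()] (all rows resampled,
#'   `dt` updated).
#' @param dt_in Input sampling interval in seconds.
#' @param dt_out Output sampling interval in seconds; must be `< dt_in`.
#' @param method `"spline"` (default, cubic) or `"linear"`.
#' @return Resampled object of the same type as `series`.
#' @export
resample <- function(series, dt_in = NULL, dt_out, method = c("spline", "linear")) {
  method <- match.arg(method)
  if (inherits(series, "voxel_matrix")) {
    out <- series
    out$data <- t(apply(series$data, 1L, resample, dt_in = series$dt,
                        dt_out = dt_out, method = method))
    out$dt <- dt_out
    return(out)
  }
  if (is.null(dt_in)) stop("`dt_in` is required for a plain numeric series")
  if (!(dt_out > 0 && dt_out < dt_in))
    stop("`dt_out` must be positive and smaller than `dt_in` (upsampling only)")
  x <- as.numeric(series)
  t_in <- (seq_along(x) - 1) * dt_in
  t_out <- seq(0, t_in[length(t_in)] + 1e-12, by = dt_out)
  t_out <- t_out[t_out <= t_in[length(t_in)] + 1e-9]
  if (method == "spline") {
    stats::spline(t_in, x, xout = t_out, method = "fmm")$y
  } else {
    stats::approx(t_in, x, xout = t_out)$y
  }
}
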