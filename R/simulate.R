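# Validation frameworks for the slope detector: the contrast x noise
# robustness grid, the TR sampling-error sweep, and the contrast/noise
# estimators used to place real carpet plots on the grid.

#' Estimate the intensity contrast of a carpet
#'
#' Smooths the carpet and returns the difference between the averaged
#' lightest and the averaged darkest regions: the mean of pixels above the
#' 90th percentile minus the mean of pixels below the 10th percentile of
#' the smoothed image.
#'
#' @param carpet A `shag_carpet` or a plain numeric matrix.
#' @param sigma_time,sigma_row Blur parameters (defaults 2 and 5 samples).
#' @return Contrast in (scaled) intensity units.
#' @export
estimate_contrast <- function(carpet, sigma_time = 2, sigma_row = 5) {
  m <- if (inherits(carpet, "shag_carpet")) carpet$data else as.matrix(carpet)
  sm <- blur2d(m, sigma_time, sigma_row)
  hi <- quantile(sm, 0.9)
  lo <- quantile(sm, 0.1)
  if (hi <= lo) return(0)
  mean(sm[sm >= hi]) - mean(sm[sm <= lo])
}

#' Estimate the additive noise level of a carpet
#'
#' Models the image as clean + i.i.d. Gaussian noise and estimates the
#' noise standard deviation from the residual between the raw and the
#' smoothed image, corrected for the smoother's residual-variance factor
#' (so that pure white noise is recovered unbiased). The spread is measured
#' by the median absolute deviation, which ignores the localized leakage a
#' sharp clean edge leaves in the residual.
#'
#' @inheritParams estimate_contrast
#' @return Estimated noise standard deviation in intensity units.
#' @export
estimate_noise_sd <- function(carpet, sigma_time = 2, sigma_row = 5) {
  m <- if (inherits(carpet, "shag_carpet")) carpet$data else as.matrix(carpet)
  if (ncol(m) < 4L) stop("need at least 4 time samples")
  sm <- blur2d(m, sigma_time, sigma_row)
  resid <- m - sm
  stats::mad(as.numeric(resid)) / blur_residual_factor(sigma_time, sigma_row)
}

#' Synthetic DSC-like base carpet
#'
#' A clean, delay-sorted carpet with a single falling (bolus-arrival) edge:
#' each row is a z-scored gamma-variate signal dip whose onset is shifted
#' linearly across rows by the transit time. Serves as the clean component
#' of the robustness grid when no real scan is available.
#'
#' @param n_rows Number of voxel rows (default 16000, a scaled-down
#'   whole-brain DSC carpet; trial-to-trial transit variance scales with
#'   the ratio of the detector's row-blur correlation length to the row
#'   count, so toy-sized bases overstate the detector's variability).
#' @param duration Scan duration in seconds (default 180).
#' @param tr Sampling interval in seconds (default 1.5).
#' @param transit Ground-truth transit time in seconds (default 4.2).
#' @param t0 Bolus onset at the earliest row in seconds. The default 60.4
#'   places the onset off the sampling grid at a phase where the noiseless
#'   detected transit slightly exceeds the true value, the regime in which
#'   added noise can only attenuate the detected slope (see the vignette on
#'   sampling-phase bias).
#' @param tp Gamma-variate time-to-peak (default 4 s).
#' @return A `shag_carpet` whose rows are already sorted (latest arrival on
#'   top); attribute `true_transit` records the ground truth.
#' @export
dsc_base_carpet <- function(n_rows = 16000, duration = 180, tr = 1.5,
                            transit = 4.2, t0 = 60.4, tp = 4) {
  t <- seq(0, duration - tr, by = tr)
  delays <- seq(0, transit, length.out = n_rows)
  rows <- vapply(delays, function(d) {
    y <- -gamma_variate(t, t0 + d, tp)
    (y - mean(y)) / sd(y)
  }, numeric(length(t)))
  data <- t(rows)[rev(seq_len(n_rows)), , drop = FALSE]  # largest delay on top
  carpet <- new_shag_carpet(
    data = data, dt = tr, order = seq_len(n_rows) - 1L,
    delays_sorted = rev(delays), quality_sorted = rep(1, n_rows),
    crop = c(1L, n_rows), n_removed = 0L, scaled = TRUE,
    provenance = list(method = "synthetic_dsc"))
  attr(carpet, "true_transit") <- transit
  carpet
}

#' Contrast x noise robustness grid
#'
#' Evaluates the slope detector over a grid of image qualities: the clean
#' component of `base` is rescaled to each target contrast, i.i.d. Gaussian
#' noise of each target sd is added, and the (single) edge is re-fitted in
#' `n_trials` independent noise draws per cell, always at the edge center
#' located once on the clean base (fixed geometry, so per-cell statistics
#' isolate the detector's response to image quality). The baseline is the
#' transit detected on the clean base at native contrast.
#'
#' @param base A clean single-edge `shag_carpet`, e.g. [dsc_base_carpet()].
#' @param contrasts Numeric vector of target contrasts (intensity units).
#' @param noise_sds Numeric vector of noise standard deviations.
#' @param n_trials Trials per cell (default 30).
#' @param seed RNG seed; the grid is reproducible from it.
#' @param polarity Edge polarity of the base (default `"falling"`).
#' @param sigma_time,sigma_row Detector blur parameters.
#' @return A tibble of class `noise_grid`: one row per cell with
#'   `contrast`, `noise_sd`, `mean_transit_s`, `sd_transit_s`, `n_trials`,
#'   and a `transits` list column of per-trial values; attribute
#'   `baseline_transit_s` is the noiseless reference.
#' @export
noise_robustness_grid <- function(base, contrasts, noise_sds, n_trials = 30,
                                  seed = 1L, polarity = "falling",
                                  sigma_time = 2, sigma_row = 5) {
  stopifnot(inherits(base, "shag_carpet"))
  native <- estimate_contrast(base, sigma_time, sigma_row)
  center <- estimate_edge_centers(base, 1L, polarity,
                                  sigma_time = sigma_time)
  if (!length(center))
    stop("no detectable edge in the noiseless base carpet")
  baseline <- detect_edge(base, center[1], polarity,
                          sigma_time = sigma_time,
                          sigma_row = sigma_row)$transit_time_s
  cells <- tidyr::expand_grid(contrast = contrasts, noise_sd = noise_sds)
  res <- with_seed(seed, {
    purrr::pmap_dfr(cells, function(contrast, noise_sd) {
      scaled <- base
      scaled$data <- base$data * (contrast / native)
      transits <- vapply(seq_len(n_trials), function(i) {
        noisy <- scaled
        noisy$data <- scaled$data +
          matrix(rnorm(length(scaled$data), sd = noise_sd),
                 nrow(scaled$data), ncol(scaled$data))
        detect_edge(noisy, center[1], polarity,
                    sigma_time = sigma_time,
                    sigma_row = sigma_row)$transit_time_s
      }, numeric(1))
      tibble::tibble(contrast = contrast, noise_sd = noise_sd,
                     mean_transit_s = mean(transits),
                     sd_transit_s = sd(transits),
                     n_trials = n_trials, transits = list(transits))
    })
  })
  structure(res, class = unique(c("noise_grid", class(res))),
            baseline_transit_s = baseline, native_contrast = native,
            seed = seed)
}

#' TR sampling-error sweep
#'
#' Quantifies the transit-time error introduced by finite temporal
#' sampling: an ideal, noise-free linear edge with known transit time is
#' sampled at interval `tr` for each sampling-start offset on a uniform
#' grid over `[0, tr)`, the slope detector is run, and the signed error
#' (estimated minus true) is recorded per offset. The error depends on the
#' true transit time, the TR, and where sampling begins; its magnitude is
#' bounded by the TR.
#'
#' @param true_transit True transit time in seconds (> 0).
#' @param tr Sampling interval in seconds (> 0).
#' @param n_offsets Number of start offsets over `[0, tr)` (default 50).
#' @param n_rows Rows of the ideal edge image (default 400, comparable to
#'   a cropped single-slice carpet; with many fewer rows the detector's row
#'   blur attenuates the fitted slope near the image boundary).
#' @param duration Length of the sampled record in seconds (default
#'   6 true transits plus 20 TR, so the window always fits).
#' @param polarity Edge polarity (default `"rising"`).
#' @param sigma_time,sigma_row Detector blur parameters.
#' @return A tibble of class `tr_error_sweep`: columns `offset_s`,
#'   `estimated_s`, `error_s`; attributes `true_transit`, `tr`.
#' @export
tr_error_sweep <- function(true_transit, tr, n_offsets = 50, n_rows = 400,
                           duration = NULL, polarity = "rising",
                           sigma_time = 2, sigma_row = 5) {
  stopifnot(true_transit > 0, tr > 0)
  duration <- duration %||% (6 * true_transit + 20 * tr)
  offsets <- seq(0, tr, length.out = n_offsets + 1L)[seq_len(n_offsets)]
  # event time per delay-ascending rank r: t_edge + transit * r / (R - 1)
  t_edge <- duration / 2 - true_transit / 2
  ranks <- seq_len(n_rows) - 1L
  event <- t_edge + true_transit * ranks / (n_rows - 1)
  sgn <- if (polarity == "rising") 1 else -1
  res <- purrr::map_dfr(offsets, function(phi) {
    t_samp <- seq(phi, duration, by = tr)
    img <- t(vapply(event, function(e) sgn * as.numeric(t_samp >= e),
                    numeric(length(t_samp))))
    img <- img[rev(seq_len(n_rows)), , drop = FALSE]   # latest arrival on top
    carpet <- new_shag_carpet(
      data = img, dt = tr, order = seq_len(n_rows) - 1L,
      delays_sorted = rev(event), quality_sorted = rep(1, n_rows),
      crop = c(1L, n_rows), n_removed = 0L, scaled = TRUE)
    center <- mean(event) - phi
    window <- true_transit + 8 * tr
    e <- detect_edge(carpet, center, polarity, window = window,
                     sigma_time = sigma_time, sigma_row = sigma_row)
    tibble::tibble(offset_s = phi, estimated_s = e$transit_time_s,
                   error_s = e$transit_time_s - true_transit)
  })
  structure(res, class = unique(c("tr_error_sweep", class(res))),
            true_transit = true_transit, tr = tr)
}

#' Plot a robustness grid
#'
#' @param object A `noise_grid` from [noise_robustness_grid()].
#' @param ... Ignored.
#' @return A ggplot tile plot of mean transit per cell.
#' @export
autoplot.noise_grid <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$contrast),
                               y = factor(.data$noise_sd),
                               fill = .data$mean_transit_s)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.2f)", .data$mean_transit_s,
                      .data$sd_transit_s)), size = 2.5) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "contrast", y = "noise sd",
                  fill = "mean transit (s)") +
    ggplot2::theme_minimal()
}

#' Plot a TR-error sweep
#'
#' @param object A `tr_error_sweep`.
#' @param ... Ignored.
#' @return A ggplot of signed error against sampling offset.
#' @export
autoplot.tr_error_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$offset_s, y = .data$error_s)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "sampling start offset (s)",
                  y = "transit-time error (s)") +
    ggplot2::theme_minimal()
}
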