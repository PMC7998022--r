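# Synthetic BOLD phantoms with known per-voxel arrival delays. Each phantom
# is a shared base signal, time-shifted per voxel, plus i.i.d. Gaussian
# noise; a configurable fraction of voxels carries no pattern at all. The
# ground truth (delays, clean matrix, noise assignment) travels with the
# data so every downstream stage can be validated without real scans.

#' Delay models for phantoms
#'
#' `delay_linear_span()` spreads delays evenly over `[0, span]` seconds
#' across the pattern voxels (assignment order is randomised under the
#' phantom seed). `delay_uniform()` draws each delay independently from
#' `[min_s, max_s]`.
#'
#' @param span,min_s,max_s Delay extents in seconds.
#' @return A delay-model description used by [phantom_spec()].
#' @export
delay_linear_span <- function(span) {
  stopifnot(is.numeric(span), length(span) == 1L, span >= 0)
  list(type = "linear_span", span = span)
}

#' @rdname delay_linear_span
#' @export
delay_uniform <- function(min_s, max_s) {
  stopifnot(is.numeric(min_s), is.numeric(max_s), max_s >= min_s)
  list(type = "uniform_random", min = min_s, max = max_s)
}

default_modality_params <- function(modality) {
  switch(modality,
    rs = list(n_components = NULL, freqs = NULL, amps = NULL, phases = NULL),
    dsc = list(t0 = 10, tp = 4, depth = 3, baseline = 0, alpha = 3),
    co2 = list(block_onsets = c(120, 360), block_durations = c(120, 120),
               amplitude = 2, tau = 8, baseline_mmhg = 40, delta_mmhg = 10)
  )
}

#' Specify a synthetic phantom
#'
#' Describes a synthetic dataset of one of three modalities: `rs`
#' (resting-state BOLD carrying a shared band-limited 0.01-0.1 Hz
#' oscillation), `dsc` (dynamic susceptibility contrast with a gamma-variate
#' signal dip), or `co2` (block-design CO2 challenge with an exponential
#' vasodilatory response). Every pattern voxel holds the modality base
#' signal shifted by that voxel's delay.
#'
#' @param modality One of `"rs"`, `"dsc"`, `"co2"`.
#' @param n_voxels Number of voxels.
#' @param duration Scan duration in seconds.
#' @param tr Repetition time (sampling interval) in seconds.
#' @param delay_model A [delay_linear_span()] or [delay_uniform()] model.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (intensity units; 0 for a noiseless phantom).
#' @param noise_voxel_fraction Fraction in `[0, 1)` of voxels that carry no
#'   pattern, only noise.
#' @param motion_times Times (s) at which whole-brain motion spikes are
#'   injected; empty for none.
#' @param motion_amplitude Intensity offset of each motion spike.
#' @param seed Integer RNG seed; generation is fully reproducible from it.
#' @param modality_params Named list overriding modality defaults. For `rs`:
#'   `freqs`, `amps`, `phases` (or `n_components` to draw 3-8 sinusoids in
#'   0.01-0.1 Hz). For `dsc`: `t0`, `tp`, `depth`, `baseline`, `alpha`. For
#'   `co2`: `block_onsets`, `block_durations`, `amplitude`, `tau`,
#'   `baseline_mmhg`, `delta_mmhg`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(modality = c("rs", "dsc", "co2"), n_voxels = 400,
                         duration = 360, tr = 0.72,
                         delay_model = delay_linear_span(4.5),
                         noise_sd = 0, noise_voxel_fraction = 0,
                         motion_times = numeric(0), motion_amplitude = 5,
                         seed = 1L, modality_params = list()) {
  modality <- match.arg(modality)
  if (tr <= 0) stop("`tr` must be positive")
  if (duration <= 0) stop("`duration` must be positive")
  if (duration / tr < 16) stop("`duration/tr` must allow at least 16 samples")
  if (n_voxels < 1) stop("`n_voxels` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (noise_voxel_fraction < 0 || noise_voxel_fraction >= 1)
    stop("`noise_voxel_fraction` must lie in [0, 1)")
  span <- delay_model_span(delay_model)
  if (span >= duration / 2)
    stop("delay span must be smaller than half the scan duration")
  if (length(motion_times) &&
      (any(motion_times < 0) || any(motion_times >= duration)))
    stop("all `motion_times` must lie in [0, duration)")
  params <- utils::modifyList(default_modality_params(modality),
                              modality_params)
  structure(
    list(modality = modality, n_voxels = as.integer(n_voxels),
         duration = duration, tr = tr, delay_model = delay_model,
         noise_sd = noise_sd, noise_voxel_fraction = noise_voxel_fraction,
         motion_times = motion_times, motion_amplitude = motion_amplitude,
         seed = as.integer(seed), modality_params = params),
    class = "phantom_spec"
  )
}

delay_model_span <- function(dm) {
  switch(dm$type,
    linear_span = dm$span,
    uniform_random = dm$max - dm$min,
    stop("unknown delay model: ", dm$type)
  )
}

#' Gamma-variate bolus curve
#'
#' The standard first-pass bolus shape
#' `g(t) = ((t - t0)/tp)^alpha * exp(alpha * (1 - (t - t0)/tp))` for
#' `t > t0`, zero before onset. Its extremum (value 1) sits at `t0 + tp`.
#'
#' @param t Times in seconds.
#' @param t0 Bolus onset time (s).
#' @param tp Time from onset to peak (s).
#' @param alpha Shape parameter (default 3).
#' @return Curve values, peak normalised to 1.
#' @export
gamma_variate <- function(t, t0, tp, alpha = 3) {
  u <- (t - t0) / tp
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- u[pos]^alpha * exp(alpha * (1 - u[pos]))
  out
}

# Base-signal generator on a fine grid. Returns list(t, value) covering
# [t_min, t_max]; called inside the phantom's seeded RNG scope.
phantom_base_signal <- function(spec, t_min, t_max, dt_fine = 0.01) {
  t <- seq(t_min, t_max, by = dt_fine)
  p <- spec$modality_params
  v <- switch(spec$modality,
    rs = {
      if (is.null(p$freqs)) {
        m <- p$n_components %||% sample(3:8, 1L)
        p$freqs <- runif(m, 0.01, 0.1)
        p$amps <- runif(m, 0.5, 1)
        p$phases <- runif(m, 0, 2 * pi)
      }
      p$amps <- p$amps %||% rep(1, length(p$freqs))
      p$phases <- p$phases %||% rep(0, length(p$freqs))
      rowSums(vapply(seq_along(p$freqs), function(i)
        p$amps[i] * sin(2 * pi * p$freqs[i] * t + p$phases[i]),
        numeric(length(t))))
    },
    dsc = p$baseline - p$depth * gamma_variate(t, p$t0, p$tp, p$alpha),
    co2 = {
      box <- numeric(length(t))
      for (i in seq_along(p$block_onsets)) {
        on <- p$block_onsets[i]
        off <- on + p$block_durations[i]
        box[t >= on & t < off] <- 1
      }
      # single-exponential vasodilatory response, unit-area kernel
      kt <- seq(0, 6 * p$tau, by = dt_fine)
      kern <- exp(-kt / p$tau)
      kern <- kern / sum(kern)
      resp <- stats::filter(c(box, numeric(length(kern))), kern,
                            method = "convolution", sides = 1)
      p$amplitude * as.numeric(resp)[seq_along(box)]
    }
  )
  list(t = t, value = v, params = p)
}

#' Generate a phantom dataset
#'
#' Builds the clean voxel-by-time matrix (base signal shifted per voxel by
#' cubic interpolation of a 0.01 s fine grid), zeroes out the designated
#' noise voxels, adds i.i.d. Gaussian noise, and injects any requested
#' motion spikes. Reproducible bit-for-bit from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `matrix` (a [voxel_matrix()]) and `truth`,
#'   where `truth` contains `delays` (s; `NA` for noise voxels),
#'   `clean_matrix`, `noise_sd`, `noise_voxel_ids` (0-based),
#'   `true_transit_time` (delay span over pattern voxels), and the resolved
#'   modality parameters.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$n_voxels
    nt <- floor(spec$duration / spec$tr + 1e-9)
    t_samp <- (seq_len(nt) - 1) * spec$tr
    span <- delay_model_span(spec$delay_model)

    n_noise <- floor(spec$noise_voxel_fraction * n)
    noise_idx <- if (n_noise > 0) sort(sample.int(n, n_noise)) else integer(0)
    pattern_idx <- setdiff(seq_len(n), noise_idx)

    delays <- rep(NA_real_, n)
    dm <- spec$delay_model
    if (dm$type == "linear_span") {
      vals <- if (length(pattern_idx) == 1L) 0 else
        seq(0, dm$span, length.out = length(pattern_idx))
      delays[pattern_idx] <- vals[sample.int(length(pattern_idx))]
    } else {
      delays[pattern_idx] <- runif(length(pattern_idx), dm$min, dm$max)
    }

    base <- phantom_base_signal(spec, t_min = -span - 1,
                                t_max = spec$duration + 1)
    clean <- matrix(0, n, nt)
    for (v in pattern_idx) {
      clean[v, ] <- stats::spline(base$t, base$value,
                                  xout = t_samp - delays[v],
                                  method = "fmm")$y
    }
    noisy <- clean
    if (spec$noise_sd > 0)
      noisy <- noisy + matrix(rnorm(n * nt, sd = spec$noise_sd), n, nt)

    vm <- voxel_matrix(noisy, spec$tr)
    for (mt in spec$motion_times)
      vm <- inject_motion(vm, mt, spec$motion_amplitude)

    pat_delays <- delays[pattern_idx]
    truth <- structure(list(
      delays = delays,
      clean_matrix = clean,
      noise_sd = spec$noise_sd,
      noise_voxel_ids = vm$voxel_ids[noise_idx],
      true_transit_time = if (length(pat_delays))
        max(pat_delays) - min(pat_delays) else 0,
      modality_params = base$params,
      seed = spec$seed
    ), class = "phantom_truth")
    list(matrix = vm, truth = truth)
  })
}

#' Inject a whole-brain motion spike
#'
#' Offsets a single time column (the sample nearest `time`) by `amplitude`
#' in every voxel, mimicking the instantaneous vertical stripe a head
#' movement leaves in a carpet plot.
#'
#' @param matrix A [voxel_matrix()].
#' @param time Spike time in seconds; must lie in `[0, duration)`.
#' @param amplitude Intensity offset added to the column.
#' @return The modified [voxel_matrix()].
#' @export
inject_motion <- function(matrix, time, amplitude) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  dur <- vm_duration(matrix)
  if (time < 0 || time >= dur)
    stop(sprintf("motion time %g s outside scan [0, %g)", time, dur))
  j <- round(time / matrix$dt) + 1L
  j <- min(max(j, 1L), ncol(matrix$data))
  matrix$data[, j] <- matrix$data[, j] + amplitude
  matrix
}

#' End-tidal CO2 trace for a CO2 phantom
#'
#' The administered end-tidal CO2 protocol implied by a `co2`
#' [phantom_spec()]: baseline partial pressure with block elevations.
#'
#' @param spec A `co2` [phantom_spec()].
#' @param dt Sampling interval of the trace in seconds (default 1).
#' @return A tibble with columns `time_s` and `pco2_mmhg` (a
#'   `regressor_trace`).
#' @export
phantom_etco2 <- function(spec, dt = 1) {
  stopifnot(inherits(spec, "phantom_spec"), spec$modality == "co2")
  p <- spec$modality_params
  t <- seq(0, spec$duration - dt, by = dt)
  v <- rep(p$baseline_mmhg, length(t))
  for (i in seq_along(p$block_onsets)) {
    on <- p$block_onsets[i]
    off <- on + p$block_durations[i]
    v[t >= on & t < off] <- p$baseline_mmhg + p$delta_mmhg
  }
  regressor_trace(t, v)
}
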