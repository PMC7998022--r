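# The slope-detection algorithm. A tilted intensity edge in a delay-sorted
# carpet is located per row as the time of maximum (rising) or minimum
# (falling) horizontal derivative of the blurred image; an ordinary
# least-squares line through those breakpoints gives the edge's slope, and
# slope x (rows - 1) gives the transit time: the time the underlying event
# takes to traverse all sorted voxels.
#
# Row convention: carpets store the largest delay at the top (row 1).
# Breakpoint times are regressed on the delay-ascending rank
# r = R - row, r = 0 for the earliest-arriving (bottom) row, so that an
# edge propagating in delay order has positive slope and positive transit
# time (a DSC bolus transit is positive by construction). Negative transit
# times mark edges tilted against the propagation direction.

#' Upper bound on the number of detectable edges
#'
#' An oscillation of frequency `f_max` can produce at most one rising (and
#' one falling) edge per period, so at most `floor(duration * f_max)` edges
#' of a given polarity fit in a scan.
#'
#' @param duration Scan duration in seconds.
#' @param f_max Highest oscillation frequency in Hz (0.1 Hz for the sLFO
#'   band).
#' @return Integer edge budget. Warns when the budget is zero.
#' @export
edge_budget <- function(duration, f_max) {
  stopifnot(duration > 0, f_max > 0)
  n <- as.integer(floor(duration * f_max + 1e-9))
  if (n == 0L) warning("no detectable oscillation fits in ", duration, " s")
  n
}

# Smoothed global signal and its central-difference time derivative.
global_derivative <- function(carpet, sigma_time = 2) {
  g <- conv1d(global_signal(carpet), gaussian_kernel(sigma_time))
  n <- length(g)
  d <- numeric(n)
  d[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) / (2 * carpet$dt)
  list(global = g, deriv = d)
}

#' Estimate candidate edge-center times
#'
#' Takes the first time-derivative of the row-averaged (global) carpet
#' signal and returns the times of its `n` largest positive local maxima
#' (rising polarity) or most negative local minima (falling), mutually
#' separated by at least `min_separation` seconds. Fewer than `n`
#' qualifying peaks returns what exists.
#'
#' @param carpet A `shag_carpet`.
#' @param n Maximum number of centers, typically [edge_budget()].
#' @param polarity `"rising"` or `"falling"`.
#' @param min_separation Minimum spacing between centers in seconds
#'   (default 5, half the shortest sLFO period).
#' @param sigma_time Gaussian smoothing (in samples) applied to the global
#'   signal before differentiation (default 2).
#' @return Numeric vector of center times in seconds, ascending.
#' @export
estimate_edge_centers <- function(carpet, n, polarity = c("rising", "falling"),
                                  min_separation = 5, sigma_time = 2) {
  polarity <- match.arg(polarity)
  stopifnot(n >= 1)
  gd <- global_derivative(carpet, sigma_time)
  d <- gd$deriv
  if (polarity == "rising") {
    idx <- local_extrema(d, "max")
    idx <- idx[d[idx] > 0]
    strength <- d[idx]
  } else {
    idx <- local_extrema(d, "min")
    idx <- idx[d[idx] < 0]
    strength <- -d[idx]
  }
  if (!length(idx)) return(numeric(0))
  times <- (idx - 1) * carpet$dt
  ord <- order(-strength)
  chosen <- numeric(0)
  for (i in ord) {
    if (all(abs(times[i] - chosen) >= min_separation)) {
      chosen <- c(chosen, times[i])
      if (length(chosen) >= n) break
    }
  }
  sort(chosen)
}

#' Detect one tilted edge and fit its transit time
#'
#' Implements the slope-detection algorithm around a single candidate
#' center: (1) blur the carpet with a separable 2D Gaussian; (2) apply a
#' horizontal (time-axis) central-difference derivative per row;
#' (3) restrict to columns within `window/2` of `center_time`; (4) record,
#' for every row, the time of the maximum derivative (minimum for falling
#' edges); (5) regress breakpoint time on delay-ascending row rank by
#' ordinary least squares. The slope (s per row) times `rows - 1` is the
#' transit time.
#'
#' @param carpet A `shag_carpet` (typically cropped).
#' @param center_time Candidate edge location in seconds (from
#'   [estimate_edge_centers()]).
#' @param polarity `"rising"` or `"falling"`.
#' @param window Full width of the searched time window in seconds;
#'   `NULL` (default) uses twice the half mean peak-to-peak interval of the
#'   global signal, capped at 10 s total.
#' @param sigma_time,sigma_row Gaussian blur standard deviations in samples
#'   (time axis) and rows (voxel axis); defaults 2 and 5.
#' @return One-row tibble: `center_time_s`, `polarity`, `slope_s_per_row`,
#'   `intercept_s` (fitted time at the earliest-delay row),
#'   `transit_time_s`, `r_squared`, plus a `points` list column holding the
#'   per-row breakpoints (`row`, `rank`, `time_s`).
#' @export
detect_edge <- function(carpet, center_time, polarity = c("rising", "falling"),
                        window = NULL, sigma_time = 2, sigma_row = 5) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(carpet, "shag_carpet"))
  window <- window %||% default_window(carpet, sigma_time)
  d <- carpet$data
  R <- nrow(d)
  nt <- ncol(d)
  sm <- blur2d(d, sigma_time, sigma_row)
  deriv <- matrix(0, R, nt)
  deriv[, 2:(nt - 1)] <- (sm[, 3:nt, drop = FALSE] -
                          sm[, 1:(nt - 2), drop = FALSE]) / (2 * carpet$dt)
  cols <- which(abs((seq_len(nt) - 1) * carpet$dt - center_time) <=
                  window / 2 + 1e-9)
  cols <- cols[cols >= 2L & cols <= nt - 1L]
  if (length(cols) < 3L)
    stop("degenerate search window: fewer than 3 usable columns")
  sub <- deriv[, cols, drop = FALSE]
  pick <- if (polarity == "rising") max.col(sub, ties.method = "first")
          else max.col(-sub, ties.method = "first")
  bp_time <- (cols[pick] - 1) * carpet$dt
  rank <- R - seq_len(R)                    # 0 = earliest (bottom) row
  fit <- stats::lm.fit(cbind(1, rank), bp_time)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((bp_time - mean(bp_time))^2)
  tibble::tibble(
    center_time_s = center_time,
    polarity = polarity,
    slope_s_per_row = slope,
    intercept_s = intercept,
    transit_time_s = slope * (R - 1),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    points = list(tibble::tibble(row = seq_len(R), rank = rank,
                                 time_s = bp_time))
  )
}

# Default search window: +/- half the mean peak-to-peak interval of the
# smoothed global signal, capped at +/- 5 s; must isolate one oscillation.
default_window <- function(carpet, sigma_time = 2) {
  g <- conv1d(global_signal(carpet), gaussian_kernel(sigma_time))
  pk <- local_extrema(g, "max")
  half <- if (length(pk) >= 2L) mean(diff(pk)) * carpet$dt / 2 else 5
  2 * min(half, 5)
}

#' Detect all edges of one polarity in a carpet
#'
#' Runs [estimate_edge_centers()] (capped at the [edge_budget()]) and fits
#' each candidate with [detect_edge()], then applies the inclusion rules of
#' [select_edges()].
#'
#' @inheritParams detect_edge
#' @param n_max Maximum number of edges; default
#'   `edge_budget(duration, f_max)`.
#' @param f_max Highest oscillation frequency in Hz used for the budget
#'   (default 0.1).
#' @param min_separation Passed to [estimate_edge_centers()].
#' @param contrast_floor,rate_floor Passed to [select_edges()].
#' @return An edge set: tibble of class `shag_edge_set`, one row per
#'   detected edge, sorted by center time, with inclusion flags; attributes
#'   record the detector parameters and carpet provenance.
#' @export
detect_edges <- function(carpet, polarity = c("rising", "falling"),
                         n_max = NULL, f_max = 0.1, window = NULL,
                         sigma_time = 2, sigma_row = 5, min_separation = 5,
                         contrast_floor = 0.2, rate_floor = NULL) {
  polarity <- match.arg(polarity)
  duration <- ncol(carpet$data) * carpet$dt
  n_max <- n_max %||% edge_budget(duration, f_max)
  if (n_max < 1L) return(empty_edge_set(carpet, polarity))
  centers <- estimate_edge_centers(carpet, n_max, polarity, min_separation,
                                   sigma_time)
  if (!length(centers)) return(empty_edge_set(carpet, polarity))
  edges <- purrr::map_dfr(centers, function(ct)
    detect_edge(carpet, ct, polarity, window, sigma_time, sigma_row))
  edges <- dplyr::mutate(edges, edge = dplyr::row_number(), .before = 1)
  edges <- select_edges(edges, carpet, contrast_floor, rate_floor,
                        sigma_time)
  structure(edges,
            class = unique(c("shag_edge_set", class(tibble::tibble()))),
            params = list(polarity = polarity, n_max = n_max,
                          sigma_time = sigma_time, sigma_row = sigma_row,
                          window = window, min_separation = min_separation,
                          contrast_floor = contrast_floor,
                          rate_floor = rate_floor),
            provenance = carpet$provenance)
}

empty_edge_set <- function(carpet, polarity) {
  structure(tibble::tibble(edge = integer(0), center_time_s = numeric(0),
                           polarity = character(0),
                           slope_s_per_row = numeric(0),
                           intercept_s = numeric(0),
                           transit_time_s = numeric(0),
                           r_squared = numeric(0), contrast = numeric(0),
                           rate = numeric(0), included = logical(0),
                           reason = character(0), points = list()),
            class = unique(c("shag_edge_set", class(tibble::tibble()))),
            params = list(polarity = polarity),
            provenance = carpet$provenance)
}

#' Apply the edge inclusion rules
#'
#' For each edge, the global-signal contrast is the difference between the
#' local extremum the edge leads into and the one it leaves: for a rising
#' edge, the following local maximum minus the preceding local minimum (the
#' reverse for falling). An edge is kept iff its contrast exceeds
#' `contrast_floor` (default 0.2, in scaled intensity units) and the
#' global-derivative magnitude at its center reaches `rate_floor` (default:
#' the 25th percentile of the qualifying derivative peaks). Excluded edges
#' are retained with their exclusion reason.
#'
#' @param edges Edge tibble from [detect_edge()] calls.
#' @param carpet The carpet the edges came from.
#' @param contrast_floor Minimum global-signal contrast (default 0.2).
#' @param rate_floor Minimum derivative magnitude at the edge center;
#'   `NULL` for the adaptive percentile default.
#' @param sigma_time Smoothing used for the global signal (default 2).
#' @return The edge tibble with `contrast`, `rate`, `included`, `reason`
#'   columns, sorted by center time.
#' @export
select_edges <- function(edges, carpet, contrast_floor = 0.2,
                         rate_floor = NULL, sigma_time = 2) {
  gd <- global_derivative(carpet, sigma_time)
  g <- gd$global
  d <- gd$deriv
  t_axis <- (seq_along(g) - 1) * carpet$dt
  maxima <- local_extrema(g, "max")
  minima <- local_extrema(g, "min")
  per_edge <- purrr::map_dfr(seq_len(nrow(edges)), function(i) {
    ct <- edges$center_time_s[i]
    rising <- edges$polarity[i] == "rising"
    ci <- which.min(abs(t_axis - ct))
    if (rising) {
      prev_ext <- minima[minima <= ci]
      next_ext <- maxima[maxima >= ci]
    } else {
      prev_ext <- maxima[maxima <= ci]
      next_ext <- minima[minima >= ci]
    }
    lead_val <- if (length(next_ext)) g[next_ext[1]] else g[length(g)]
    prev_val <- if (length(prev_ext)) g[prev_ext[length(prev_ext)]] else g[1]
    contrast <- if (rising) lead_val - prev_val else prev_val - lead_val
    nb <- max(1L, round(1 / carpet$dt / 4))   # small neighborhood
    win <- max(1L, ci - nb):min(length(d), ci + nb)
    rate <- if (rising) max(d[win]) else max(-d[win])
    tibble::tibble(contrast = contrast, rate = rate,
                   lead_value = lead_val)
  })
  edges$contrast <- per_edge$contrast
  edges$rate <- per_edge$rate
  edges$lead_value <- per_edge$lead_value
  if (is.null(rate_floor)) {
    pk <- if (all(edges$polarity == "falling"))
      -d[local_extrema(d, "min")] else d[local_extrema(d, "max")]
    pk <- pk[pk > 0]
    rate_floor <- if (length(pk)) unname(quantile(pk, 0.25)) else 0
  }
  edges$included <- edges$contrast > contrast_floor & edges$rate >= rate_floor
  edges$reason <- dplyr::case_when(
    edges$contrast <= contrast_floor ~ "contrast",
    edges$rate < rate_floor ~ "rate",
    TRUE ~ ""
  )
  dplyr::arrange(edges, .data$center_time_s)
}
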