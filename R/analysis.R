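# Transit-time summaries, the top-fraction global-intensity grouping, the
# rank-sum (Hodges-Lehmann) confidence interval for a difference of
# medians, and the rising-vs-falling polarity comparison.

#' Summarize transit times of an edge set
#'
#' @param edgeset An edge set from [detect_edges()]; only included edges
#'   contribute.
#' @return An object of class `transit_summary`: `n_edges`, `mean_s`,
#'   `sd_s` (`NA` for fewer than 2 edges), `negatives` (count of negative
#'   transit times) and the per-edge `table`.
#' @export
summarize_transits <- function(edgeset) {
  kept <- dplyr::filter(tibble::as_tibble(edgeset), .data$included)
  if (nrow(kept) == 0L) stop("no included edges to summarize")
  tt <- kept$transit_time_s
  structure(list(
    n_edges = length(tt),
    mean_s = mean(tt),
    sd_s = if (length(tt) >= 2L) sd(tt) else NA_real_,
    negatives = sum(tt < 0),
    table = kept[, setdiff(names(kept), "points")]
  ), class = "transit_summary")
}

#' @export
print.transit_summary <- function(x, ...) {
  cat(sprintf("<transit summary> %d edges: %.2f +/- %.2f s, %d negative\n",
              x$n_edges, x$mean_s, x$sd_s, x$negatives))
  invisible(x)
}

#' Group edges by the peak they lead into
#'
#' Splits included edges into a `top_fraction` group -- edges leading into
#' a local maximum of the global signal that lies within the top `fraction`
#' of all global-signal samples -- and a `remainder` group. The default
#' fraction of 0.15 follows the practice of thresholding the top 15% of
#' global BOLD intensities as the frames most likely to carry a neuronal
#' contribution.
#'
#' @param edgeset An edge set from [detect_edges()] (its `lead_value`
#'   column holds the extremum each edge leads into).
#' @param global Numeric vector: the global signal the threshold is taken
#'   over (use [global_signal()] of the same carpet).
#' @param fraction Top fraction in `(0, 1)` (default 0.15).
#' @return Tibble with columns `edge`, `transit_time_s`, `group`
#'   (`"top_fraction"` or `"remainder"`); attribute `threshold` records the
#'   cut value.
#' @export
group_top_fraction <- function(edgeset, global, fraction = 0.15) {
  stopifnot(fraction > 0, fraction < 1)
  kept <- dplyr::filter(tibble::as_tibble(edgeset), .data$included)
  thr <- unname(quantile(global, 1 - fraction))
  out <- tibble::tibble(
    edge = kept$edge,
    transit_time_s = kept$transit_time_s,
    group = ifelse(kept$lead_value > thr, "top_fraction", "remainder"))
  attr(out, "threshold") <- thr
  attr(out, "fraction") <- fraction
  out
}

#' Rank-sum confidence interval for a difference of medians
#'
#' Hodges-Lehmann style confidence interval for the location difference
#' between two independent samples: the interval is cut from the ordered
#' pairwise differences `a_i - b_j` at ranks derived from the normal
#' approximation of the Wilcoxon rank-sum `W` statistic (with continuity
#' correction). The point estimate is the median of the pairwise
#' differences.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return A list with `lo`, `hi`, `estimate`, `alpha`. Degenerate
#'   all-equal samples yield a zero-width interval with a warning.
#' @export
ranksum_median_ci <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  m <- length(a); n <- length(b)
  diffs <- sort(as.numeric(outer(a, b, "-")))
  mn <- m * n
  if (diffs[1] == diffs[mn]) {
    warning("all pairwise differences equal; zero-width interval")
    return(list(lo = diffs[1], hi = diffs[1], estimate = diffs[1],
                alpha = alpha))
  }
  z <- qnorm(1 - alpha / 2)
  se <- sqrt(mn * (m + n + 1) / 12)
  # cut rank of the normal approximation, continuity-corrected; clamped so
  # the interval always exists
  k <- floor(mn / 2 - z * se + 0.5)
  k <- min(max(k, 1L), floor(mn / 2))
  list(lo = diffs[k], hi = diffs[mn + 1 - k],
       estimate = median(diffs), alpha = alpha)
}

#' Compare rising- and falling-edge transit times
#'
#' Two-sample t test (Welch by default) between the included transit times
#' of two edge sets, as used to check that the choice of edge polarity does
#' not bias the transit-time distribution.
#'
#' @param rising,falling Edge sets from [detect_edges()].
#' @param pooled Use the pooled-variance (classic) t test instead of Welch.
#' @return Tibble with group means, standard deviations, sizes, the t
#'   statistic, degrees of freedom and two-sided p value.
#' @export
compare_polarity <- function(rising, falling, pooled = FALSE) {
  x <- dplyr::filter(tibble::as_tibble(rising), .data$included)$transit_time_s
  y <- dplyr::filter(tibble::as_tibble(falling), .data$included)$transit_time_s
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 included edges per group")
  ht <- stats::t.test(x, y, var.equal = pooled)
  tibble::tibble(
    mean_rising = mean(x), sd_rising = sd(x), n_rising = length(x),
    mean_falling = mean(y), sd_falling = sd(y), n_falling = length(y),
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value)
}

#' @export
tidy.shag_edge_set <- function(x, ...) {
  tibble::as_tibble(x)[, setdiff(names(x), "points")]
}

#' @export
glance.shag_edge_set <- function(x, ...) {
  kept <- x$transit_time_s[x$included]
  tibble::tibble(
    n_detected = nrow(x),
    n_included = sum(x$included),
    mean_transit_s = if (length(kept)) mean(kept) else NA_real_,
    sd_transit_s = if (length(kept) >= 2) sd(kept) else NA_real_,
    negatives = sum(kept < 0))
}

#' @export
tidy.transit_summary <- function(x, ...) x$table

#' @export
glance.transit_summary <- function(x, ...) {
  tibble::tibble(n_edges = x$n_edges, mean_s = x$mean_s, sd_s = x$sd_s,
                 negatives = x$negatives)
}

#' Broom-style generics
#'
#' `tidy()` returns the per-edge table of an edge set or summary;
#' `glance()` returns its one-row summary.
#'
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @return A tibble.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
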