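# SHAG carpet plots: voxel rows ordered by arrival delay, descending from
# the top, optionally cropped of the contiguous low-quality blocks that
# collect at the extremes of the ordering.

new_shag_carpet <- function(data, dt, order, delays_sorted, quality_sorted,
                            crop, n_removed, scaled, provenance = list()) {
  structure(list(data = data, dt = dt, order = order,
                 delays_sorted = delays_sorted,
                 quality_sorted = quality_sorted,
                 crop = crop, n_removed = n_removed, scaled = scaled,
                 provenance = provenance),
            class = "shag_carpet")
}

#' Build a SHAG carpet plot
#'
#' Sorts the rows of a scaled voxel matrix by their estimated arrival delay
#' in descending order -- the largest (latest) delay at the top row. Ties
#' are broken by ascending voxel id. Voxels flagged as unreliable by the
#' delay estimator still participate in the sort using their (unreliable)
#' delay, which stacks them at the extremes of the ordering; `NA` delays
#' sort to the very top.
#'
#' @param matrix A scaled [voxel_matrix()].
#' @param dmap A delay map covering exactly the matrix's voxels (see
#'   [rs_delays()], [dsc_ttp()], [co2_delays()]).
#' @return An object of class `shag_carpet`: fields `data` (rows x time),
#'   `order` (voxel id per row), `delays_sorted`, `quality_sorted`, `crop`
#'   (kept-row range in the pre-crop ordering), `n_removed`, `dt`.
#' @export
build_shag <- function(matrix, dmap) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  if (!matrix$scaled) stop("`matrix` must be scaled (see scale_demean())")
  if (!setequal(dmap$voxel_id, matrix$voxel_ids))
    stop("delay map and matrix cover different voxel sets")
  dm <- dmap[match(matrix$voxel_ids, dmap$voxel_id), ]
  ord <- order(-dm$delay_s, dm$voxel_id, na.last = FALSE)
  new_shag_carpet(
    data = matrix$data[ord, , drop = FALSE],
    dt = matrix$dt,
    order = matrix$voxel_ids[ord],
    delays_sorted = dm$delay_s[ord],
    quality_sorted = dm$quality[ord],
    crop = c(1L, nrow(matrix$data)),
    n_removed = 0L,
    scaled = matrix$scaled,
    provenance = list(method = attr(dmap, "method"),
                      reference = attr(dmap, "reference")))
}

#' Crop low-quality voxels from the carpet extremes
#'
#' Removes the maximal contiguous blocks at the top and bottom of the
#' sorted matrix consisting of voxels whose match quality is below
#' `quality_floor`. Interior low-quality voxels are retained: cropping only
#' ever removes continuous portions from the ends, mirroring how noisy
#' voxels with extreme delays pile up there.
#'
#' @param carpet An uncropped [build_shag()] carpet.
#' @param quality_floor Quality threshold (MCCC or fit R squared; default
#'   0.3).
#' @return The cropped `shag_carpet`; `crop` and `n_removed` updated.
#' @export
crop_shag <- function(carpet, quality_floor = 0.3) {
  stopifnot(inherits(carpet, "shag_carpet"))
  if (carpet$n_removed > 0L) stop("carpet is already cropped")
  q <- carpet$quality_sorted
  bad <- !is.finite(q) | q < quality_floor
  n <- length(bad)
  first <- 1L
  while (first <= n && bad[first]) first <- first + 1L
  last <- n
  while (last >= 1L && bad[last]) last <- last - 1L
  if (first > last || (n - (last - first + 1L)) > 0.9 * n)
    stop("quality floor too strict: crop would remove > 90% of rows")
  keep <- seq(first, last)
  carpet$data <- carpet$data[keep, , drop = FALSE]
  carpet$order <- carpet$order[keep]
  carpet$delays_sorted <- carpet$delays_sorted[keep]
  carpet$quality_sorted <- carpet$quality_sorted[keep]
  carpet$crop <- c(first, last)
  carpet$n_removed <- n - length(keep)
  carpet
}

#' Split a carpet by tissue class
#'
#' Partitions the carpet rows by predominant tissue type (e.g. gray matter,
#' white matter, CSF), preserving the within-tissue delay-descending order.
#' Voxels that fall in no mask are collected in an `unlabeled` carpet with
#' a warning.
#'
#' @param carpet A `shag_carpet`.
#' @param masks Named list of voxel-id vectors (0-based ids as used in
#'   [extract_matrix()]), e.g. `list(GM = ..., WM = ..., CSF = ...)`.
#' @return Named list of `shag_carpet` objects (empty tissues have zero
#'   rows); row counts sum to the input row count.
#' @export
split_by_tissue <- function(carpet, masks) {
  stopifnot(inherits(carpet, "shag_carpet"), is.list(masks),
            !is.null(names(masks)))
  assigned <- rep(NA_character_, length(carpet$order))
  for (nm in names(masks)) {
    hit <- carpet$order %in% masks[[nm]] & is.na(assigned)
    assigned[hit] <- nm
  }
  if (anyNA(assigned)) {
    warning(sum(is.na(assigned)), " voxels in no tissue mask; ",
            "assigned to 'unlabeled'")
    assigned[is.na(assigned)] <- "unlabeled"
  }
  out <- lapply(unique(c(names(masks), "unlabeled")), function(nm) {
    keep <- which(assigned == nm)
    sub <- carpet
    sub$data <- carpet$data[keep, , drop = FALSE]
    sub$order <- carpet$order[keep]
    sub$delays_sorted <- carpet$delays_sorted[keep]
    sub$quality_sorted <- carpet$quality_sorted[keep]
    sub$provenance$tissue <- nm
    sub
  })
  names(out) <- unique(c(names(masks), "unlabeled"))
  if (!"unlabeled" %in% assigned) out$unlabeled <- NULL
  out
}

#' Row-averaged (global) signal of a carpet
#'
#' @param carpet A `shag_carpet`.
#' @return Numeric vector: the carpet's column means, one value per time
#'   frame.
#' @export
global_signal <- function(carpet) {
  stopifnot(inherits(carpet, "shag_carpet"))
  colMeans(carpet$data)
}

#' @export
print.shag_carpet <- function(x, ...) {
  cat(sprintf(paste0(
    "<shag_carpet> %d rows x %d samples, dt = %g s, %d removed by crop\n",
    "  delays %0.2f .. %0.2f s (descending from top)\n"),
    nrow(x$data), ncol(x$data), x$dt, x$n_removed,
    max(x$delays_sorted, na.rm = TRUE), min(x$delays_sorted, na.rm = TRUE)))
  invisible(x)
}

#' Plot a SHAG carpet
#'
#' Grayscale heatmap with time on the x axis and delay-sorted rows on the y
#' axis (row 1, the largest delay, at the top), intensity limits symmetric
#' about zero for scaled data. Detected edges can be overlaid as red fitted
#' lines.
#'
#' @param object A `shag_carpet`.
#' @param edges Optional edge set from [detect_edges()]; included edges are
#'   drawn solid, excluded dashed.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.shag_carpet <- function(object, edges = NULL, ...) {
  d <- object$data
  lim <- max(abs(d))
  df <- tidyr::expand_grid(row = seq_len(nrow(d)),
                           col = seq_len(ncol(d)))
  df$time_s <- (df$col - 1) * object$dt
  df$intensity <- d[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-lim, lim)) +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "time (s)", y = "voxel (delay-sorted)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(edges) && nrow(edges) > 0) {
    R <- nrow(d)
    seg <- dplyr::mutate(
      edges,
      t_top = .data$intercept_s + .data$slope_s_per_row * (R - 1),
      t_bottom = .data$intercept_s)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t_bottom, xend = .data$t_top,
                   y = R, yend = 1,
                   linetype = .data$included),
      color = "red", linewidth = 0.4, inherit.aes = FALSE) +
      ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                                `FALSE` = "dashed"),
                                     guide = "none")
  }
  p
}

#' Render a carpet to a PNG file
#'
#' @param carpet A `shag_carpet`.
#' @param path Output PNG path.
#' @param edges Optional edge set to overlay.
#' @param width,height,dpi Device size in inches and resolution.
#' @return `path`, invisibly.
#' @export
render_carpet <- function(carpet, path, edges = NULL, width = 7,
                          height = 4, dpi = 150) {
  p <- autoplot.shag_carpet(carpet, edges = edges)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
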