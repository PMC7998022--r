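#' Voxel-by-time matrix
#'
#' The common substrate of every pipeline stage: one row per in-mask voxel,
#' one column per time frame, sample `i` taken at time `(i - 1) * dt`.
#'
#' @param data Numeric matrix, voxels x time.
#' @param dt Sampling interval in seconds (the TR for unresampled data).
#' @param voxel_ids Integer vector of voxel identifiers (0-based raster
#'   indices when extracted from a volume). Defaults to `0:(nrow - 1)`.
#' @param scaled Logical; `TRUE` once rows have been z-scored.
#' @param coords Optional tibble with columns `voxel_id`, `x`, `y`, `z`
#'   (0-based voxel coordinates) for mapping back into a volume.
#'
#' @return An object of class `voxel_matrix`.
#' @export
voxel_matrix <- function(data, dt, voxel_ids = NULL, scaled = FALSE,
                         coords = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 2L)
    stop("`data` must be a numeric matrix with >= 1 row and >= 2 columns")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number (seconds)")
  voxel_ids <- as.integer(voxel_ids %||% (seq_len(nrow(data)) - 1L))
  if (length(voxel_ids) != nrow(data))
    stop("`voxel_ids` length must equal the number of rows")
  if (anyDuplicated(voxel_ids)) stop("`voxel_ids` must be unique")
  structure(
    list(data = data, dt = dt, voxel_ids = voxel_ids,
         scaled = isTRUE(scaled), coords = coords),
    class = "voxel_matrix"
  )
}

#' @export
print.voxel_matrix <- function(x, ...) {
  cat(sprintf(
    "<voxel_matrix> %d voxels x %d samples, dt = %g s (%.1f s)%s\n",
    nrow(x$data), ncol(x$data), x$dt, ncol(x$data) * x$dt,
    if (x$scaled) ", scaled" else ""))
  invisible(x)
}

#' @export
dim.voxel_matrix <- function(x) dim(x$data)

#' Sample times of a voxel matrix
#'
#' @param x A [voxel_matrix()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
sample_times <- function(x) (seq_len(ncol(x$data)) - 1) * x$dt

#' Duration of a voxel matrix
#'
#' @param x A [voxel_matrix()].
#' @return Scan duration in seconds (`n_samples * dt`).
#' @export
vm_duration <- function(x) ncol(x$data) * x$dt
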