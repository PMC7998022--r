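# NIfTI volume I/O, voxel extraction in a documented raster order, and TSV
# serialization of regressors, delay maps, edge tables and voxel matrices.

#' 4D BOLD run
#'
#' Container for a 4D intensity array with its repetition time and brain
#' mask. Header/orientation metadata from a loaded NIfTI file is passed
#' through opaquely and reused on save.
#'
#' @param volume 4D numeric array `(x, y, z, t)`.
#' @param tr Repetition time in seconds.
#' @param mask 3D logical array matching the spatial dimensions; defaults to
#'   all voxels.
#' @param reference Optional NIfTI object to copy header metadata from.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(volume, tr, mask = NULL, reference = NULL) {
  if (length(dim(volume)) != 4L) stop("expected 4D volume (x, y, z, t)")
  if (dim(volume)[4] < 2L) stop("expected at least 2 time frames")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0 || !is.finite(tr))
    stop("`tr` must be a single positive number (seconds)")
  sp <- dim(volume)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), sp))
    stop("mask shape must match the spatial dimensions of the volume")
  if (!any(mask)) stop("mask contains no voxels")
  structure(list(volume = volume, tr = tr, mask = mask,
                 reference = reference),
            class = "bold_run")
}

#' Load a 4D BOLD NIfTI file
#'
#' @param path Path to a NIfTI-1/2 4D image.
#' @param mask_path Optional path to a 3D mask image (voxels with value
#'   `> 0` are in-mask).
#' @param tr Repetition time in seconds; when `NULL` it is read from the
#'   header (`pixdim[4]`), and a missing or non-positive header value is an
#'   error.
#' @return A [bold_run()].
#' @export
load_bold <- function(path, mask_path = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop(sprintf("expected 4D image, got %dD: %s", length(dim(img)), path))
  if (is.null(tr)) {
    pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
    tr <- if (length(pd) >= 4) pd[4] else NA_real_
    if (!is.finite(tr) || tr <= 0)
      stop("TR missing from NIfTI header; supply `tr` explicitly")
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    if (length(dim(m)) != 3L) stop("mask must be a 3D image")
    mask <- array(as.array(m) > 0, dim(m))
  }
  bold_run(as.array(img), tr = tr, mask = mask, reference = img)
}

#' Save a BOLD run as NIfTI
#'
#' @param run A [bold_run()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_bold <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$volume, reference = run$reference)
  vox <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  RNifti::pixdim(img) <- c(vox[1:3], run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract the in-mask voxel-by-time matrix
#'
#' Rows are ordered by a fixed raster scan of the mask: x fastest, then y,
#' then z (R's native array order), with 0-based voxel ids
#' `id = (x - 1) + nx * (y - 1) + nx * ny * (z - 1)`. The order is therefore
#' identical across runs of the same mask.
#'
#' @param run A [bold_run()].
#' @return A [voxel_matrix()] with `coords` mapping rows back to the volume.
#' @export
extract_matrix <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  sp <- dim(run$volume)[1:3]
  nt <- dim(run$volume)[4]
  lin <- which(run$mask)                       # column-major = x,y,z raster
  flat <- matrix(run$volume, prod(sp), nt)
  data <- flat[lin, , drop = FALSE]
  ijk <- arrayInd(lin, sp)
  coords <- tibble::tibble(voxel_id = lin - 1L,
                           x = ijk[, 1] - 1L, y = ijk[, 2] - 1L,
                           z = ijk[, 3] - 1L)
  voxel_matrix(data, dt = run$tr, voxel_ids = lin - 1L, coords = coords)
}

#' Write a voxel matrix back into a volume
#'
#' Inverse of [extract_matrix()]: places each row at its voxel id; voxels
#' outside the matrix are zero.
#'
#' @param matrix A [voxel_matrix()] extracted from `run`.
#' @param run The originating [bold_run()].
#' @return A [bold_run()] holding the reconstructed 4D volume.
#' @export
matrix_to_volume <- function(matrix, run) {
  stopifnot(inherits(matrix, "voxel_matrix"), inherits(run, "bold_run"))
  sp <- dim(run$volume)[1:3]
  nt <- ncol(matrix$data)
  flat <- matrix(0, prod(sp), nt)
  flat[matrix$voxel_ids + 1L, ] <- matrix$data
  bold_run(array(flat, c(sp, nt)), tr = matrix$dt, mask = run$mask,
           reference = run$reference)
}

#' Physiological regressor trace
#'
#' A sampled external reference signal, e.g. end-tidal CO2 in mmHg.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param values Measurement values.
#' @return A tibble with columns `time_s`, `value`, class `regressor_trace`.
#' @export
regressor_trace <- function(times, values) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (length(times) < 2L) stop("empty regressor: need at least 2 samples")
  if (any(diff(times) <= 0))
    stop("regressor time column must be strictly increasing (no duplicates)")
  structure(tibble::tibble(time_s = as.numeric(times),
                           value = as.numeric(values)),
            class = c("regressor_trace", "tbl_df", "tbl", "data.frame"))
}

#' Load a regressor trace from TSV/CSV
#'
#' Expects a header and two columns: time (seconds) and value.
#'
#' @param path File path; tab- or comma-separated.
#' @return A [regressor_trace()].
#' @export
load_regressor <- function(path) {
  first <- readLines(path, n = 2L)
  if (length(first) < 2L) stop("empty regressor: ", path)
  sep <- if (grepl(",", first[1])) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 2L) stop("regressor needs a time and a value column")
  regressor_trace(df[[1]], df[[2]])
}

#' Write a regressor trace
#' @param trace A [regressor_trace()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_regressor <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a voxel matrix to TSV
#'
#' One row per voxel with the sampling interval and scaling flag recorded on
#' a leading comment line, so the file round-trips through [read_matrix()].
#'
#' @param matrix A [voxel_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_s=%.17g scaled=%d", matrix$dt,
                     as.integer(matrix$scaled)), con)
  df <- data.frame(voxel_id = matrix$voxel_ids, matrix$data)
  names(df) <- c("voxel_id", sprintf("t%04d", seq_len(ncol(matrix$data)) - 1L))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @return `read_matrix()` returns the reconstructed [voxel_matrix()].
#' @export
read_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# dt_s=", hdr)) stop("not a voxel-matrix TSV: ", path)
  dt <- as.numeric(sub("^# dt_s=([^ ]+) .*$", "\\1", hdr))
  scaled <- sub("^.*scaled=([01])$", "\\1", hdr) == "1"
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  voxel_matrix(as.matrix(df[, -1, drop = FALSE]), dt = dt,
               voxel_ids = df$voxel_id, scaled = scaled)
}

#' Write / read a delay map as TSV
#'
#' Columns: `voxel_id`, optional `x,y,z`, `delay_s`, `quality`, `flagged`.
#' Estimator metadata (method, reference, grid resolution) is stored on a
#' leading comment line.
#'
#' @param dmap A delay map (see [rs_delays()]).
#' @param path File path.
#' @return `path` (write) or the delay map (read), invisibly/visibly.
#' @export
write_delay_map <- function(dmap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s resolution_s=%.17g reference=%s",
                     attr(dmap, "method"), attr(dmap, "resolution_s"),
                     gsub("\\s", "_", attr(dmap, "reference"))), con)
  utils::write.table(as.data.frame(dmap), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_delay_map
#' @export
read_delay_map <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# method=", hdr)) stop("not a delay-map TSV: ", path)
  df <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                            skip = 1L))
  new_delay_map(df,
                method = sub("^# method=([^ ]+) .*$", "\\1", hdr),
                reference = sub("^.*reference=(.*)$", "\\1", hdr),
                resolution_s = as.numeric(
                  sub("^.*resolution_s=([^ ]+) .*$", "\\1", hdr)))
}

#' Write / read an edge table as TSV
#'
#' Per-row breakpoints (a list column) are not serialized; all scalar edge
#' fields round-trip.
#'
#' @param edges An edge set (see [detect_edges()]).
#' @param path File path.
#' @return `path` (write) or an edge tibble (read).
#' @export
write_edges <- function(edges, path) {
  df <- as.data.frame(edges[, setdiff(names(edges), "points")])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
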