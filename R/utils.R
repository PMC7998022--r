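# Internal numerical helpers shared across modules.

#' @importFrom stats sd qnorm quantile median coef fitted rnorm runif setNames
#' @importFrom utils head tail
NULL

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Discrete Gaussian kernel, truncated at 4 sigma, unit sum. sigma = 0 gives
# the identity kernel.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# Reflect-pad a vector by np samples at each end (whole-sample reflection,
# end points not duplicated).
reflect_pad <- function(x, np) {
  n <- length(x)
  np <- min(np, n - 1L)
  c(x[seq(np + 1L, 2L)], x, x[seq(n - 1L, n - np)])
}

# Trim a kernel so its half-width fits inside a signal of length n, and
# renormalize. Needed when a blur sigma is large relative to a small image.
fit_kernel <- function(kernel, n) {
  half <- (length(kernel) - 1L) %/% 2L
  if (half <= n - 1L) return(kernel)
  keep <- seq(half + 1L - (n - 1L), half + 1L + (n - 1L))
  k <- kernel[keep]
  k / sum(k)
}

# Centered 1-D convolution with reflective boundary, same length as input.
conv1d <- function(x, kernel) {
  kernel <- fit_kernel(kernel, length(x))
  if (length(kernel) == 1L) return(x * kernel)
  half <- (length(kernel) - 1L) %/% 2L
  xp <- reflect_pad(x, half)
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(y)[seq(half + 1L, half + length(x))]
}

# Convolve every column of a matrix with `kernel`, reflective boundary.
conv_cols <- function(m, kernel) {
  kernel <- fit_kernel(kernel, nrow(m))
  if (length(kernel) == 1L) return(m * kernel)
  half <- (length(kernel) - 1L) %/% 2L
  np <- min(half, nrow(m) - 1L)
  top <- m[seq(np + 1L, 2L), , drop = FALSE]
  bot <- m[seq(nrow(m) - 1L, nrow(m) - np), , drop = FALSE]
  mp <- rbind(top, m, bot)
  y <- stats::filter(mp, kernel, method = "convolution", sides = 2)
  y <- matrix(as.numeric(y), nrow = nrow(mp), ncol = ncol(m))
  y[seq(np + 1L, np + nrow(m)), , drop = FALSE]
}

# Separable 2-D Gaussian blur of a rows (voxels) x columns (time) matrix.
blur2d <- function(m, sigma_time, sigma_row) {
  kt <- gaussian_kernel(sigma_time)
  kr <- gaussian_kernel(sigma_row)
  m <- conv_cols(m, kr)                       # along the voxel axis
  t(conv_cols(t(m), kt))                      # along the time axis
}

# Variance factor of (x - blur(x)) for white noise input: residual sd equals
# sigma * sqrt(1 - 2 k00 + sum(K^2)) for the separable kernel K = u v'.
blur_residual_factor <- function(sigma_time, sigma_row) {
  u <- gaussian_kernel(sigma_time)
  v <- gaussian_kernel(sigma_row)
  k00 <- u[(length(u) + 1L) %/% 2L] * v[(length(v) + 1L) %/% 2L]
  sqrt(max(1 - 2 * k00 + sum(u^2) * sum(v^2), .Machine$double.eps))
}

# Normalized (Pearson, truncated-overlap) cross-correlation of every row of X
# against the reference y, over lags -max_lag..max_lag in steps of dt.
# Positive lag means the row arrives *later* than the reference
# (row[t] ~ y[t - lag]). Returns list(lags, cc) with cc voxels x lags.
xcorr_map <- function(X, y, dt, max_lag) {
  n <- ncol(X)
  stopifnot(length(y) == n)
  kmax <- floor(max_lag / dt + 1e-9)
  if (kmax >= n - 2L) stop("max_lag too large for the series length")
  ks <- seq(-kmax, kmax)
  Sx <- t(apply(X, 1L, cumsum))
  Sx2 <- t(apply(X^2, 1L, cumsum))
  Sy <- cumsum(y)
  Sy2 <- cumsum(y^2)
  cc <- matrix(NA_real_, nrow(X), length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    if (k >= 0) {
      ix <- seq(k + 1L, n)          # x indices
      iy <- seq(1L, n - k)          # y indices
      sx <- Sx[, n] - (if (k > 0) Sx[, k] else 0)
      sx2 <- Sx2[, n] - (if (k > 0) Sx2[, k] else 0)
      sy <- Sy[n - k]
      sy2 <- Sy2[n - k]
    } else {
      a <- -k
      ix <- seq(1L, n - a)
      iy <- seq(a + 1L, n)
      sx <- Sx[, n - a]
      sx2 <- Sx2[, n - a]
      sy <- Sy[n] - Sy[a]
      sy2 <- Sy2[n] - Sy2[a]
    }
    nk <- length(ix)
    cross <- as.numeric(X[, ix, drop = FALSE] %*% y[iy])
    num <- cross - sx * sy / nk
    den <- sqrt(pmax(sx2 - sx^2 / nk, 0) * max(sy2 - sy^2 / nk, 0))
    cc[, j] <- ifelse(den > 0, num / den, 0)
  }
  list(lags = ks * dt, cc = cc)
}

# Indices of strict local maxima (or minima) of a vector, excluding ends.
local_extrema <- function(x, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") x <- -x
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- seq(2L, n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
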