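# Shared fixtures, built in code at test time.

rs_spec_small <- function(n_voxels = 60, noise_sd = 0, seed = 3,
                          span = 4.5, ...) {
  phantom_spec("rs", n_voxels = n_voxels, duration = 360, tr = 0.72,
               delay_model = delay_linear_span(span), noise_sd = noise_sd,
               seed = seed, ...)
}

dsc_spec_small <- function(n_voxels = 30, noise_sd = 0, seed = 5, ...) {
  phantom_spec("dsc", n_voxels = n_voxels, duration = 180, tr = 1.5,
               delay_model = delay_linear_span(4.2), noise_sd = noise_sd,
               seed = seed,
               modality_params = list(t0 = 60, tp = 4, depth = 3), ...)
}

co2_spec_small <- function(n_voxels = 40, noise_sd = 0, seed = 9, ...) {
  phantom_spec("co2", n_voxels = n_voxels, duration = 600, tr = 1,
               delay_model = delay_linear_span(5.0), noise_sd = noise_sd,
               seed = seed, ...)
}

# A clean synthetic carpet with one perfectly linear rising edge: row of
# rank r steps from -a to +a at time t_edge + transit * r / (R - 1),
# sampled at dt. Rows stored latest-arrival-on-top like a real carpet.
linear_edge_carpet <- function(n_rows = 120, n_time = 200, dt = 0.5,
                               t_edge = 40, transit = 4.5, amplitude = 1,
                               noise_sd = 0, seed = 1) {
  ranks <- seq_len(n_rows) - 1L
  event <- t_edge + transit * ranks / (n_rows - 1)
  t_samp <- (seq_len(n_time) - 1) * dt
  img <- t(vapply(event, function(e)
    amplitude * (2 * as.numeric(t_samp >= e) - 1), numeric(n_time)))
  img <- img[rev(seq_len(n_rows)), , drop = FALSE]
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(length(img), sd = noise_sd),
                        nrow(img), ncol(img))
  }
  carpet <- shagcarpet:::new_shag_carpet(
    data = img, dt = dt, order = seq_len(n_rows) - 1L,
    delays_sorted = rev(event), quality_sorted = rep(1, n_rows),
    crop = c(1L, n_rows), n_removed = 0L, scaled = TRUE)
  attr(carpet, "true_transit") <- transit
  attr(carpet, "t_edge") <- t_edge
  carpet
}

# Brute-force transit oracle for a noiseless single-edge image: per row,
# the first sample at/after the known event time, fitted directly.
breakpoint_fit_oracle <- function(carpet) {
  d <- carpet$data
  R <- nrow(d)
  bp <- apply(d, 1L, function(row) {
    j <- which(diff(row) != 0)
    (j[1] + 1 - 1) * carpet$dt   # first sample after the step, time of col j+1
  })
  rank <- R - seq_len(R)
  fit <- stats::lm(bp ~ rank)
  unname(coef(fit)[2]) * (R - 1)
}
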