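test_that("single-frequency shifts of +/- one TR are recovered exactly", {
  # three voxels: a 0.05 Hz sinusoid shifted by {-0.72, 0, +0.72} s; the
  # symmetric phasor sum makes the global mean the zero-delay reference,
  # and 0.72 s is exactly 10 steps of the 0.072 s delay grid
  dt <- 0.72
  t <- seq(0, 360 - dt, by = dt)
  shifts <- c(-0.72, 0, 0.72)
  m <- t(vapply(shifts, function(s) sin(2 * pi * 0.05 * (t - s)),
                numeric(length(t))))
  vm <- scale_demean(voxel_matrix(m, dt))
  dm <- rs_delays(vm)
  expect_equal(dm$delay_s, shifts, tolerance = 1e-9)
  expect_true(all(dm$quality > 0.99))
})

test_that("identical voxels give zero delay and unit MCCC", {
  dt <- 0.72
  t <- seq(0, 360 - dt, by = dt)
  m <- matrix(rep(sin(2 * pi * 0.04 * t), 5), nrow = 5, byrow = TRUE)
  dm <- rs_delays(scale_demean(voxel_matrix(m, dt)))
  expect_equal(dm$delay_s, rep(0, 5))
  expect_equal(dm$quality, rep(1, 5), tolerance = 1e-6)
})

test_that("rs delays recover a noiseless linear span on the 0.072 s grid", {
  ph <- make_phantom(rs_spec_small(n_voxels = 60))
  dm <- rs_delays(scale_demean(ph$matrix))
  truth <- ph$truth$delays
  expect_equal(cor(dm$delay_s, truth, method = "spearman"), 1)
  centered_err <- (dm$delay_s - mean(dm$delay_s)) - (truth - mean(truth))
  expect_lte(max(abs(centered_err)), 0.072)
  expect_error(rs_delays(scale_demean(ph$matrix), max_lag = 200), "max_lag")
})

test_that("dsc TTP equals the analytic gamma-variate extremum", {
  # noiseless dips: TTP = t0 + tp, read on the 0.0001 s grid
  tr <- 1.5
  t <- seq(0, 180 - tr, by = tr)
  m <- rbind(-3 * gamma_variate(t, 10, 4),
             -3 * gamma_variate(t, 10, 6))
  dm <- dsc_ttp(voxel_matrix(m, tr))
  expect_equal(dm$delay_s[1], 14, tolerance = 1e-4)
  expect_equal(dm$delay_s[2] - dm$delay_s[1], 2, tolerance = 2e-4)
  expect_true(all(!dm$flagged))
})

test_that("dsc TTP is robust to noise at 10% of dip depth", {
  ph <- make_phantom(dsc_spec_small(n_voxels = 30, noise_sd = 0.3, seed = 21))
  dm <- dsc_ttp(ph$matrix)
  good <- !dm$flagged
  expect_gt(mean(good), 0.9)
  err <- dm$delay_s[good] - (64 + ph$truth$delays[good])
  expect_lt(sqrt(mean(err^2)), 1.5 / 2)          # RMSE < tr/2
})

test_that("flat voxels without a dip are flagged, not fitted", {
  tr <- 1.5
  t <- seq(0, 180 - tr, by = tr)
  set.seed(4)
  m <- rbind(-3 * gamma_variate(t, 10, 4), rnorm(length(t), sd = 0.05))
  dm <- dsc_ttp(voxel_matrix(m, tr))
  expect_false(dm$flagged[1])
  expect_true(dm$flagged[2])
})

test_that("co2 delays read a pure regressor shift on the 0.1 s grid", {
  spec <- co2_spec_small(n_voxels = 4)
  et <- phantom_etco2(spec)
  dt <- 1
  t <- seq(0, 600 - dt, by = dt)
  base <- approx(et$time_s, et$value, xout = t, rule = 2)$y
  shifts <- c(0, 1, 3, 7.5)
  m <- t(vapply(shifts, function(s)
    approx(et$time_s, et$value, xout = t - s, rule = 2)$y,
    numeric(length(t))))
  dm <- co2_delays(scale_demean(voxel_matrix(m, dt)), et)
  rel <- dm$delay_s - dm$delay_s[1]
  expect_equal(rel, shifts, tolerance = 0.1 + 1e-9)
})

test_that("co2 phantom delay span is recovered within 0.2 s", {
  spec <- co2_spec_small(n_voxels = 40)
  ph <- make_phantom(spec)
  dm <- co2_delays(scale_demean(ph$matrix), phantom_etco2(spec))
  est_span <- max(dm$delay_s) - min(dm$delay_s)
  expect_lt(abs(est_span - ph$truth$true_transit_time), 0.2 + 1e-9)
  expect_equal(cor(dm$delay_s, ph$truth$delays, method = "spearman"), 1)
})

test_that("pure-noise voxels fall below the MCCC quality floor", {
  spec <- co2_spec_small(n_voxels = 30, noise_sd = 0.4, seed = 17,
                         noise_voxel_fraction = 0.2)
  ph <- make_phantom(spec)
  dm <- co2_delays(scale_demean(ph$matrix), phantom_etco2(spec))
  is_noise <- ph$matrix$voxel_ids %in% ph$truth$noise_voxel_ids
  expect_true(all(dm$flagged[is_noise]))
  expect_true(all(!dm$flagged[!is_noise]))
})

test_that("cross-correlation lag is antisymmetric in its arguments", {
  set.seed(6)
  x <- as.numeric(arima.sim(list(ar = 0.9), 500))
  y <- c(rep(0, 4), x[1:496])                     # y = x delayed by 4 samples
  a <- shagcarpet:::xcorr_map(rbind(y), x, 1, 20)
  b <- shagcarpet:::xcorr_map(rbind(x), y, 1, 20)
  la <- a$lags[which.max(a$cc)]
  lb <- b$lags[which.max(b$cc)]
  expect_equal(la, 4)
  expect_equal(lb, -4)
})
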