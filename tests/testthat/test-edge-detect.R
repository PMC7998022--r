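test_that("edge budget is floor(duration x f_max)", {
  expect_identical(edge_budget(360, 0.1), 36L)
  expect_identical(edge_budget(100, 0.05), 5L)
  expect_warning(b <- edge_budget(10, 0.01), "no detectable")
  expect_identical(b, 0L)
})

test_that("edge centers land on step changes and sinusoid rise points", {
  # a single synchronized step in every row
  cp <- linear_edge_carpet(n_rows = 50, n_time = 300, dt = 0.5,
                           t_edge = 100, transit = 0)
  ctr <- estimate_edge_centers(cp, 5, "rising")
  expect_length(ctr, 1)
  expect_lt(abs(ctr - 100), 2 * cp$dt)

  # pure 0.05 Hz global sinusoid: rising centers at derivative maxima,
  # spaced one 20 s period apart
  dt <- 0.5
  t <- seq(0, 360 - dt, by = dt)
  m <- matrix(rep(sin(2 * pi * 0.05 * t), 40), nrow = 40, byrow = TRUE)
  cps <- shagcarpet:::new_shag_carpet(m, dt, 0:39, rep(0, 40), rep(1, 40),
                                      c(1L, 40L), 0L, TRUE)
  ctr2 <- estimate_edge_centers(cps, 18, "rising")
  expect_gte(length(ctr2), 16)
  # interior spacing one full period; the first peak may sit clipped at the
  # record boundary
  expect_true(all(abs(diff(ctr2[-1]) - 20) <= 2 * dt))

  # flat carpet yields nothing
  flat <- shagcarpet:::new_shag_carpet(matrix(0, 5, 50), dt, 0:4, rep(0, 5),
                                       rep(1, 5), c(1L, 5L), 0L, TRUE)
  expect_length(estimate_edge_centers(flat, 3, "rising"), 0)
})

test_that("a clean linear edge yields its transit within the TR envelope", {
  # dt fine enough that breakpoint quantization (var dt^2/12) does not
  # dominate the fit residual
  cp <- linear_edge_carpet(n_rows = 400, n_time = 400, transit = 4.5,
                           dt = 0.25)
  e <- detect_edge(cp, center_time = attr(cp, "t_edge") + 2.25, "rising",
                   window = 4.5 + 8 * cp$dt)
  expect_lt(abs(e$transit_time_s - 4.5), 0.25)   # within the dt envelope
  expect_gt(e$r_squared, 0.99)
  expect_equal(nrow(e$points[[1]]), 400)
})

test_that("vertical edges give zero transit and reversed tilt negative", {
  cp <- linear_edge_carpet(n_rows = 100, transit = 0, t_edge = 50)
  e <- detect_edge(cp, 50, "rising")
  expect_lt(abs(e$transit_time_s), cp$dt)
  # flipping the rows reverses the tilt -> negative transit
  cp2 <- linear_edge_carpet(n_rows = 100, transit = 4.5, t_edge = 40)
  cp2$data <- cp2$data[rev(seq_len(nrow(cp2$data))), ]
  e2 <- detect_edge(cp2, 42.25, "rising", window = 4.5 + 8 * cp2$dt)
  expect_lt(e2$transit_time_s, -3.5)
})

test_that("detector equals the direct breakpoint-fit oracle on clean edges", {
  for (transit in c(2.0, 4.5)) {
    cp <- linear_edge_carpet(n_rows = 300, transit = transit, dt = 0.5,
                             t_edge = 40.21)
    oracle <- breakpoint_fit_oracle(cp)
    e <- detect_edge(cp, 40.21 + transit / 2, "rising",
                     window = transit + 8 * cp$dt, sigma_row = 0)
    expect_lt(abs(e$transit_time_s - oracle), cp$dt)
  }
})

test_that("transit is equivariant to time shifts and stable to row thinning", {
  cp <- linear_edge_carpet(n_rows = 300, n_time = 300, transit = 4.5,
                           t_edge = 40, dt = 0.5)
  e <- detect_edge(cp, 42.25, "rising", window = 9)
  # shift the whole carpet by +10 s (20 columns)
  shifted <- cp
  shifted$data <- cbind(matrix(-1, 300, 20),
                        cp$data[, 1:(ncol(cp$data) - 20)])
  es <- detect_edge(shifted, 52.25, "rising", window = 9)
  expect_equal(es$transit_time_s, e$transit_time_s, tolerance = 0.02)
  expect_equal(es$intercept_s - e$intercept_s, 10, tolerance = 0.2)
  # drop every other row: transit changes by < 5%
  half <- cp
  keep <- seq(1, 300, by = 2)
  half$data <- cp$data[keep, ]
  half$delays_sorted <- cp$delays_sorted[keep]
  half$quality_sorted <- cp$quality_sorted[keep]
  half$order <- cp$order[keep]
  eh <- detect_edge(half, 42.25, "rising", window = 9)
  expect_lt(abs(eh$transit_time_s - e$transit_time_s) /
              abs(e$transit_time_s), 0.05)
})

test_that("breakpoint fit quality degrades monotonically with noise", {
  r2 <- vapply(c(0.1, 0.5, 1.0, 2.0), function(s) {
    mean(vapply(1:5, function(i) {
      cp <- linear_edge_carpet(n_rows = 150, transit = 4.5, t_edge = 40,
                               noise_sd = s, seed = 100 + i)
      detect_edge(cp, 42.25, "rising", window = 9)$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r2) < 0.05))              # non-increasing within MC noise
})

test_that("inclusion rules enforce the 0.2 contrast floor", {
  dt <- 0.72
  t <- seq(0, 360 - dt, by = dt)
  # strong 0.05 Hz oscillation plus one weak oscillation segment
  g <- sin(2 * pi * 0.05 * t)
  m <- matrix(rep(g, 30), nrow = 30, byrow = TRUE) * 0.6
  cp <- shagcarpet:::new_shag_carpet(m, dt, 0:29, rep(0, 30), rep(1, 30),
                                     c(1L, 30L), 0L, TRUE)
  ed <- detect_edges(cp, "rising", contrast_floor = 0.2, rate_floor = 0)
  expect_true(all(ed$included))
  expect_true(all(ed$contrast > 0.2))
  # scale the carpet so peak-to-trough contrast drops below the floor
  weak <- cp
  weak$data <- m * 0.08
  edw <- detect_edges(weak, "rising", contrast_floor = 0.2, rate_floor = 0)
  expect_true(all(!edw$included))
  expect_true(all(edw$reason == "contrast"))
  # edge count respects the budget
  expect_lte(nrow(ed), edge_budget(360, 0.1))
})

test_that("phantom oscillation peaks produce one included edge per cycle", {
  ph <- make_phantom(phantom_spec("rs", n_voxels = 80, duration = 360,
                                  tr = 0.72,
                                  delay_model = delay_linear_span(4.5),
                                  seed = 31,
                                  modality_params = list(
                                    freqs = 0.04, amps = 1, phases = 0)))
  sc <- scale_demean(ph$matrix)
  cp <- crop_shag(build_shag(sc, rs_delays(sc)))
  ed <- detect_edges(cp, "rising", rate_floor = 0)
  # a 0.04 Hz oscillation has ~14 full rising edges in 360 s
  expect_gte(sum(ed$included), 12)
  expect_lte(sum(ed$included), edge_budget(360, 0.1))
})
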