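fake_dmap <- function(ids, delays, quality = rep(1, length(ids)),
                      floor = 0.3) {
  shagcarpet:::new_delay_map(
    tibble::tibble(voxel_id = ids, delay_s = delays, quality = quality,
                   flagged = quality < floor),
    method = "rs_mccc", reference = "test", resolution_s = 0.072)
}

test_that("rows sort by descending delay with voxel-id tie-break", {
  m <- scale_demean(voxel_matrix(matrix(rnorm(30), 3, 10), dt = 1,
                                 voxel_ids = 0:2))
  cp <- build_shag(m, fake_dmap(0:2, c(1, 3, 2)))
  expect_equal(cp$order, c(1L, 2L, 0L))
  expect_equal(cp$delays_sorted, c(3, 2, 1))
  cp2 <- build_shag(m, fake_dmap(0:2, c(2, 2, 2)))
  expect_equal(cp2$order, 0:2)
  expect_error(build_shag(m, fake_dmap(5:7, c(1, 2, 3))), "voxel sets")
})

test_that("sorting is a pure permutation and recovers true rank order", {
  ph <- make_phantom(rs_spec_small(n_voxels = 60))
  sc <- scale_demean(ph$matrix)
  dm <- rs_delays(sc)
  cp <- build_shag(sc, dm)
  expect_equal(sort(cp$order), sort(sc$voxel_ids))
  expect_equal(sort(as.numeric(cp$data)), sort(as.numeric(sc$data)))
  # noiseless linear span: sorted order equals the true delay rank order
  truth <- ph$truth$delays[match(cp$order, sc$voxel_ids)]
  expect_equal(truth, sort(truth, decreasing = TRUE))  # descending down rows
  expect_true(all(diff(cp$delays_sorted) <= 0))
})

test_that("crop removes only contiguous extreme low-quality blocks", {
  m <- scale_demean(voxel_matrix(matrix(rnorm(100), 10, 10), dt = 1,
                                 voxel_ids = 0:9))
  q <- c(0.1, 0.2, 0.9, 0.8, 0.1, 0.9, 0.7, 0.9, 0.05, 0.1)
  dm <- fake_dmap(0:9, delays = 10:1, quality = q)
  cp <- crop_shag(build_shag(m, dm), quality_floor = 0.3)
  expect_equal(cp$crop, c(3L, 8L))
  expect_equal(cp$n_removed, 4L)
  expect_equal(nrow(cp$data), 6)
  # the interior low-quality voxel (rank 5) is retained
  expect_true(0.1 %in% cp$quality_sorted)
  # floor of -1 removes nothing; all-good map is the identity crop
  cp0 <- crop_shag(build_shag(m, dm), quality_floor = -1)
  expect_equal(cp0$n_removed, 0L)
  expect_error(crop_shag(build_shag(m, dm), quality_floor = 1.1),
               "too strict")
})

test_that("phantom noise voxels are cropped from the extremes", {
  spec <- rs_spec_small(n_voxels = 80, noise_sd = 0.35, seed = 19,
                        noise_voxel_fraction = 0.25)
  ph <- make_phantom(spec)
  sc <- scale_demean(ph$matrix)
  dm <- rs_delays(sc)
  cp <- crop_shag(build_shag(sc, dm))
  frac_removed <- cp$n_removed / 80
  expect_gte(frac_removed, 0.10)
  expect_lte(frac_removed, 0.35)
  removed_ids <- setdiff(sc$voxel_ids, cp$order)
  expect_gte(mean(removed_ids %in% ph$truth$noise_voxel_ids), 0.9)
})

test_that("tissue split preserves order and partitions rows", {
  ph <- make_phantom(rs_spec_small(n_voxels = 30))
  sc <- scale_demean(ph$matrix)
  cp <- build_shag(sc, rs_delays(sc))
  masks <- list(GM = 0:14, WM = 15:24, CSF = 25:29)
  parts <- split_by_tissue(cp, masks)
  expect_named(parts, c("GM", "WM", "CSF"))
  expect_equal(sum(vapply(parts, function(p) nrow(p$data), 0L)), 30L)
  for (p in parts) expect_true(all(diff(p$delays_sorted) <= 0))
  all_gm <- split_by_tissue(cp, list(GM = 0:29))
  expect_equal(all_gm$GM$data, cp$data)
  expect_warning(split_by_tissue(cp, list(GM = 0:10)), "unlabeled")
})

test_that("rendering writes a valid PNG with symmetric limits", {
  ph <- make_phantom(rs_spec_small(n_voxels = 30))
  sc <- scale_demean(ph$matrix)
  cp <- crop_shag(build_shag(sc, rs_delays(sc)))
  ed <- detect_edges(cp, "rising")
  f <- tempfile(fileext = ".png")
  render_carpet(cp, f, edges = ed, width = 4, height = 3)
  expect_true(file.exists(f))
  expect_identical(readBin(f, "raw", 8),
                   as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
  p <- autoplot(cp)
  lims <- p$scales$get_scales("fill")$limits
  expect_equal(lims[1], -lims[2])
})

test_that("post-sort event times are linear in row on a noiseless phantom", {
  ph <- make_phantom(rs_spec_small(n_voxels = 60))
  sc <- scale_demean(ph$matrix)
  cp <- build_shag(sc, rs_delays(sc))
  # the true event alignment: delays sorted down rows regress perfectly
  fit <- lm(cp$delays_sorted ~ seq_along(cp$delays_sorted))
  expect_gt(summary(fit)$r.squared, 0.999)
})
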