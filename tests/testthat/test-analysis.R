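edge_set_from <- function(transits) {
  n <- length(transits)
  structure(tibble::tibble(
    edge = seq_len(n), center_time_s = seq_len(n) * 10,
    polarity = "rising", slope_s_per_row = transits / 99,
    intercept_s = 0, transit_time_s = transits, r_squared = 0.9,
    contrast = 1, rate = 1, lead_value = 1, included = TRUE, reason = "",
    points = replicate(n, tibble::tibble(), simplify = FALSE)),
    class = unique(c("shag_edge_set", class(tibble::tibble()))))
}

test_that("transit summaries report mean, sd and negative count", {
  s <- summarize_transits(edge_set_from(c(4, 4, 4)))
  expect_equal(s$mean_s, 4)
  expect_equal(s$sd_s, 0)
  expect_equal(s$negatives, 0)
  s2 <- summarize_transits(edge_set_from(c(3, -1)))
  expect_equal(s2$negatives, 1)
  es <- edge_set_from(c(1, 2))
  es$included <- FALSE
  expect_error(summarize_transits(es), "no included edges")
  g <- glance(edge_set_from(c(3, -1)))
  expect_equal(g$negatives, 1)
  expect_equal(g$n_included, 2)
})

test_that("end-to-end phantom transit matches truth within the TR envelope", {
  ph <- make_phantom(rs_spec_small(n_voxels = 150, noise_sd = 0.15,
                                   seed = 23))
  sc <- scale_demean(ph$matrix)
  cp <- crop_shag(build_shag(sc, rs_delays(sc)))
  ed <- detect_edges(cp, "rising")
  s <- summarize_transits(ed)
  expect_gte(s$n_edges, 5)
  expect_lt(abs(s$mean_s - 4.5), 0.6)
})

test_that("top-fraction grouping keys on the peak an edge leads into", {
  es <- edge_set_from(c(4, 3, 5))
  es$lead_value <- c(0.2, 0.9, 0.3)
  g <- seq(0, 1, length.out = 101)     # 85th percentile threshold = 0.85
  grp <- group_top_fraction(es, g, fraction = 0.15)
  expect_equal(grp$group, c("remainder", "top_fraction", "remainder"))
  grp_all <- group_top_fraction(es, g, fraction = 0.999)
  expect_true(all(grp_all$group == "top_fraction"))
  # near-zero fraction: threshold above every lead value
  grp_none <- group_top_fraction(es, c(g, 2), fraction = 0.001)
  expect_true(all(grp_none$group == "remainder"))
})

test_that("rank-sum CI is shift-equivariant and contains obvious values", {
  a <- c(1, 2, 3, 7, 5)
  b <- c(2, 1, 3, 5, 4)
  ci <- ranksum_median_ci(a, b)
  expect_true(ci$lo <= 0 && 0 <= ci$hi)
  ci2 <- ranksum_median_ci(a + 2, b)
  expect_equal(ci2$lo, ci$lo + 2)
  expect_equal(ci2$hi, ci$hi + 2)
  expect_warning(z <- ranksum_median_ci(c(1, 1), c(1, 1)), "zero-width")
  expect_equal(c(z$lo, z$hi), c(0, 0))
})

test_that("CI endpoints equal exact rank-sum enumeration for small samples", {
  # wilcox.test with exact=TRUE enumerates the exact null distribution of W
  set.seed(14)
  for (m in c(3, 4, 5)) for (n in c(4, 5)) {
    a <- rnorm(m, 5, 2)
    b <- rnorm(n, 3, 2)
    ci <- ranksum_median_ci(a, b)
    wt <- suppressWarnings(wilcox.test(a, b, conf.int = TRUE, exact = TRUE))
    expect_equal(c(ci$lo, ci$hi), as.numeric(wt$conf.int), tolerance = 1e-12)
  }
})

test_that("95% CI coverage sits in the nominal band over 1000 simulations", {
  set.seed(5)
  true_shift <- 1.2
  cov <- mean(replicate(1000, {
    a <- rnorm(15, 3 + true_shift, 1.5)
    b <- rnorm(15, 3, 1.5)
    ci <- ranksum_median_ci(a, b)
    ci$lo <= true_shift && true_shift <= ci$hi
  }))
  expect_gte(cov, 0.93)
  expect_lte(cov, 0.97)
})

test_that("polarity comparison reduces to the two-sample t test", {
  r <- edge_set_from(c(4.1, 3.9, 4.0, 4.2))
  f <- edge_set_from(c(4.1, 3.9, 4.0, 4.2))
  res <- compare_polarity(r, f)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  f2 <- edge_set_from(c(1.0, 1.1, 0.9, 1.0))
  res2 <- compare_polarity(r, f2)
  expect_lt(res2$p_value, 0.01)
  # agrees with a permutation test within 0.05
  set.seed(7)
  x <- c(4.5, 3.2, 4.8, 3.9, 4.1, 2.8)
  y <- c(3.8, 3.1, 4.0, 3.3, 3.6)
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  perm <- replicate(4000, {
    i <- sample(11, 6)
    mean(pool[i]) - mean(pool[-i])
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  p_t <- compare_polarity(edge_set_from(x), edge_set_from(y))$p_value
  expect_lt(abs(p_perm - p_t), 0.05)
  short <- edge_set_from(3)
  expect_error(compare_polarity(short, f), "at least 2")
})
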