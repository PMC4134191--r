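wrap_values <- function(v, dm = NULL) {
  # embed a vector into a minimal volume + all-true mask
  if (is.null(dm)) {
    n <- length(v)
    dm <- c(n, 2, 2)
    v <- rep(v, 4)
  }
  list(vol = image_volume(array(v, dm), c(1, 1, 1), units = "a.u."),
       mask = roi_mask(array(TRUE, dm), c(1, 1, 1)))
}

test_that("region statistics match hand and brute-force computation", {
  vol <- image_volume(array(0, c(5, 2, 2)) + c(1, 2, 3, 4, 5), c(1, 1, 1))
  mv <- array(FALSE, c(5, 2, 2))
  mv[, 1, 1] <- TRUE  # one column holding exactly {1, 2, 3, 4, 5}
  mask <- roi_mask(mv, c(1, 1, 1))
  st <- region_stats(vol, mask)
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sd(c(1, 2, 3, 4, 5)))
  expect_equal(round(st$sd, 4), 1.5811)
  expect_equal(round(st$cv, 3), 0.527)
  expect_equal(st$median, 3)

  for (seed in 1:5) {
    v <- withr::with_seed(seed, runif(7 * 6 * 5, 1, 9))
    mv <- withr::with_seed(seed + 50,
                           array(runif(210) > 0.4, c(7, 6, 5)))
    if (sum(mv) < 2) next
    vol <- image_volume(array(v, c(7, 6, 5)), c(2, 2, 1))
    st <- region_stats(vol, roi_mask(mv, c(2, 2, 1)))
    bf <- bf_region_stats(vol$values, mv)
    expect_equal(st$n_voxels, bf$n)
    expect_equal(st$mean, bf$mean)
    expect_equal(st$sd, bf$sd)
    expect_equal(st$min, bf$min)
    expect_equal(st$max, bf$max)
    expect_equal(st$median, bf$median)
    expect_equal(st$cv, bf$cv)
    expect_equal(st$volume_mL, bf$n * 4 / 1000)
  }
})

test_that("constant ROIs have zero SD and CV; bad masks error", {
  x <- wrap_values(rep(7, 4), c(2, 2, 4))
  st <- region_stats(x$vol, x$mask)
  expect_equal(st$sd, 0)
  expect_equal(st$cv, 0)
  empty <- roi_mask(array(FALSE, c(2, 2, 4)), c(1, 1, 1))
  expect_error(region_stats(x$vol, empty), "empty")
  neg <- image_volume(array(-1, c(2, 2, 4)), c(1, 1, 1))
  expect_warning(stn <- region_stats(neg, x$mask), "not positive")
  expect_true(is.na(stn$cv))
})

test_that("CV is scale-invariant and decreases under positive shifts", {
  v <- withr::with_seed(2, runif(6 * 6 * 6, 1, 5))
  vol <- image_volume(array(v, c(6, 6, 6)), c(1, 1, 1))
  mask <- roi_mask(array(TRUE, c(6, 6, 6)), c(1, 1, 1))
  cv0 <- region_stats(vol, mask)$cv
  for (seed in 1:20) {
    c_ <- withr::with_seed(seed, runif(1, 0.01, 100))
    scaled <- image_volume(vol$values * c_, c(1, 1, 1))
    expect_equal(region_stats(scaled, mask)$cv, cv0, tolerance = 1e-12)
  }
  shifted <- image_volume(vol$values + 1, c(1, 1, 1))
  expect_lt(region_stats(shifted, mask)$cv, cv0)
})

test_that("cv_from_moments reproduces published table CVs", {
  expect_equal(round(cv_from_moments(333665.19, 50224.01), 2), 0.15)
  expect_equal(round(cv_from_moments(542301.38, 50281.7), 2), 0.09)
})

test_that("histograms are zero-anchored, conservative, and detect bimodality", {
  x <- wrap_values(rep(2.5, 8), c(2, 2, 2))
  h <- roi_histogram(x$vol, x$mask, bin_width = 1)
  expect_equal(sum(h$count), 8)
  expect_equal(h$count[h$bin_left == 2], 8)
  expect_true(all(h$count[h$bin_left != 2] == 0))

  for (seed in 1:5) {
    ph <- generate_phantom(standard_suite_spec(seed = seed))
    hh <- roi_histogram(ph$channels$glucose, ph$truth$tumor_mask, 0.05)
    expect_equal(sum(hh$count), sum(ph$truth$tumor_mask$values))
    expect_equal(diff(hh$bin_left), rep(0.05, nrow(hh) - 1))
    # edges are integer multiples of the width (zero-anchored)
    expect_equal(hh$bin_left / 0.05, round(hh$bin_left / 0.05))
  }

  # two well-separated compartments -> two local maxima
  spec <- phantom_spec(c(32, 32, 32), c(1, 1, 1), background_level = 0,
                       tumor_center_mm = c(15.5, 15.5, 15.5),
                       tumor_radii_mm = 12, tumor_level = 1,
                       hotspots = list(list(center_mm = c(15.5, 15.5, 15.5),
                                            radius_mm = 8, multiplier = 2)),
                       psf_fwhm_mm = 1, noise_model = noise_proportional(0.03),
                       seed = 4)
  ph <- generate_phantom(spec)
  hb <- roi_histogram(ph$channels$glucose, ph$truth$tumor_mask, 0.1)
  peaks <- sum(diff(sign(diff(hb$count[hb$count > 0]))) < 0)
  expect_gte(peaks, 2)
})

test_that("fold enrichment follows the mixture closed form", {
  # sub = whole is exactly 1
  x <- wrap_values(runif(27, 1, 2), c(3, 3, 3))
  expect_equal(fold_enrichment(x$vol, x$mask, x$mask)$fold, 1)

  # noiseless, unblurred: hotspot at multiplier 2 filling fraction f of the
  # tumor gives fold = 2 / (1 - f + 2 f)
  ph <- generate_phantom(standard_suite_spec(seed = 1, multiplier = 2,
                                             psf_fwhm_mm = 0,
                                             noise_fraction = 0))
  hs <- ph$truth$hotspot_masks[[1]]
  tm <- ph$truth$tumor_mask
  f <- sum(hs$values) / sum(tm$values)
  fe <- fold_enrichment(ph$channels$glucose, hs, tm)
  expect_equal(fe$fold, 2 / (1 - f + 2 * f), tolerance = 1e-12)
  expect_equal(fe$fold, 1.818, tolerance = 0.02)  # f is ~10% by design

  # subset violation and degenerate means are errors
  out_mask <- roi_mask(!tm$values, tm$spacing_mm)
  expect_error(fold_enrichment(ph$channels$glucose, out_mask, tm),
               "subset")
  zero <- image_volume(array(0, dim(tm$values)), tm$spacing_mm)
  expect_error(fold_enrichment(zero, hs, tm), "positive")
})

test_that("group CV comparison matches the pooled-t brute force", {
  a <- c(0.31, 0.29, 0.33, 0.30, 0.32)
  b <- c(0.20, 0.22, 0.18, 0.21)
  res <- compare_cv_groups(a, b)
  # brute force pooled two-sample t
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_bf <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_bf <- 2 * stats::pt(-abs(t_bf), df = length(a) + length(b) - 2)
  expect_equal(res$statistic, t_bf)
  expect_equal(res$p_value, p_bf)
  expect_equal(res$df, length(a) + length(b) - 2)
  expect_equal(res$pct_difference, (mean(a) - mean(b)) / mean(b) * 100)

  # identical degenerate groups: t = 0, p = 1
  same <- compare_cv_groups(c(0.2, 0.2), c(0.2, 0.2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # Welch variant reports fractional df
  w <- compare_cv_groups(a, b * 3, var_equal = FALSE)
  expect_identical(w$method, "Welch t")
  expect_error(compare_cv_groups(0.3, c(0.2, 0.1)), "at least 2")
})

test_that("tidy and glance return the one-row comparison summary", {
  res <- compare_cv_groups(c(0.31, 0.29, 0.33), c(0.20, 0.22, 0.18))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("mean_a", "mean_b", "pct_difference", "statistic",
                     "df", "p_value", "n_a", "n_b", "method"))
  expect_identical(glance(res), td)
})
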