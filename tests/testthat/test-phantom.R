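spec_nohs <- function(seed = 1) {
  phantom_spec(grid_shape = c(24, 24, 24), spacing_mm = c(1, 1, 1),
               background_level = 10, tumor_center_mm = c(11.5, 11.5, 11.5),
               tumor_radii_mm = c(7, 7, 7), tumor_level = 100,
               psf_fwhm_mm = 0, noise_model = noise_none(), seed = seed)
}

test_that("phantom specs reject invalid geometry", {
  expect_error(phantom_spec(c(10, 10, 10), c(1, 1, -1), 0, c(5, 5, 5),
                            c(2, 2, 2)), "positive")
  expect_error(phantom_spec(c(10, 10, 10), c(1, 1, 1), 0, c(5, 5, 5),
                            c(6, 6, 6)), "outside the voxel grid")
  expect_error(
    phantom_spec(c(24, 24, 24), c(1, 1, 1), 0, c(11.5, 11.5, 11.5), 7,
                 hotspots = list(list(center_mm = c(17, 11.5, 11.5),
                                      radius_mm = 3, multiplier = 2))),
    "outside the tumor")
  expect_error(
    phantom_spec(c(24, 24, 24), c(1, 1, 1), 0, c(11.5, 11.5, 11.5), 7,
                 hotspots = list(list(center_mm = c(11.5, 11.5, 11.5),
                                      radius_mm = 2, multiplier = 0))),
    "multiplier")
})

test_that("piecewise-constant scenes take exactly the prescribed levels", {
  ph <- generate_phantom(spec_nohs())
  expect_setequal(unique(as.vector(ph$channels$glucose$values)), c(10, 100))

  spec2 <- spec_nohs()
  spec2$hotspots <- list(list(center_mm = c(11.5, 11.5, 11.5),
                              radius_mm = 3, multiplier = 2))
  ph2 <- generate_phantom(spec2)
  hs <- ph2$truth$hotspot_masks[[1]]
  expect_equal(mean(ph2$channels$glucose$values[hs$values]) / 100, 2.0)
  expect_setequal(unique(as.vector(ph2$channels$glucose$values)),
                  c(10, 100, 200))
  # hypoxia channel nonzero only inside the hotspot (no blur applied here)
  expect_true(all(ph2$channels$hypoxia$values[!hs$values] == 0))
  expect_true(all(ph2$channels$hypoxia$values[hs$values] > 0))
})

test_that("ground-truth tumor volume matches the analytic ellipsoid", {
  spec <- phantom_spec(c(64, 64, 64), c(1, 1, 1), 0,
                       tumor_center_mm = c(31.5, 31.5, 31.5),
                       tumor_radii_mm = c(10, 10, 10), tumor_level = 1)
  ph <- generate_phantom(spec)
  analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(roi_volume(ph$truth$tumor_mask)$volume_mm3 - analytic) /
              analytic, 0.02)
})

test_that("compartments nest and generation is seed-deterministic", {
  for (seed in c(2, 5)) {
    ph <- generate_phantom(standard_suite_spec(seed = seed))
    tumor <- ph$truth$tumor_mask$values
    for (hs in ph$truth$hotspot_masks) {
      expect_true(all(!hs$values | tumor))  # hotspot subset of tumor
    }
    ph_again <- generate_phantom(standard_suite_spec(seed = seed))
    expect_identical(ph_again$channels$glucose$values,
                     ph$channels$glucose$values)
    expect_identical(ph_again$channels$hypoxia$values,
                     ph$channels$hypoxia$values)
  }
  # different seeds differ (noise + hotspot placement)
  a <- generate_phantom(standard_suite_spec(seed = 1))
  b <- generate_phantom(standard_suite_spec(seed = 2))
  expect_false(identical(a$channels$glucose$values,
                         b$channels$glucose$values))
})

test_that("PSF blur is an identity at fwhm 0 and conserves interior mass", {
  vol <- withr::with_seed(1, image_volume(array(runif(20^3), c(20, 20, 20)),
                                          c(1, 1, 1)))
  expect_identical(apply_psf_blur(vol, 0)$values, vol$values)
  expect_error(apply_psf_blur(vol, -1), ">= 0")

  spike <- array(0, c(41, 41, 41))
  spike[21, 21, 21] <- 123.4
  sv <- image_volume(spike, c(1, 1, 2))
  bl <- apply_psf_blur(sv, fwhm_mm = 5, pad_value = 0)
  expect_equal(sum(bl$values), 123.4, tolerance = 1e-6)
  expect_equal(which.max(bl$values), which.max(spike))
  # symmetry about the spike (isotropic case)
  sv2 <- image_volume(spike, c(1, 1, 1))
  bl2 <- apply_psf_blur(sv2, fwhm_mm = 5, pad_value = 0)$values
  expect_equal(bl2[21 + 3, 21, 21], bl2[21, 21 - 3, 21], tolerance = 1e-12)
  expect_equal(bl2[21, 21, 21 + 4], bl2[21 - 4, 21, 21], tolerance = 1e-12)
})

test_that("blur converts FWHM to voxel units through the spacing", {
  # same physical FWHM on two grids: the physical spread of the response
  # to a point source is the same sigma_mm = fwhm / (2 sqrt(2 ln 2))
  sigma_mm <- 6 / (2 * sqrt(2 * log(2)))
  spike <- array(0, c(61, 9, 9)); spike[31, 5, 5] <- 1
  fine <- apply_psf_blur(image_volume(spike, c(1, 1, 1)), 6, 0)
  spike2 <- array(0, c(31, 9, 9)); spike2[16, 5, 5] <- 1
  coarse <- apply_psf_blur(image_volume(spike2, c(2, 1, 1)), 6, 0)
  spread <- function(profile, x_mm) {
    sqrt(sum(profile * x_mm^2) / sum(profile))
  }
  expect_equal(spread(fine$values[, 5, 5], (0:60 - 30) * 1), sigma_mm,
               tolerance = 0.02)
  expect_equal(spread(coarse$values[, 5, 5], (0:30 - 15) * 2), sigma_mm,
               tolerance = 0.02)
})

test_that("noise models are seeded, unbiased, and clip at zero", {
  vol <- image_volume(array(100, c(50, 50, 40)), c(1, 1, 1))
  expect_identical(add_noise(vol, noise_none(), 1)$values, vol$values)

  n1 <- add_noise(vol, noise_gaussian(5), seed = 42)
  n2 <- add_noise(vol, noise_gaussian(5), seed = 42)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values,
                         add_noise(vol, noise_gaussian(5), 43)$values))
  # 1e5 voxels: sample SD within 2% of sigma
  expect_lt(abs(sd(n1$values) - 5) / 5, 0.02)

  np <- add_noise(vol, noise_proportional(0.1), seed = 42)
  expect_lt(abs(sd(np$values) - 10) / 10, 0.02)

  # heavy constant noise on a low signal clips and records the fraction
  lo <- image_volume(array(1, c(20, 20, 20)), c(1, 1, 1))
  nc <- add_noise(lo, noise_gaussian(5), seed = 1)
  expect_true(all(nc$values >= 0))
  expect_gt(attr(nc, "clipped_fraction"), 0.3)
})

test_that("IHC fixtures hit the requested dispersion and reproduce by seed", {
  t0 <- generate_ihc_fixture(20, 150, 0, 40, 0, seed = 1)
  expect_equal(nrow(t0), 20)
  expect_true(all(t0$intensity == 150) && all(t0$positive_area_pct == 40))
  scores <- region_expression(t0$intensity, t0$positive_area_pct)
  expect_equal(marker_heterogeneity(scores)$cv, 0)

  expect_identical(generate_ihc_fixture(20, 150, 0.3, 40, 0.2, seed = 9),
                   generate_ihc_fixture(20, 150, 0.3, 40, 0.2, seed = 9))

  big <- generate_ihc_fixture(1e4, 150, 0.2, 40, 0, seed = 5)
  sc <- region_expression(big$intensity, big$positive_area_pct)
  emp_cv <- sd(sc) / mean(sc)
  expect_lt(abs(emp_cv - 0.2) / 0.2, 0.05)
  expect_lt(abs(mean(big$intensity) - 150) / 150, 0.02)
})

test_that("in-tumor CV increases strictly with hotspot contrast (no noise)", {
  cvs <- vapply(c(1, 1.5, 2, 3), function(m) {
    ph <- generate_phantom(standard_suite_spec(seed = 11, multiplier = m,
                                               noise_fraction = 0))
    region_stats(ph$channels$glucose, ph$truth$tumor_mask)$cv
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})
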