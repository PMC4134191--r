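test_that("1D edge detection equals the brute-force gradient argmax", {
  r <- seq(0.25, 20, by = 0.25)
  for (seed in 1:10) {
    prof <- withr::with_seed(seed, {
      edge <- runif(1, 5, 15)
      4 / (1 + exp((r - edge) / runif(1, 0.3, 2))) + 1 +
        rnorm(length(r), 0, 0.02)
    })
    # brute-force: central finite differences, first most-negative slope
    g <- numeric(length(r))
    for (i in seq_along(r)) {
      lo <- max(1, i - 1); hi <- min(length(r), i + 1)
      g[i] <- (prof[hi] - prof[lo]) / (r[hi] - r[lo])
    }
    expect_equal(profile_edge_radius(prof, r,
                                     curvature_correction = FALSE)$radius_mm,
                 r[which.min(g)])
  }
  # flat profile: no edge
  expect_true(is.na(profile_edge_radius(rep(2, length(r)), r)$radius_mm))
})

test_that("a sharp binary sphere is recovered within a voxel", {
  sc <- blurred_sphere_volume(radius_mm = 10, fwhm_mm = 0)
  p <- segmentation_params(seed_point_mm = sc$center_mm, max_radius_mm = 20)
  roi <- segment_gradient_edge(sc$volume, p)
  expect_identical(roi$role, "ROI_E")
  ext <- axis_half_extent_mm(roi, sc$center_mm)
  expect_true(all(abs(ext - 10) <= 1))
  expect_gt(dice(roi$values, sc$truth$values), 0.9)
})

test_that("a blurred sphere's boundary is recovered within a voxel per axis", {
  sc <- blurred_sphere_volume(radius_mm = 10, fwhm_mm = 6, contrast = 4)
  p <- segmentation_params(seed_point_mm = sc$center_mm, max_radius_mm = 20)
  roi <- segment_gradient_edge(sc$volume, p)
  ext <- axis_half_extent_mm(roi, sc$center_mm)
  expect_true(all(abs(ext - 10) <= 1))
  expect_gt(dice(roi$values, sc$truth$values), 0.85)
  # without the curvature correction the boundary sits visibly inside
  p_raw <- segmentation_params(seed_point_mm = sc$center_mm,
                               max_radius_mm = 20,
                               curvature_correction = FALSE)
  roi_raw <- segment_gradient_edge(sc$volume, p_raw)
  expect_lt(effective_radius_mm(roi_raw), effective_radius_mm(roi))
})

test_that("segmentation contains the seed, is face-connected, deterministic", {
  ph <- generate_phantom(standard_suite_spec(seed = 3, hotspot = FALSE))
  p <- segmentation_params(seed_point_mm = c(23.5, 23.5, 23.5),
                           max_radius_mm = 20, smoothing_fwhm_mm = 2)
  roi <- segment_gradient_edge(ph$channels$glucose, p)
  expect_true(roi$values[24, 24, 24])
  labs <- tumorhet:::label_components(roi$values, "face")
  expect_equal(max(labs), 1)
  roi2 <- segment_gradient_edge(ph$channels$glucose, p)
  expect_identical(roi$values, roi2$values)
})

test_that("segmentation rejects bad seeds and flat images", {
  sc <- blurred_sphere_volume()
  expect_error(segment_gradient_edge(
    sc$volume, segmentation_params(c(-5, 0, 0), 20)), "outside")
  # seed in the background: below the global median
  expect_error(segment_gradient_edge(
    sc$volume, segmentation_params(c(2, 2, 2), 20)), "median")
  flat <- image_volume(array(1 + seq(0, 1e-9, length.out = 8000),
                             c(20, 20, 20)), c(1, 1, 1))
  expect_error(segment_gradient_edge(
    flat, segmentation_params(c(10, 10, 10), 9)), "rays")
})

test_that("hotspot detection separates two disjoint ground-truth hotspots", {
  ctr <- (c(48, 48, 48) - 1) / 2
  spec <- phantom_spec(
    c(48, 48, 48), c(1, 1, 1), background_level = 0.1,
    tumor_center_mm = ctr, tumor_radii_mm = c(14, 14, 14), tumor_level = 1,
    hotspots = list(
      list(center_mm = ctr + c(7, 0, 0), radius_mm = 4, multiplier = 2),
      list(center_mm = ctr - c(7, 0, 0), radius_mm = 4, multiplier = 3)),
    psf_fwhm_mm = 1.5, noise_model = noise_proportional(0.02), seed = 5)
  ph <- generate_phantom(spec)
  found <- detect_hotspots(ph$channels$hypoxia, ph$truth$tumor_mask,
                           hotspot_params(threshold_value = 0.4))
  expect_length(found, 2)
  # sorted by descending mean: first found matches the stronger truth spot
  expect_gt(dice(found[[1]]$values, ph$truth$hotspot_masks[[2]]$values), 0.8)
  expect_gt(dice(found[[2]]$values, ph$truth$hotspot_masks[[1]]$values), 0.8)
  # pairwise disjoint and nested in the tumor
  expect_false(any(found[[1]]$values & found[[2]]$values))
  for (f in found) expect_true(all(!f$values | ph$truth$tumor_mask$values))
})

test_that("hotspot detection handles degenerate thresholds", {
  vol <- image_volume(array(5, c(10, 10, 10)), c(1, 1, 1))
  tumor <- roi_mask(rasterize_sphere(4, c(1, 1, 1),
                                     grid_shape = c(10, 10, 10))$values,
                    c(1, 1, 1))
  # constant channel at fraction 0.5: everything passes, one component
  found <- detect_hotspots(vol, tumor, hotspot_params(threshold_value = 0.5))
  expect_length(found, 1)
  expect_identical(found[[1]]$values, tumor$values)
  # absolute threshold above the max: empty result
  none <- detect_hotspots(vol, tumor,
                          hotspot_params("absolute", threshold_value = 10))
  expect_length(none, 0)
  # minimum volume filter removes small components
  v2 <- array(0, c(10, 10, 10)); v2[5, 5, 5] <- 9
  vol2 <- image_volume(v2, c(1, 1, 1))
  found2 <- detect_hotspots(vol2, tumor,
                            hotspot_params("absolute", threshold_value = 5,
                                           min_region_volume_mm3 = 2))
  expect_length(found2, 0)
  expect_error(detect_hotspots(vol, roi_mask(array(FALSE, c(10, 10, 10)),
                                             c(1, 1, 1))), "empty")
})
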