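# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, all-pairs distances) so they share no code path
# with the implementation they check.

# Naive first-order statistics over in-mask voxels.
bf_region_stats <- function(values, mask_values) {
  v <- c()
  for (i in seq_along(values)) {
    if (mask_values[i]) v <- c(v, values[i])
  }
  n <- length(v)
  mu <- sum(v) / n
  s2 <- sum((v - mu)^2) / (n - 1)
  list(n = n, mean = mu, sd = sqrt(s2), min = min(v), max = max(v),
       median = unname(stats::quantile(v, 0.5, type = 2)),
       cv = sqrt(s2) / mu)
}

# All-pairs contraction rule: keep an in-mask voxel iff its center is at
# distance >= distance_mm from every voxel center outside the mask,
# including the virtual layer of outside voxels hugging the grid border.
bf_contract <- function(mask_values, spacing_mm, distance_mm) {
  dm <- dim(mask_values)
  idx <- which(array(TRUE, dm), arr.ind = TRUE) - 1
  ctr <- idx %*% diag(spacing_mm)
  inm <- as.vector(mask_values)
  hi <- (dm - 1) * spacing_mm
  out_pts <- ctr[!inm, , drop = FALSE]
  in_idx <- which(inm)
  keep <- logical(length(inm))
  # all-pairs squared distances, chunked: |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  out_sq <- rowSums(out_pts^2)
  for (chunk in split(in_idx, ceiling(seq_along(in_idx) / 512))) {
    p <- ctr[chunk, , drop = FALSE]
    d_in_grid <- if (nrow(out_pts)) {
      d2 <- outer(rowSums(p^2), out_sq, "+") - 2 * p %*% t(out_pts)
      sqrt(pmax(apply(d2, 1, min), 0))
    } else rep(Inf, length(chunk))
    d_border <- pmin(
      apply(sweep(p, 2, spacing_mm, "+"), 1, min),
      apply(sweep(-p, 2, hi + spacing_mm, "+"), 1, min))
    keep[chunk] <- pmin(d_in_grid, d_border) >= distance_mm
  }
  array(keep, dm)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Random blobby masks for property tests: thresholded smoothed noise, so
# components have structure (not pure speckle) but arbitrary topology.
random_mask <- function(dm, spacing_mm, seed, fill = 0.45) {
  withr::with_seed(seed, {
    v <- array(runif(prod(dm)), dm)
    vol <- image_volume(v, spacing_mm)
    sm <- apply_psf_blur(vol, fwhm_mm = 2.5 * min(spacing_mm),
                         pad_value = 0.5)
    array(sm$values > stats::quantile(sm$values, 1 - fill), dm)
  })
}

# Compact noiseless two-level sphere volume for segmentation checks.
blurred_sphere_volume <- function(radius_mm = 10, fwhm_mm = 6,
                                  contrast = 4, n = 48, spacing = 1) {
  ctr <- (n - 1) / 2 * spacing
  ref <- image_volume(array(0, c(n, n, n)), rep(spacing, 3))
  d2 <- rowSums(sweep(tumorhet:::voxel_centers_mm(ref), 2, rep(ctr, 3))^2)
  scene <- array(ifelse(d2 <= radius_mm^2, contrast, 1), c(n, n, n))
  vol <- image_volume(scene, rep(spacing, 3), units = "a.u.")
  list(volume = apply_psf_blur(vol, fwhm_mm, pad_value = 1),
       truth = roi_mask(array(d2 <= radius_mm^2, c(n, n, n)),
                        rep(spacing, 3)),
       center_mm = rep(ctr, 3))
}

# Recovered half-extent of a mask along one axis through a center voxel.
axis_half_extent_mm <- function(mask, center_vox0) {
  w <- which(mask$values, arr.ind = TRUE) - 1
  vapply(1:3, function(ax) {
    oth <- setdiff(1:3, ax)
    on_axis <- abs(w[, oth[1]] - center_vox0[oth[1]]) <= 0.5 &
      abs(w[, oth[2]] - center_vox0[oth[2]]) <= 0.5
    sel <- w[on_axis, ax]
    (max(sel) - min(sel)) / 2 * mask$spacing_mm[ax]
  }, numeric(1))
}
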