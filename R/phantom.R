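#' Noise models for synthetic volumes
#'
#' Three voxel-noise variants for the phantom generator: `noise_none()` (no
#' noise), `noise_gaussian(sigma)` (additive zero-mean Gaussian with constant
#' SD in intensity units), and `noise_proportional(fraction)` (zero-mean
#' Gaussian whose SD is `fraction` times the local noise-free intensity, a
#' crude stand-in for the signal-dependent variance of reconstructed
#' emission and fluorescence images). Negative results are clipped at zero —
#' tracer concentrations are non-negative — and the clipped voxel fraction is
#' recorded on the output as attribute `"clipped_fraction"`.
#'
#' @param sigma Noise SD in intensity units (`noise_gaussian`).
#' @param fraction Noise SD as a fraction of local intensity
#'   (`noise_proportional`).
#' @return A `noise_model` object.
#' @export
noise_none <- function() structure(list(type = "none"), class = "noise_model")

#' @rdname noise_none
#' @export
noise_gaussian <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(type = "gaussian_constant", sigma = sigma),
            class = "noise_model")
}

#' @rdname noise_none
#' @export
noise_proportional <- function(fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L, fraction >= 0)
  structure(list(type = "gaussian_proportional", fraction = fraction),
            class = "noise_model")
}

#' Specification of a synthetic tumor scene
#'
#' Full parameterization of a digital tumor phantom: an ellipsoidal tumor
#' compartment on a constant background, optional spherical hotspot
#' subregions of elevated uptake, Gaussian point-spread blur at a stated
#' FWHM, and a noise model. Rendering is voxel-center point sampling: a voxel
#' belongs to a compartment iff its center lies inside the analytic shape.
#' Invariants are validated here: strictly positive spacing, the tumor
#' ellipsoid fully inside the grid, and every hotspot sphere fully inside the
#' tumor ellipsoid.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param spacing_mm Positive real triple, voxel pitch in mm.
#' @param background_level Background intensity (>= 0).
#' @param tumor_center_mm,tumor_radii_mm Ellipsoid center and semi-axes (mm).
#' @param tumor_level Tumor compartment intensity.
#' @param hotspots List of hotspots, each `list(center_mm =, radius_mm =,
#'   multiplier =)` with `multiplier > 0`; hotspot voxels take
#'   `tumor_level * multiplier` in the glucose channel.
#' @param psf_fwhm_mm Gaussian point-spread FWHM in mm (0 = no blur).
#' @param noise_model A [noise_none()]-family object.
#' @param units Intensity unit label for generated channels.
#' @param include_hypoxia Add a hypoxia channel (nonzero only inside
#'   hotspots before blur) when hotspots are present.
#' @param seed Integer seed; identical spec + seed reproduces bit-identical
#'   output.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape, spacing_mm, background_level = 0,
                         tumor_center_mm, tumor_radii_mm, tumor_level = 1,
                         hotspots = list(), psf_fwhm_mm = 0,
                         noise_model = noise_none(), units = "arbitrary",
                         include_hypoxia = TRUE, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L),
            length(spacing_mm) == 3L)
  if (any(spacing_mm <= 0)) abort("`spacing_mm` must be strictly positive.")
  if (background_level < 0) abort("`background_level` must be >= 0.")
  tumor_center_mm <- as.numeric(tumor_center_mm)
  tumor_radii_mm <- as.numeric(tumor_radii_mm)
  if (length(tumor_radii_mm) == 1L) tumor_radii_mm <- rep(tumor_radii_mm, 3)
  if (any(tumor_radii_mm <= 0)) abort("`tumor_radii_mm` must be positive.")
  if (!inherits(noise_model, "noise_model")) {
    abort("`noise_model` must be created with noise_none()/noise_gaussian()/noise_proportional().")
  }
  if (psf_fwhm_mm < 0) abort("`psf_fwhm_mm` must be >= 0.")

  # Tumor must fit inside the physical extent spanned by voxel centers.
  lo <- c(0, 0, 0)
  hi <- (grid_shape - 1L) * spacing_mm
  if (any(tumor_center_mm - tumor_radii_mm < lo) ||
      any(tumor_center_mm + tumor_radii_mm > hi)) {
    abort("Tumor ellipsoid extends outside the voxel grid.")
  }
  for (h in hotspots) {
    if (!all(c("center_mm", "radius_mm", "multiplier") %in% names(h))) {
      abort("Each hotspot needs `center_mm`, `radius_mm`, `multiplier`.")
    }
    if (h$multiplier <= 0) abort("Hotspot `multiplier` must be > 0.")
    if (h$radius_mm <= 0) abort("Hotspot `radius_mm` must be > 0.")
    # Conservative containment: normalized center offset plus the hotspot
    # radius scaled by the smallest semi-axis must stay within the ellipsoid.
    u <- (as.numeric(h$center_mm) - tumor_center_mm) / tumor_radii_mm
    if (sqrt(sum(u^2)) + h$radius_mm / min(tumor_radii_mm) > 1 + 1e-12) {
      abort("Hotspot sphere extends outside the tumor ellipsoid.")
    }
  }
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         background_level = background_level,
         tumor_center_mm = tumor_center_mm, tumor_radii_mm = tumor_radii_mm,
         tumor_level = tumor_level, hotspots = hotspots,
         psf_fwhm_mm = psf_fwhm_mm, noise_model = noise_model,
         units = units, include_hypoxia = include_hypoxia,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Standard compact phantom suite
#'
#' The fixed study conditions used throughout the package's validation
#' suites: a 48x48x48 grid at 1 mm isotropic pitch, a spherical tumor of
#' radius 10 mm centered in the grid at intensity 1 on a 0.1 background
#' (10:1 tumor-to-background, 4:1 for the segmentation variant), an optional
#' single hotspot occupying 10% of the tumor volume (radius `10 * 0.1^(1/3)`
#' mm) whose center is jittered within a 2 mm ball per seed, Gaussian PSF
#' blur at FWHM 6 mm, and 5% proportional noise. See the methods vignette
#' for the rationale behind each value.
#'
#' @param seed Integer seed (drives hotspot placement and noise).
#' @param hotspot Include the hotspot subregion?
#' @param multiplier Hotspot uptake multiplier.
#' @param psf_fwhm_mm Blur FWHM in mm.
#' @param noise_fraction Proportional noise fraction (0 disables noise).
#' @param contrast Tumor-to-background intensity ratio.
#' @return A `phantom_spec`.
#' @export
standard_suite_spec <- function(seed = 1L, hotspot = TRUE, multiplier = 2,
                                psf_fwhm_mm = 6, noise_fraction = 0.05,
                                contrast = 10) {
  center <- (c(48, 48, 48) - 1) / 2
  hs <- list()
  if (hotspot) {
    jitter <- withr::with_seed(as.integer(seed) + 7L, {
      u <- rnorm(3)
      u / sqrt(sum(u^2)) * runif(1)^(1 / 3) * 2
    })
    hs <- list(list(center_mm = center + jitter,
                    radius_mm = 10 * 0.1^(1 / 3), multiplier = multiplier))
  }
  phantom_spec(
    grid_shape = c(48, 48, 48), spacing_mm = c(1, 1, 1),
    background_level = 1 / contrast, tumor_center_mm = center,
    tumor_radii_mm = c(10, 10, 10), tumor_level = 1, hotspots = hs,
    psf_fwhm_mm = psf_fwhm_mm,
    noise_model = if (noise_fraction > 0) noise_proportional(noise_fraction)
                  else noise_none(),
    units = "a.u.", seed = seed
  )
}

#' Geometry-faithful clinical PET phantom spec
#'
#' A whole-field phantom matching a clinical PET reconstruction grid
#' (128x128x47 voxels at 4.7 x 4.7 x 3.3 mm) with a 25 mm-radius tumor and
#' FWHM 6 mm blur; useful for exercising realistic anisotropy and voxel
#' counts.
#' @inheritParams standard_suite_spec
#' @export
pet_geometry_spec <- function(seed = 1L, hotspot = FALSE, multiplier = 2) {
  shape <- c(128, 128, 47)
  sp <- c(4.7, 4.7, 3.3)
  center <- (shape - 1) / 2 * sp
  hs <- if (hotspot) {
    list(list(center_mm = center, radius_mm = 25 * 0.1^(1 / 3),
              multiplier = multiplier))
  } else list()
  phantom_spec(shape, sp, background_level = 0.1, tumor_center_mm = center,
               tumor_radii_mm = c(25, 25, 25), tumor_level = 1,
               hotspots = hs, psf_fwhm_mm = 6,
               noise_model = noise_proportional(0.05), units = "bq/mL",
               seed = seed)
}

#' Geometry-faithful FMT xenograft phantom spec
#'
#' A fluorescence-tomography-like phantom with 0.25 mm z pitch and a 225 mm^3
#' tumor (radius 3.77 mm), approximating a two-week xenograft; blur FWHM
#' 1 mm.
#' @inheritParams standard_suite_spec
#' @export
fmt_geometry_spec <- function(seed = 1L, hotspot = TRUE, multiplier = 2) {
  shape <- c(40, 40, 72)
  sp <- c(0.5, 0.5, 0.25)
  center <- (shape - 1) / 2 * sp
  hs <- if (hotspot) {
    list(list(center_mm = center, radius_mm = 3.77 * 0.1^(1 / 3),
              multiplier = multiplier))
  } else list()
  phantom_spec(shape, sp, background_level = 0.1, tumor_center_mm = center,
               tumor_radii_mm = c(3.77, 3.77, 3.77), tumor_level = 1,
               hotspots = hs, psf_fwhm_mm = 1,
               noise_model = noise_proportional(0.05), units = "pmol/mm^3",
               seed = seed)
}

#' Generate a digital tumor phantom with ground truth
#'
#' Renders the piecewise-constant scene described by a [phantom_spec()]
#' (background, tumor, hotspots, by voxel-center membership), applies
#' Gaussian point-spread blur (constant-value padding at the background
#' level) and then noise, in that order. Ground-truth masks are the crisp
#' pre-blur compartment supports — the anatomy is sharp, only the image is
#' blurred, mirroring real acquisition. A `"glucose"` channel is always
#' produced; a `"hypoxia"` channel (nonzero only inside hotspots before
#' blur, amplitude equal to each hotspot's multiplier) is added when
#' hotspots exist and `include_hypoxia` is set.
#'
#' @param spec A `phantom_spec`.
#' @return A list of class `tumor_phantom` with elements `channels` (a
#'   [channel_set()]), `truth` (list with `tumor_mask`, `hotspot_masks`,
#'   `true_levels`), and `spec`.
#' @examples
#' ph <- generate_phantom(standard_suite_spec(seed = 1))
#' ph$channels
#' ph$truth$tumor_mask
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  ref <- image_volume(array(0, dm), spec$spacing_mm, units = spec$units)
  ctr <- voxel_centers_mm(ref)

  u <- sweep(ctr, 2, spec$tumor_center_mm, "-")
  u <- sweep(u, 2, spec$tumor_radii_mm, "/")
  tumor <- array(rowSums(u^2) <= 1, dm)

  hotspot_masks <- lapply(spec$hotspots, function(h) {
    d2 <- rowSums(sweep(ctr, 2, as.numeric(h$center_mm), "-")^2)
    m <- array(d2 <= h$radius_mm^2, dm) & tumor  # enforce nesting
    roi_mask(m, spec$spacing_mm, role = "hotspot")
  })

  scene <- array(spec$background_level, dm)
  scene[tumor] <- spec$tumor_level
  hyp <- array(0, dm)
  for (i in seq_along(spec$hotspots)) {
    hm <- hotspot_masks[[i]]$values
    scene[hm] <- spec$tumor_level * spec$hotspots[[i]]$multiplier
    hyp[hm] <- spec$hotspots[[i]]$multiplier
  }

  glucose <- image_volume(scene, spec$spacing_mm, units = spec$units)
  glucose <- apply_psf_blur(glucose, spec$psf_fwhm_mm,
                            pad_value = spec$background_level)
  glucose <- add_noise(glucose, spec$noise_model, seed = spec$seed + 1L)

  channels <- list(glucose = glucose)
  if (spec$include_hypoxia && length(spec$hotspots) > 0) {
    hypoxia <- image_volume(hyp, spec$spacing_mm, units = spec$units)
    hypoxia <- apply_psf_blur(hypoxia, spec$psf_fwhm_mm, pad_value = 0)
    hypoxia <- add_noise(hypoxia, spec$noise_model, seed = spec$seed + 2L)
    channels$hypoxia <- hypoxia
  }

  truth <- list(
    tumor_mask = roi_mask(tumor, spec$spacing_mm, role = "ground_truth"),
    hotspot_masks = hotspot_masks,
    true_levels = c(list(background = spec$background_level,
                         tumor = spec$tumor_level),
                    setNames(
                      lapply(spec$hotspots,
                             function(h) spec$tumor_level * h$multiplier),
                      if (length(spec$hotspots))
                        paste0("hotspot_", seq_along(spec$hotspots))
                      else character(0)))
  )
  structure(list(channels = channel_set(channels), truth = truth,
                 spec = spec),
            class = "tumor_phantom")
}

#' @export
print.tumor_phantom <- function(x, ...) {
  cat(sprintf("<tumor_phantom> seed %d, %d channel(s), %d hotspot(s), fwhm %g mm\n",
              x$spec$seed, length(x$channels), length(x$truth$hotspot_masks),
              x$spec$psf_fwhm_mm))
  invisible(x)
}

#' Gaussian point-spread blur in physical units
#'
#' Separable Gaussian smoothing with `sigma_mm = fwhm_mm / (2 sqrt(2 ln 2))`
#' per axis, converted to voxel units by the per-axis spacing (so anisotropic
#' grids blur isotropically in physical space). The discrete kernel is
#' sampled out to 4 sigma and normalized to unit sum, so total intensity over
#' structures away from the grid border is conserved to floating-point
#' precision. Out-of-grid voxels are treated as the constant `pad_value`
#' (use the scene's background level to avoid artificial edge gradients at
#' the grid border). `fwhm_mm = 0` is the exact identity.
#'
#' @param volume An `image_volume`.
#' @param fwhm_mm Full-width at half-maximum of the Gaussian PSF, in mm.
#' @param pad_value Constant intensity assumed outside the grid.
#' @return A blurred `image_volume` on the same grid.
#' @export
apply_psf_blur <- function(volume, fwhm_mm, pad_value = 0) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || is.na(fwhm_mm)) {
    abort("`fwhm_mm` must be a single number.")
  }
  if (fwhm_mm < 0) abort("`fwhm_mm` must be >= 0.")
  if (fwhm_mm == 0) return(volume)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vals <- volume$values
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / volume$spacing_mm[ax]
    if (sigma_vox < 1e-8) next
    r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
    w <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
    w <- w / sum(w)
    vals <- convolve_axis(vals, w, ax, pad_value)
  }
  out <- volume
  out$values <- vals
  out
}

# Separable 1D convolution along `axis` with constant padding, implemented as
# a weighted sum of shifted sub-arrays of the padded volume (vectorized; no
# per-voxel loop).
convolve_axis <- function(vals, kernel, axis, pad_value) {
  dm <- dim(vals)
  r <- (length(kernel) - 1L) %/% 2L
  pdm <- dm
  pdm[axis] <- dm[axis] + 2L * r
  padded <- array(pad_value, pdm)
  core <- lapply(seq_along(dm), function(a) seq_len(dm[a]))
  ins <- core
  ins[[axis]] <- seq_len(dm[axis]) + r
  padded[ins[[1]], ins[[2]], ins[[3]]] <- vals
  out <- array(0, dm)
  for (j in seq_along(kernel)) {
    sel <- core
    sel[[axis]] <- seq_len(dm[axis]) + (j - 1L)
    out <- out + kernel[j] * padded[sel[[1]], sel[[2]], sel[[3]]]
  }
  out
}

#' Add voxel noise to a volume
#'
#' Applies the given [noise model][noise_none()] deterministically for a
#' seed. Negative voxels are clipped at zero; the clipped fraction is stored
#' as attribute `"clipped_fraction"` on the returned volume.
#'
#' @param volume An `image_volume`.
#' @param noise_model A `noise_model` object.
#' @param seed Integer seed.
#' @return A noisy `image_volume`.
#' @export
add_noise <- function(volume, noise_model, seed) {
  stopifnot(inherits(volume, "image_volume"))
  if (!inherits(noise_model, "noise_model")) {
    abort("`noise_model` must be a noise_model object.")
  }
  if (noise_model$type == "none") return(volume)
  n <- length(volume$values)
  noisy <- withr::with_seed(as.integer(seed), {
    switch(noise_model$type,
      gaussian_constant = volume$values + rnorm(n, 0, noise_model$sigma),
      gaussian_proportional = volume$values +
        rnorm(n, 0, 1) * noise_model$fraction * volume$values,
      abort(sprintf("Unknown noise model '%s'.", noise_model$type)))
  })
  clipped <- mean(noisy < 0)
  noisy[noisy < 0] <- 0
  out <- volume
  out$values <- array(noisy, dim(volume$values))
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Synthetic per-region IHC score table
#'
#' Emulates a pathologist's scoring of representative regions on a stained
#' tumor section: per-region staining intensity and positive-area percentage
#' drawn from lognormal distributions (strictly positive, right-skewed, and
#' directly parameterizable by mean and CV), with the area clipped to
#' [0, 100]. A zero CV yields exactly constant values. Reproducible by seed.
#'
#' @param n_regions Number of scored regions (>= 2); the heterogeneity
#'   protocol this emulates uses 20.
#' @param intensity_mean,intensity_cv Mean and coefficient of variation of
#'   the staining-intensity distribution.
#' @param area_mean_pct,area_cv Mean (percent, 0-100 scale) and CV of the
#'   positive-area distribution.
#' @param seed Integer seed.
#' @param tumor_id,marker Identifier columns for the output table.
#' @return A tibble with columns `tumor_id, marker, region, intensity,
#'   positive_area_pct`.
#' @export
generate_ihc_fixture <- function(n_regions, intensity_mean, intensity_cv,
                                 area_mean_pct, area_cv, seed,
                                 tumor_id = "T1", marker = "marker") {
  stopifnot(n_regions >= 2, intensity_cv >= 0, area_cv >= 0,
            intensity_mean >= 0, area_mean_pct >= 0, area_mean_pct <= 100)
  draw <- function(m, cv, n) {
    if (cv == 0 || m == 0) return(rep(m, n))
    sdlog <- sqrt(log1p(cv^2))
    rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  withr::with_seed(as.integer(seed), {
    intensity <- draw(intensity_mean, intensity_cv, n_regions)
    area <- pmin(100, pmax(0, draw(area_mean_pct, area_cv, n_regions)))
    tibble(tumor_id = tumor_id, marker = marker,
           region = seq_len(n_regions), intensity = intensity,
           positive_area_pct = area)
  })
}
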