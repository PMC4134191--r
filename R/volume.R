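#' 3D image volume with physical voxel geometry
#'
#' The common currency of all imaging stages: a 3D scalar array plus the
#' physical grid it lives on. The physical position of the *center* of voxel
#' `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`, all in
#' millimetres. Intensities carry a free-text unit label (e.g. `"bq/mL"` for
#' PET activity concentration, `"pmol/mm^3"` for fluorescent probe
#' concentration) that is propagated unchanged into every statistics table.
#'
#' @param values 3D numeric array of voxel intensities; all finite.
#' @param spacing_mm Positive length-3 numeric, physical voxel pitch per axis
#'   in mm.
#' @param origin_mm Length-3 numeric, physical position of voxel (0,0,0)'s
#'   center in mm.
#' @param units Free-text intensity unit label.
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(1, c(4, 4, 4)), spacing_mm = c(4.7, 4.7, 3.3))
#' vol
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                         units = "arbitrary") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  if (any(dim(values) < 2L)) {
    abort("`values` must have at least 2 voxels along every axis.")
  }
  if (!all(is.finite(values))) abort("`values` must be finite.")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 strictly positive finite numbers.")
  }
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm))) {
    abort("`origin_mm` must be 3 finite numbers.")
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
         units = as.character(units)[1]),
    class = "image_volume"
  )
}

roi_roles <- c("ROI_E", "ROI_C", "hotspot", "whole_tumor", "ground_truth")

#' Binary region-of-interest mask bound to a voxel grid
#'
#' A logical 3D array sharing the grid (shape, spacing, origin) of the
#' volume(s) it is applied to, tagged with the role it plays in the analysis:
#' `"ROI_E"` for an edge-delineated tumor boundary, `"ROI_C"` for its
#' circumferentially contracted version, `"hotspot"` for a marker-positive
#' subregion, `"whole_tumor"` or `"ground_truth"` for reference masks.
#' Non-logical input is binarized (any nonzero value becomes `TRUE`); if that
#' loses information a warning is emitted.
#'
#' @param values 3D logical (or coercible 0/1) array.
#' @param spacing_mm,origin_mm Grid geometry, as in [image_volume()].
#' @param role One of `"ROI_E"`, `"ROI_C"`, `"hotspot"`, `"whole_tumor"`,
#'   `"ground_truth"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                     role = "ground_truth") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  role <- match.arg(role, roi_roles)
  if (!is.logical(values)) {
    num <- as.numeric(values)
    if (any(!num %in% c(0, 1))) {
      warn("Mask contains values other than 0/1; any nonzero voxel is treated as in-mask.")
    }
    values <- array(num != 0, dim(values))
  }
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 strictly positive numbers.")
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
         role = role),
    class = "roi_mask"
  )
}

#' Named set of co-registered channels
#'
#' Bundles named [image_volume()] objects acquired on one shared grid, e.g.
#' hypoxia / vascular / glucose probe channels of a multiplexed fluorescence
#' tomography scan. Construction enforces co-registration via
#' [validate_coregistered()], so ROI transfer between channels is always safe.
#'
#' @param ... Named `image_volume` objects, or a single named list of them.
#' @return An object of class `channel_set`.
#' @export
channel_set <- function(...) {
  chans <- list(...)
  if (length(chans) == 1L && !inherits(chans[[1]], "image_volume") &&
      is.list(chans[[1]])) {
    chans <- chans[[1]]
  }
  if (length(chans) == 0L) abort("A channel set needs at least one channel.")
  if (is.null(names(chans)) || any(!nzchar(names(chans)))) {
    abort("Every channel must be named.")
  }
  ok <- vapply(chans, inherits, logical(1), "image_volume")
  if (!all(ok)) abort("Every channel must be an `image_volume`.")
  out <- structure(chans, class = "channel_set")
  validate_coregistered(out)
  out
}

# Grid descriptor used by all consistency checks.
grid_of <- function(x) {
  list(shape = dim(x$values), spacing_mm = x$spacing_mm,
       origin_mm = x$origin_mm)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) <= tol) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol)
}

# Error unless `mask` lives on `vol`'s grid.
check_same_grid <- function(vol, mask, what = "mask") {
  ga <- grid_of(vol)
  gb <- grid_of(mask)
  if (!identical(ga$shape, gb$shape)) {
    abort(sprintf("%s shape (%s) does not match volume shape (%s).", what,
                  paste(gb$shape, collapse = "x"),
                  paste(ga$shape, collapse = "x")))
  }
  for (ax in 1:3) {
    if (abs(ga$spacing_mm[ax] - gb$spacing_mm[ax]) > 1e-6) {
      abort(sprintf("%s spacing differs from volume spacing on axis %d.",
                    what, ax))
    }
    if (abs(ga$origin_mm[ax] - gb$origin_mm[ax]) > 1e-6) {
      abort(sprintf("%s origin differs from volume origin on axis %d.",
                    what, ax))
    }
  }
  invisible(TRUE)
}

#' Physical volume of one voxel
#' @param x An `image_volume` or `roi_mask`.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing_mm)

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm, units '%s'\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"), x$units))
  cat(sprintf("  intensity range [%g, %g], origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask:%s> %s voxels @ %s mm, %d in-mask (%.3g mm^3)\n",
              x$role, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              sum(x$values), sum(x$values) * voxel_volume_mm3(x)))
  invisible(x)
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %d channel(s) on a %s grid: %s\n", length(x),
              paste(dim(x[[1]]$values), collapse = "x"),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Check that channels share one voxel grid
#'
#' ROI transfer between channels is only meaningful when the channels are
#' co-registered; any grid mismatch is an error naming the offending channel
#' and axis, never silently resampled.
#'
#' @param channels A `channel_set`, or a named list of `image_volume`s.
#' @param tol_mm Tolerance on spacing and origin agreement, in mm.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_coregistered <- function(channels, tol_mm = 1e-6) {
  if (length(channels) == 0L) abort("At least one channel is required.")
  ref <- grid_of(channels[[1]])
  nms <- names(channels)
  for (idx in seq_along(channels)) {
    g <- grid_of(channels[[idx]])
    if (!identical(ref$shape, g$shape)) {
      abort(sprintf("Channel '%s': shape %s does not match '%s' (%s).",
                    nms[idx], paste(g$shape, collapse = "x"), nms[1],
                    paste(ref$shape, collapse = "x")))
    }
    for (ax in 1:3) {
      if (abs(ref$spacing_mm[ax] - g$spacing_mm[ax]) > tol_mm) {
        abort(sprintf("Channel '%s': spacing mismatch on axis %d (%g vs %g mm).",
                      nms[idx], ax, g$spacing_mm[ax], ref$spacing_mm[ax]))
      }
      if (abs(ref$origin_mm[ax] - g$origin_mm[ax]) > tol_mm) {
        abort(sprintf("Channel '%s': origin mismatch on axis %d.", nms[idx], ax))
      }
    }
  }
  invisible(TRUE)
}

# Physical coordinates (mm) of all voxel centers, as an n x 3 matrix in the
# array's linear (column-major) order.
voxel_centers_mm <- function(x) {
  dm <- dim(x$values)
  idx <- arrayInd(seq_len(prod(dm)), dm) - 1L
  sweep(idx %*% diag(x$spacing_mm), 2, x$origin_mm, "+")
}
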