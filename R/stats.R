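#' Descriptive statistics of voxel intensities within an ROI
#'
#' First-order statistics over the in-mask voxels: count, physical volume,
#' mean, sample standard deviation (n-1 denominator), min, max, median, and
#' the dimensionless coefficient of variation `cv = sd / mean` — the
#' heterogeneity measure this package is built around. The median of an
#' even-count sample is the midpoint of the two central values. When the
#' mean is not positive the CV is undefined and reported as `NA` with a
#' warning. CV is conventionally *printed* at 2 decimals in tabular output;
#' the returned value keeps full precision.
#'
#' @param volume An `image_volume`.
#' @param mask A nonempty `roi_mask` on the same grid.
#' @return A one-row tibble of class `region_stats` with columns `roi`,
#'   `n_voxels`, `volume_mL`, `mean`, `sd`, `min`, `max`, `median`, `cv`,
#'   `units`.
#' @examples
#' vol <- image_volume(array(1:125, c(5, 5, 5)), c(1, 1, 1), units = "bq/mL")
#' m <- roi_mask(array(TRUE, c(5, 5, 5)), c(1, 1, 1))
#' region_stats(vol, m)
#' @export
region_stats <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(volume, mask)
  v <- volume$values[mask$values]
  if (length(v) == 0L) abort("Mask is empty; no voxels to summarize.")
  mu <- mean(v)
  s <- if (length(v) >= 2L) sd(v) else NA_real_
  cv <- if (is.na(s)) {
    NA_real_
  } else if (mu > 0) {
    s / mu
  } else {
    warn("ROI mean is not positive; CV is undefined and reported as NA.")
    NA_real_
  }
  out <- tibble(
    roi = mask$role, n_voxels = length(v),
    volume_mL = length(v) * voxel_volume_mm3(mask) / 1000,
    mean = mu, sd = s, min = min(v), max = max(v), median = median(v),
    cv = cv, units = volume$units
  )
  class(out) <- c("region_stats", class(out))
  out
}

#' Coefficient of variation from reported moments
#'
#' `sd / mean` — useful for re-deriving CVs from published summary tables
#' (report at two decimals to match conventional table formatting).
#' @param mean,sd Mean and standard deviation (same units).
#' @return Dimensionless CV, full precision.
#' @examples
#' round(cv_from_moments(333665.19, 50224.01), 2)  # 0.15
#' @export
cv_from_moments <- function(mean, sd) {
  if (any(mean <= 0)) {
    warn("Non-positive mean; CV undefined, returning NA.")
    return(ifelse(mean > 0, sd / mean, NA_real_))
  }
  sd / mean
}

#' Intensity histogram of an ROI
#'
#' Uniform, left-closed right-open bins anchored at zero (bin k covers
#' `[k * bin_width, (k + 1) * bin_width)`), so binning is reproducible and
#' independent of the data range. Counts sum to the ROI voxel count.
#' A bin width of 1000 in the volume's native intensity unit mirrors
#' conventional PET activity-concentration histograms.
#'
#' @param volume An `image_volume`.
#' @param mask A nonempty `roi_mask` on the same grid.
#' @param bin_width Bin width in intensity units (> 0).
#' @return A tibble of class `roi_histogram` with columns `bin_left`,
#'   `bin_right`, `count` (empty interior bins included), plus attributes
#'   `bin_width`, `units`, `roi`.
#' @export
roi_histogram <- function(volume, mask, bin_width = 1000) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(volume, mask)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be > 0.")
  }
  v <- volume$values[mask$values]
  if (length(v) == 0L) abort("Mask is empty; nothing to histogram.")
  if (any(v < 0)) abort("Zero-anchored histogram requires non-negative intensities.")
  bin <- floor(v / bin_width)
  lo <- min(bin)
  hi <- max(bin)
  counts <- tabulate(bin - lo + 1L, nbins = hi - lo + 1L)
  out <- tibble(
    bin_left = (lo:hi) * bin_width,
    bin_right = (lo:hi + 1) * bin_width,
    count = as.integer(counts)
  )
  attr(out, "bin_width") <- bin_width
  attr(out, "units") <- volume$units
  attr(out, "roi") <- mask$role
  class(out) <- c("roi_histogram", class(out))
  out
}

#' Fold enrichment of a subregion over its containing region
#'
#' The ratio of the mean intensity inside a subregion (e.g. a hypoxic
#' hotspot) to the mean over the whole containing region (e.g. the whole
#' tumor): `fold = mean(sub) / mean(whole)`. The subregion must be a voxel
#' subset of the whole region; violations are errors, as is a non-positive
#' whole-region mean.
#'
#' @param volume An `image_volume` (the channel being quantified).
#' @param sub_mask,whole_mask Nonempty `roi_mask`s on the volume's grid,
#'   with `sub_mask` a subset of `whole_mask`.
#' @return A one-row tibble of class `enrichment_result` with `sub_mean`,
#'   `whole_mean`, `fold`, `n_sub`, `n_whole`, `units`.
#' @export
fold_enrichment <- function(volume, sub_mask, whole_mask) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(sub_mask, "roi_mask"),
            inherits(whole_mask, "roi_mask"))
  check_same_grid(volume, sub_mask, "sub mask")
  check_same_grid(volume, whole_mask, "whole mask")
  if (!any(sub_mask$values)) abort("Subregion mask is empty.")
  if (!any(whole_mask$values)) abort("Whole-region mask is empty.")
  if (any(sub_mask$values & !whole_mask$values)) {
    abort("Subregion mask is not a subset of the whole-region mask.")
  }
  sub_mean <- mean(volume$values[sub_mask$values])
  whole_mean <- mean(volume$values[whole_mask$values])
  if (whole_mean <= 0) abort("Whole-region mean must be positive.")
  out <- tibble(sub_mean = sub_mean, whole_mean = whole_mean,
                fold = sub_mean / whole_mean,
                n_sub = sum(sub_mask$values),
                n_whole = sum(whole_mask$values), units = volume$units)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Compare CV heterogeneity between two groups of tumors
#'
#' Two-sample two-tailed t-test on per-tumor CV values — the comparison used
#' to ask whether hypoxia-positive tumors are more metabolically
#' heterogeneous than hypoxia-negative ones. The default is Student's pooled
#' t-test; Welch's unequal-variance variant is available via
#' `var_equal = FALSE`. Also reports the percent difference of group means,
#' `(mean_a - mean_b) / mean_b * 100`. Degenerate input (both groups
#' constant with equal means) yields `t = 0`, `p = 1`.
#'
#' @param cvs_a,cvs_b Numeric vectors of per-tumor CVs (each length >= 2).
#' @param var_equal Pool variances (Student) or not (Welch).
#' @return An object of class `cv_group_test`; see [tidy.cv_group_test()].
#' @examples
#' compare_cv_groups(c(0.30, 0.32, 0.31), c(0.19, 0.21, 0.20))
#' @export
compare_cv_groups <- function(cvs_a, cvs_b, var_equal = TRUE) {
  cvs_a <- as.numeric(cvs_a)
  cvs_b <- as.numeric(cvs_b)
  if (length(cvs_a) < 2L || length(cvs_b) < 2L) {
    abort("Each group needs at least 2 CV values.")
  }
  mean_a <- mean(cvs_a)
  mean_b <- mean(cvs_b)
  if (sd(cvs_a) == 0 && sd(cvs_b) == 0) {
    if (mean_a == mean_b) {
      tt <- list(statistic = c(t = 0), p.value = 1,
                 parameter = c(df = length(cvs_a) + length(cvs_b) - 2))
    } else {
      tt <- list(statistic = c(t = sign(mean_a - mean_b) * Inf), p.value = 0,
                 parameter = c(df = length(cvs_a) + length(cvs_b) - 2))
    }
  } else {
    tt <- t.test(cvs_a, cvs_b, var.equal = var_equal)
  }
  structure(
    list(mean_a = mean_a, mean_b = mean_b,
         pct_difference = (mean_a - mean_b) / mean_b * 100,
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         method = if (var_equal) "Student pooled t" else "Welch t",
         n_a = length(cvs_a), n_b = length(cvs_b),
         cvs_a = cvs_a, cvs_b = cvs_b),
    class = "cv_group_test"
  )
}

#' @export
print.cv_group_test <- function(x, ...) {
  cat(sprintf("<cv_group_test> %s: mean CV %.3f (n=%d) vs %.3f (n=%d)\n",
              x$method, x$mean_a, x$n_a, x$mean_b, x$n_b))
  cat(sprintf("  difference %+.1f%%, t = %.3f, df = %.1f, p = %.3g\n",
              x$pct_difference, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Tidy a CV group comparison
#'
#' `tidy()` returns the one-row test summary; `glance()` is an alias with
#' the same columns (the object holds a single fit).
#' @param x A `cv_group_test`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy cv_group_test
#' @export
tidy.cv_group_test <- function(x, ...) {
  tibble(mean_a = x$mean_a, mean_b = x$mean_b,
         pct_difference = x$pct_difference, statistic = x$statistic,
         df = x$df, p_value = x$p_value, n_a = x$n_a, n_b = x$n_b,
         method = x$method)
}

#' @rdname tidy.cv_group_test
#' @method glance cv_group_test
#' @export
glance.cv_group_test <- function(x, ...) tidy(x, ...)
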