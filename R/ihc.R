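#' Pixel classification parameters for positive-pixel scoring
#'
#' Brightness thresholds on the 0-255 grayscale (darker = stronger stain)
#' partitioning pixels into negative / weak / medium / strong classes. A
#' pixel is stain-positive when its brightness is at or below
#' `positivity_threshold`. The defaults follow the conventional
#' positive-pixel-count parameterization for DAB-stained sections; the exact
#' thresholds of commercial slide scorers are proprietary, so they are
#' explicit arguments here.
#'
#' @param positivity_threshold Brightness at or below which a pixel counts
#'   as positive.
#' @param medium_max,strong_max Class bounds: brightness `<= strong_max` is
#'   strong, `(strong_max, medium_max]` medium,
#'   `(medium_max, positivity_threshold]` weak.
#' @return A `pixel_class_params` object.
#' @export
pixel_class_params <- function(positivity_threshold = 220,
                               medium_max = 175, strong_max = 100) {
  thr <- c(strong_max, medium_max, positivity_threshold)
  if (any(diff(thr) <= 0)) {
    abort("Thresholds must satisfy strong_max < medium_max < positivity_threshold.")
  }
  if (positivity_threshold < 0 || positivity_threshold > 255) {
    abort("Thresholds live on the 0-255 brightness scale.")
  }
  structure(list(positivity_threshold = positivity_threshold,
                 medium_max = medium_max, strong_max = strong_max),
            class = "pixel_class_params")
}

#' Positive-pixel score of a stained region image
#'
#' Classifies each pixel of a 2D grayscale region image (0-255 brightness,
#' darker = stronger stain) as stain-positive or negative, and summarizes:
#' `positive_area_pct` is 100 times the positive-pixel fraction, and
#' `staining_intensity` is the mean *inverted* brightness (255 - value) over
#' the positive pixels. An image with no positive pixels scores (0, 0) —
#' a valid, unstained outcome. Deterministic.
#'
#' @param region_image 2D numeric matrix with values in the range 0-255.
#' @param params A [pixel_class_params()] object.
#' @return A one-row tibble: `staining_intensity`, `positive_area_pct`,
#'   `n_pixels`, `n_positive`, plus weak/medium/strong pixel fractions of
#'   the positive class.
#' @examples
#' img <- matrix(255, 10, 10); img[1:4, ] <- 105  # 40% at inverted 150
#' positive_pixel_score(img)
#' @export
positive_pixel_score <- function(region_image, params = pixel_class_params()) {
  if (!is.matrix(region_image) || length(region_image) == 0L) {
    abort("`region_image` must be a nonempty 2D matrix.")
  }
  if (any(region_image < 0 | region_image > 255)) {
    abort("Pixel values must lie in [0, 255].")
  }
  pos <- region_image <= params$positivity_threshold
  n <- length(region_image)
  np <- sum(pos)
  if (np == 0L) {
    return(tibble(staining_intensity = 0, positive_area_pct = 0,
                  n_pixels = n, n_positive = 0L,
                  frac_weak = 0, frac_medium = 0, frac_strong = 0))
  }
  v <- region_image[pos]
  tibble(
    staining_intensity = mean(255 - v),
    positive_area_pct = 100 * np / n,
    n_pixels = n, n_positive = as.integer(np),
    frac_weak = sum(v > params$medium_max) / np,
    frac_medium = sum(v > params$strong_max & v <= params$medium_max) / np,
    frac_strong = sum(v <= params$strong_max) / np
  )
}

#' Per-region protein expression score
#'
#' Expression in a region is the staining intensity multiplied by the
#' positive-area percentage (0-100 scale, so typical scores land in the
#' tens-to-thousands range under 0-255 intensities).
#'
#' @param staining_intensity Mean inverted brightness of positive pixels
#'   (>= 0).
#' @param positive_area_pct Positive area percentage on the 0-100 scale
#'   (>= 0).
#' @return Numeric expression score (vectorized).
#' @export
region_expression <- function(staining_intensity, positive_area_pct) {
  if (any(staining_intensity < 0) || any(positive_area_pct < 0)) {
    abort("Inputs must be >= 0.")
  }
  staining_intensity * positive_area_pct
}

#' Heterogeneity of a marker's regional expression scores
#'
#' Mean, sample SD, and CV (`sd / mean`) of per-region expression scores —
#' the per-marker heterogeneity summary computed over the scored regions of
#' a tumor section. CV is conventionally printed at 2 decimals; full
#' precision is returned.
#'
#' @param scores Numeric vector of per-region expression scores (length
#'   >= 2).
#' @param marker Optional marker name for the output row.
#' @return A one-row tibble: `marker`, `n_regions`, `mean`, `sd`, `cv`.
#' @examples
#' marker_heterogeneity(c(120, 130, 110, 140), marker = "HIF-1a")
#' @export
marker_heterogeneity <- function(scores, marker = NA_character_) {
  scores <- as.numeric(scores)
  if (length(scores) < 2L) abort("At least 2 region scores are required.")
  mu <- mean(scores)
  s <- sd(scores)
  tibble(marker = marker, n_regions = length(scores), mean = mu, sd = s,
         cv = if (mu > 0) s / mu else NA_real_)
}

#' Summarize an IHC region table into per-tumor, per-marker heterogeneity
#'
#' Takes a per-region table (as produced by [generate_ihc_fixture()] or read
#' from a CSV with columns `tumor_id, marker, region, intensity,
#' positive_area_pct`), computes each region's expression score via
#' [region_expression()], and reduces to one row per (tumor, marker) with
#' [marker_heterogeneity()].
#'
#' @param regions Data frame of per-region scores.
#' @return A tibble: `tumor_id`, `marker`, `n_regions`, `mean`, `sd`, `cv`.
#' @export
ihc_heterogeneity_table <- function(regions) {
  req <- c("tumor_id", "marker", "region", "intensity", "positive_area_pct")
  if (!all(req %in% names(regions))) {
    abort(sprintf("Region table must have columns: %s.",
                  paste(req, collapse = ", ")))
  }
  regions |>
    dplyr::mutate(score = region_expression(.data$intensity,
                                            .data$positive_area_pct)) |>
    dplyr::group_by(.data$tumor_id, .data$marker) |>
    dplyr::summarise(
      n_regions = dplyr::n(),
      mean = mean(.data$score),
      sd = sd(.data$score),
      cv = sd(.data$score) / mean(.data$score),
      .groups = "drop"
    )
}

#' Bundled study summary tables
#'
#' Two small reference tables ship with the package as plain CSVs:
#'
#' * `ihc_reference_summary()` — per-tumor, per-marker expression
#'   heterogeneity (mean, SD, printed CV) for four xenograft tumors scored
#'   for HIF-1a, LDH-M, CAIX and ATP5b over 20 regions each, with each
#'   tumor's hypoxia-probe status. Columns: `tumor_id`, `status`, `marker`,
#'   `mean`, `sd`, `cv`.
#' * `pet_reference_summary()` — per-patient FDG-PET descriptive statistics
#'   of the contracted tumor ROI (ROI-C) for a four-patient head-and-neck
#'   cohort. Columns: `patient`, `volume_mL`, `max`, `min`, `mean`,
#'   `median`, `sd`, `cv` (intensities in bq/mL; `cv` as printed at 2
#'   decimals).
#'
#' These are inputs for consistency checking (does `round(sd/mean, 2)`
#' reproduce the printed CV?) and for exercising the reporting format; see
#' the methods vignette for the two patient rows where the printed CV does
#' *not* equal `round(sd/mean, 2)`.
#'
#' @return A tibble.
#' @export
ihc_reference_summary <- function() {
  as_tibble(read.csv(system.file("extdata", "ihc_marker_summary.csv",
                                 package = "tumorhet"),
                     stringsAsFactors = FALSE))
}

#' @rdname ihc_reference_summary
#' @export
pet_reference_summary <- function() {
  as_tibble(read.csv(system.file("extdata", "pet_patient_stats.csv",
                                 package = "tumorhet"),
                     stringsAsFactors = FALSE))
}
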