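#' ROI biomarkers: area and mean ADC
#'
#' Area is `n_voxels` times the voxel area (spacing product), reported in
#' cm^2. Mean ADC is taken over the mask voxels with a valid ADC fit only;
#' `n_voxels` counts all mask voxels regardless of ADC validity.
#'
#' @param mask A [binary_mask()].
#' @param adc An `adc_fit` from [fit_adc()] on the same grid, or `NULL` to
#'   compute area only.
#' @return A list of class `roi_metrics`: `n_voxels`, `area_cm2`,
#'   `mean_adc` (mm^2/s; `NA` with flag `"no_valid_adc"` when no valid
#'   voxels fall inside the mask), `n_adc_valid`, `flags`.
#' @export
roi_metrics <- function(mask, adc = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  n_vox <- sum(mask$mask)
  area_cm2 <- n_vox * prod(mask$spacing) / 100  # mm^2 -> cm^2
  mean_adc <- NA_real_
  n_adc_valid <- NA_integer_
  flags <- character(0)
  if (n_vox == 0L) flags <- c(flags, "empty_mask")
  if (!is.null(adc)) {
    stopifnot(inherits(adc, "adc_fit"))
    stop_if_grid_mismatch(mask, list(values = adc$adc, spacing = adc$spacing,
                                     origin = adc$origin))
    sel <- mask$mask & adc$valid
    n_adc_valid <- sum(sel)
    if (n_adc_valid > 0L) {
      mean_adc <- mean(adc$adc[sel])
    } else if (n_vox > 0L) {
      flags <- c(flags, "no_valid_adc")
    }
  }
  structure(list(n_voxels = n_vox, area_cm2 = area_cm2, mean_adc = mean_adc,
                 n_adc_valid = n_adc_valid, flags = flags),
            class = "roi_metrics")
}

#' Dice similarity coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, in `[0, 1]`. Conventions for the
#' degenerate cases: both masks empty gives 1 (they are identical; flagged
#' upstream), exactly one empty gives 0.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Dice coefficient (numeric scalar).
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_grid_mismatch(a, b)
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0L) return(1)
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' Center of gravity of a binary mask
#'
#' Unweighted centroid of the physical coordinates of the member-voxel
#' centers; the segmentation geometry, not the intensity field, defines it.
#'
#' @param mask A non-empty [binary_mask()].
#' @return Numeric length-2 `(x, y)` in mm.
#' @export
center_of_gravity <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("center of gravity is not applicable to an empty mask")
  co <- voxel_coords(mask, idx[, 1] - 1L, idx[, 2] - 1L)
  colMeans(co)
}

#' Center-of-gravity displacement between two masks
#'
#' Euclidean distance between the two centroids (mm), plus a dimensionless
#' normalized displacement: distance divided by the square root of a
#' reference ROI area (the reference area expressed in mm^2, so the
#' denominator `10 * sqrt(area_cm2)` is a length in mm). If either mask is
#' empty the displacement is not applicable and flagged.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @param area_ref_cm2 Reference area (cm^2) for normalization, typically
#'   the manually delineated reference ROI; `NA` skips normalization.
#' @return A list of class `overlap_metrics`: `dice`, `cog_mm`,
#'   `cog_normalized`, `flags`.
#' @export
cog_displacement <- function(a, b, area_ref_cm2 = NA_real_) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_grid_mismatch(a, b)
  d <- dice(a, b)
  flags <- character(0)
  if (sum(a$mask) == 0L || sum(b$mask) == 0L) {
    flags <- "cog_not_applicable"
    if (sum(a$mask) + sum(b$mask) == 0L) flags <- c(flags, "both_empty")
    return(structure(list(dice = d, cog_mm = NA_real_,
                          cog_normalized = NA_real_, flags = flags),
                     class = "overlap_metrics"))
  }
  cog_mm <- sqrt(sum((center_of_gravity(a) - center_of_gravity(b))^2))
  cog_norm <- if (is.na(area_ref_cm2) || area_ref_cm2 <= 0) NA_real_
              else cog_mm / (10 * sqrt(area_ref_cm2))
  structure(list(dice = d, cog_mm = cog_mm, cog_normalized = cog_norm,
                 flags = flags),
            class = "overlap_metrics")
}
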