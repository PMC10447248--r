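#' Dixon fat-fraction map
#'
#' Per-voxel percent fat signal computed from co-registered Dixon fat and
#' water images:
#' `FF(%) = 100 * SI_fat / (SI_fat + SI_water)`.
#' Voxels where the denominator is zero (no signal, e.g. air) are flagged
#' invalid rather than silently set to 0, and are excluded from median
#' neighborhoods and from the adipose mask downstream.
#'
#' @param fat Dixon fat-signal [volume3d] (arbitrary MR units, >= 0).
#' @param water Dixon water-signal [volume3d], co-registered with `fat`.
#' @param tol_mm spacing tolerance passed to [validate_geometry()].
#' @return An object of class `fat_fraction_map`: a percent-unit [volume3d]
#'   plus a logical `valid` array; invalid voxels hold `NA`.
#' @export
compute_fat_fraction <- function(fat, water, tol_mm = 0.01) {
  stopifnot(inherits(fat, "volume3d"), inherits(water, "volume3d"))
  validate_geometry(list(fat, water), tol_mm)
  if (any(fat$values < 0, na.rm = TRUE) || any(water$values < 0, na.rm = TRUE))
    stop("signal intensities must be non-negative", call. = FALSE)
  denom <- fat$values + water$values
  valid <- denom > 0
  ff <- array(NA_real_, dim(fat$values))
  ff[valid] <- 100 * fat$values[valid] / denom[valid]
  structure(list(values = ff, valid = valid, spacing = fat$spacing,
                 units = "percent"),
            class = c("fat_fraction_map", "volume3d"))
}

#' @export
print.fat_fraction_map <- function(x, ...) {
  cat(sprintf("<fat_fraction_map> %s voxels, %d invalid\n",
              paste(dim(x$values), collapse = "x"), sum(!x$valid)))
  invisible(x)
}

#' Median spatial filter for a fat-fraction map
#'
#' Each valid voxel is replaced by the median of the valid voxels in its
#' window; borders are reflect-padded so the field of view does not
#' shrink. The validity mask is preserved. Default window is the smallest
#' isotropic one, 3x3x3.
#'
#' @param ffm a `fat_fraction_map` from [compute_fat_fraction()].
#' @param kernel integer length-3 window, all odd.
#' @return The filtered `fat_fraction_map`.
#' @export
median_filter_ffm <- function(ffm, kernel = c(3, 3, 3)) {
  stopifnot(inherits(ffm, "fat_fraction_map"))
  k <- check_odd_kernel(kernel)
  out <- median_filter_values(ffm$values, k)
  out[!ffm$valid] <- NA_real_
  ffm$values <- out
  ffm
}

#' Adipose-tissue mask from the fat-fraction map
#'
#' Keeps voxels with fat fraction at or above the threshold; voxels below
#' it are removed as non-adipose. Following the rule "below 50% removed",
#' a voxel at exactly the threshold is retained. Invalid voxels are never
#' included.
#'
#' @param ffm a `fat_fraction_map`.
#' @param threshold_pct fat-fraction cut in percent (default 50).
#' @return A [binary_mask] of adipose-tissue candidate voxels.
#' @export
adipose_mask <- function(ffm, threshold_pct = 50) {
  stopifnot(inherits(ffm, "fat_fraction_map"))
  if (!is.numeric(threshold_pct) || threshold_pct < 0 || threshold_pct > 100)
    stop("parameter error: threshold must lie in [0, 100] percent",
         call. = FALSE)
  keep <- ffm$valid & !is.na(ffm$values) & ffm$values >= threshold_pct
  binary_mask(array(keep, dim(ffm$values)), ffm$spacing)
}
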