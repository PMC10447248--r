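#' Adipose Hounsfield-unit window mask
#'
#' Keeps CT voxels with radiodensity in the adipose window, inclusive at
#' both ends (default -190 to -10 HU).
#'
#' @param ct [volume3d] with units `HU`.
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return A [binary_mask].
#' @export
hu_window_mask <- function(ct, lo = -190, hi = -10) {
  stopifnot(inherits(ct, "volume3d"))
  if (ct$units != "HU")
    stop("unit error: expected a CT volume in Hounsfield units", call. = FALSE)
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("parameter error: require lo < hi for the HU window", call. = FALSE)
  binary_mask(array(ct$values >= lo & ct$values <= hi, dim(ct$values)),
              ct$spacing)
}

#' Body-weight SUV threshold mask (strict)
#'
#' Keeps voxels with SUV_bw strictly greater than the threshold
#' (default > 1.5 g/ml), the rule used in the retrospective PET-CT branch.
#'
#' @param suv_bw [volume3d] with units `SUV-g/ml`.
#' @param threshold SUV cut, g/ml (> 0).
#' @return A [binary_mask].
#' @export
suv_bw_mask <- function(suv_bw, threshold = 1.5) {
  stopifnot(inherits(suv_bw, "volume3d"))
  if (suv_bw$units != "SUV-g/ml")
    stop("unit error: expected an SUV map (SUV-g/ml)", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("parameter error: SUV threshold must be > 0", call. = FALSE)
  binary_mask(array(suv_bw$values > threshold, dim(suv_bw$values)),
              suv_bw$spacing)
}

#' Classify a PET-CT scan as BAT-positive and summarize uptake
#'
#' Intersects the HU-window and SUV masks; the subject is BAT-positive iff
#' at least `min_voxels` voxels survive. SUV_mean is defined (non-`NA`)
#' only for positives; volume is voxel count times voxel volume in ml.
#'
#' @param ct_mask [binary_mask] from [hu_window_mask()].
#' @param suv_mask [binary_mask] from [suv_bw_mask()].
#' @param suv_bw the SUV [volume3d] the mean is taken over.
#' @param min_voxels minimum surviving-voxel count for positivity
#'   (default 1).
#' @return A list of class `ct_quant_result`: `bat_positive`, `suv_mean`,
#'   `bat_volume_ml`, `voxel_count`, `min_voxels`.
#' @export
classify_and_summarize <- function(ct_mask, suv_mask, suv_bw,
                                   min_voxels = 1L) {
  stopifnot(inherits(ct_mask, "binary_mask"), inherits(suv_mask, "binary_mask"),
            inherits(suv_bw, "volume3d"))
  validate_geometry(list(ct_mask, suv_mask, suv_bw))
  if (min_voxels < 1) stop("parameter error: min_voxels must be >= 1",
                           call. = FALSE)
  bat <- ct_mask$values & suv_mask$values
  n <- sum(bat)
  positive <- n >= min_voxels
  structure(list(
    bat_positive = positive,
    suv_mean = if (positive) mean(suv_bw$values[bat]) else NA_real_,
    bat_volume_ml = n * prod(ct_mask$spacing) / 1000,
    voxel_count = as.integer(n),
    min_voxels = as.integer(min_voxels)
  ), class = "ct_quant_result")
}

#' @export
print.ct_quant_result <- function(x, ...) {
  cat(sprintf("<ct_quant_result> BAT-%s: %d voxels, %.2f ml, SUV_mean %s\n",
              if (x$bat_positive) "positive" else "negative",
              x$voxel_count, x$bat_volume_ml,
              ifelse(is.na(x$suv_mean), "undefined", sprintf("%.3f", x$suv_mean))))
  invisible(x)
}

#' Run the retrospective PET-CT BAT analysis for one subject
#'
#' Computes SUV_bw from PET activity (or accepts a pre-computed SUV map),
#' applies the adipose HU window and the strict SUV_bw threshold,
#' optionally restricts to an anatomical search region, and classifies
#' BAT-positive/negative.
#'
#' @param ct CT [volume3d] in HU.
#' @param pet PET [volume3d] in kBq/ml (converted via `subject`) or
#'   `SUV-g/ml`.
#' @param subject a [subject_scan]; only needed when `pet` is in kBq/ml.
#' @param region optional [binary_mask] restricting the search.
#' @param config a [bat_config()]; uses `suv_bw_threshold`, `hu_lo`,
#'   `hu_hi`, `min_voxels`.
#' @return A `ct_quant_result`.
#' @export
run_ct_pipeline <- function(ct, pet, subject = NULL, region = NULL,
                            config = bat_config()) {
  config <- validate_config(config)
  validate_geometry(c(list(ct, pet), if (!is.null(region)) list(region)))
  suv_bw <- if (pet$units == "kBq/ml") {
    if (is.null(subject))
      stop("subject metadata required to convert kBq/ml to SUV", call. = FALSE)
    compute_suv_bw(pet, subject)
  } else if (pet$units == "SUV-g/ml") pet
  else stop("unit error: PET volume must be kBq/ml or SUV-g/ml", call. = FALSE)
  ct_mask <- hu_window_mask(ct, config$hu_lo, config$hu_hi)
  suv_mask <- suv_bw_mask(suv_bw, config$suv_bw_threshold)
  if (!is.null(region)) {
    ct_mask <- intersect_candidates(ct_mask, region)
    suv_mask <- intersect_candidates(suv_mask, region)
  }
  classify_and_summarize(ct_mask, suv_mask, suv_bw, config$min_voxels)
}
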