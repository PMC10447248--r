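#' Default run configuration
#'
#' All tunable parameters of the two imaging pipelines in one list. The
#' fixed study values are the defaults: 50% fat-fraction cut, SUV_lean >=
#' 1.2 g/ml (BARCIST, PET-MRI branch), SUV_bw > 1.5 g/ml and HU in
#' [-190, -10] (PET-CT branch), 3x3x3 median window, (3,3,1) in-plane
#' erosion footprint, minimum cluster of 1 voxel for BAT-positivity.
#' `suv_scale` selects the SUV map used for SUV_mean reporting in the MRI
#' branch (`"bw"` or `"lean"`); thresholding always uses SUV_lean there.
#'
#' @param ... named overrides of any default.
#' @return A named list of class `bat_config`.
#' @examples
#' cfg <- bat_config(ff_threshold_pct = 40)
#' cfg$ff_threshold_pct
#' @export
bat_config <- function(...) {
  cfg <- list(
    ff_threshold_pct  = 50,
    suv_lean_threshold = 1.2,
    suv_bw_threshold  = 1.5,
    hu_lo             = -190,
    hu_hi             = -10,
    min_voxels        = 1L,
    median_kernel     = c(3L, 3L, 3L),
    erosion_footprint = c(3L, 3L, 1L),
    suv_scale         = "bw",
    apply_erosion     = TRUE
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "bat_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$ff_threshold_pct >= 0, cfg$ff_threshold_pct <= 100,
            cfg$suv_lean_threshold > 0, cfg$suv_bw_threshold > 0,
            cfg$hu_lo < cfg$hu_hi, cfg$min_voxels >= 1)
  cfg$suv_scale <- match.arg(cfg$suv_scale, c("bw", "lean"))
  check_odd_kernel(cfg$median_kernel)
  check_odd_kernel(cfg$erosion_footprint, "footprint")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' Round-trips losslessly: `read_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param path YAML file.
#' @return `read_config` returns a `bat_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$min_voxels <- as.integer(raw$min_voxels)
  raw$median_kernel <- as.integer(raw$median_kernel)
  raw$erosion_footprint <- as.integer(raw$erosion_footprint)
  do.call(bat_config, raw)
}

#' @rdname read_config
#' @param cfg a `bat_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
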