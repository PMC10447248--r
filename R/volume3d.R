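#' @keywords internal
"_PACKAGE"

VOLUME_UNITS <- c("arbitrary-MR", "kBq/ml", "SUV-g/ml", "HU", "percent")

#' 3D scalar volume with voxel spacing
#'
#' The universal image carrier: a rectangular 3D lattice of scalars with
#' per-axis voxel spacing in millimetres and a declared intensity unit.
#' Arrays are indexed `(x, y, z)` with `z` the axial (slice) axis, so an
#' in-plane kernel such as the (3, 3, 1) erosion footprint acts within
#' axial slices.
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3, voxel size in mm along each axis; all > 0.
#' @param units intensity unit tag, one of `"arbitrary-MR"`, `"kBq/ml"`,
#'   `"SUV-g/ml"`, `"HU"`, `"percent"`.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(1, dim = c(4, 4, 4)), spacing = c(2, 2, 3),
#'               units = "kBq/ml")
#' voxel_volume_ml(v)  # 12 mm^3 = 0.012 ml
#' @export
volume3d <- function(values, spacing, units) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ",
         if (is.array(values)) paste0(length(dim(values)), "D") else class(values)[1],
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm", call. = FALSE)
  units <- match.arg(units, VOLUME_UNITS)
  structure(list(values = values, spacing = spacing, units = units),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing %s mm, units %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$units))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

#' Voxel volume in millilitres
#' @param x a `volume3d` or `binary_mask`.
#' @return Scalar, ml per voxel (spacing product / 1000).
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Binary voxel mask
#'
#' A logical lattice sharing the geometry of its source volume.
#'
#' @param values logical 3D array.
#' @param spacing numeric length-3 voxel size, mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L || !is.logical(values))
    stop("`values` must be a logical 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm", call. = FALSE)
  structure(list(values = values, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d set\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$values)

#' Integer label map with a legend
#'
#' Non-negative integer lattice in which 0 means unlabeled and every
#' nonzero value present must appear in the legend (e.g. depot search
#' regions, ground-truth tissue compartments, manually drawn muscle ROIs).
#'
#' @param values integer 3D array, values >= 0.
#' @param legend named character vector mapping label value (as name) to a
#'   region name, e.g. `c("1" = "supraclavicular", "2" = "paraspinal")`.
#' @param spacing numeric length-3 voxel size, mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(values, legend, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "integer"
  if (any(values < 0L, na.rm = TRUE))
    stop("label values must be non-negative", call. = FALSE)
  present <- setdiff(unique(as.integer(values)), 0L)
  if (is.null(names(legend)) || any(!nzchar(names(legend))))
    stop("`legend` must be a named vector: label value -> region name",
         call. = FALSE)
  legend <- stats::setNames(as.character(legend), names(legend))
  missing_lab <- setdiff(as.character(present), names(legend))
  if (length(missing_lab))
    stop("labels present but absent from legend: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  spacing <- as.numeric(spacing)
  structure(list(values = values, legend = legend, spacing = spacing),
            class = "label_map")
}

#' Mask of voxels carrying a given label name
#' @param map a `label_map`.
#' @param name region name as it appears in the legend.
#' @return A `binary_mask`.
#' @export
label_mask <- function(map, name) {
  stopifnot(inherits(map, "label_map"))
  hit <- names(map$legend)[map$legend == name]
  if (!length(hit))
    stop("label name not in legend: ", name, call. = FALSE)
  binary_mask(array(map$values %in% as.integer(hit), dim(map$values)),
              map$spacing)
}

#' Enforce the co-registration assumption
#'
#' Checks that all volumes share an identical lattice shape and that voxel
#' spacings agree within `tol_mm`. Registration itself is out of scope:
#' inputs are assumed co-registered and this guard makes the assumption
#' explicit.
#'
#' @param volumes list of `volume3d`/`binary_mask`/`label_map` objects (>= 2).
#' @param tol_mm spacing agreement tolerance in mm (default 0.01).
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
validate_geometry <- function(volumes, tol_mm = 0.01) {
  if (!is.list(volumes) || length(volumes) < 2L)
    stop("need at least two volumes to validate geometry", call. = FALSE)
  ref_dim <- dim(volumes[[1]]$values)
  ref_sp  <- volumes[[1]]$spacing
  for (i in seq_along(volumes)[-1]) {
    d <- dim(volumes[[i]]$values)
    if (!identical(as.integer(d), as.integer(ref_dim))) {
      ax <- which(d != ref_dim)
      stop(sprintf("geometry error: shape mismatch on axis %s (%s vs %s)",
                   paste(ax, collapse = ","),
                   paste(ref_dim, collapse = "x"), paste(d, collapse = "x")),
           call. = FALSE)
    }
    if (any(abs(volumes[[i]]$spacing - ref_sp) > tol_mm))
      stop(sprintf("geometry error: spacing mismatch beyond %g mm (%s vs %s)",
                   tol_mm, paste(format(ref_sp), collapse = "x"),
                   paste(format(volumes[[i]]$spacing), collapse = "x")),
           call. = FALSE)
  }
  invisible(TRUE)
}
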