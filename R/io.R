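#' Read a 3D volume from NIfTI
#'
#' Thin wrapper over [RNifti::readNifti()] returning a [volume3d] whose
#' spacing is taken from the header and whose unit tag is asserted by the
#' caller (NIfTI headers rarely carry trustworthy intensity units).
#'
#' @param path NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param expected_units unit tag to stamp on the volume; see [volume3d()].
#' @return A [volume3d].
#' @export
read_volume <- function(path, expected_units) {
  if (!file.exists(path))
    stop("format error: cannot read NIfTI file: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("format error: not a readable NIfTI file: ", path,
                         call. = FALSE))
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("dimensionality error: expected a 3D image, got %dD (%s)",
                 length(d), path), call. = FALSE)
  volume3d(array(as.numeric(img), dim = d),
           spacing = RNifti::pixdim(img)[seq_len(3)],
           units = expected_units)
}

#' Write a 3D volume, mask or label map to NIfTI
#'
#' @param x a [volume3d], [binary_mask] (written as uint8) or [label_map].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  vals <- x$values
  dtype <- NULL
  if (inherits(x, "binary_mask")) {
    vals <- array(as.integer(vals), dim(vals))
    dtype <- "uint8"
  } else if (inherits(x, "label_map")) {
    vals <- array(as.integer(vals), dim(vals))
    dtype <- "int16"
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = dtype %||% "auto")
  invisible(path)
}

#' Read a subject sidecar JSON
#'
#' Expects keys `weight_kg`, `height_m`, `sex`, `dose_MBq`.
#'
#' @param path JSON file.
#' @return A [subject_scan].
#' @export
read_subject <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("weight_kg", "height_m", "sex", "dose_MBq")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("subject sidecar missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  subject_scan(weight = s$weight_kg, height = s$height_m, sex = s$sex,
               injected_dose = s$dose_MBq)
}

#' Write a subject sidecar JSON
#' @param subject a [subject_scan].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subject <- function(subject, path) {
  jsonlite::write_json(
    list(weight_kg = subject$weight, height_m = subject$height,
         sex = subject$sex, dose_MBq = subject$injected_dose),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
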