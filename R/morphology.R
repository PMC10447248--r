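# 3D neighborhood machinery shared by the median filter and binary erosion.
# Everything is vectorized over offsets: one sub-array extraction per
# footprint cell, never a per-voxel loop.

check_odd_kernel <- function(k, what = "kernel") {
  k <- as.integer(k)
  if (length(k) != 3L || any(k < 1L) || any(k %% 2L == 0L))
    stop("parameter error: ", what, " dimensions must be odd and >= 1",
         call. = FALSE)
  k
}

# reflect-pad a 3D array by r voxels per axis (edge voxel duplicated)
reflect_pad <- function(v, r) {
  d <- dim(v)
  ix <- lapply(1:3, function(a) {
    n <- d[a]; ra <- r[a]
    c(rev(seq_len(min(ra, n))), seq_len(n), rev(seq_len(n))[seq_len(min(ra, n))])
  })
  v[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# gather the k1*k2*k3 neighborhood of every voxel into a matrix
# (rows = voxels in array order, cols = footprint offsets)
neighborhood_matrix <- function(padded, d, k) {
  r <- (k - 1L) %/% 2L
  m <- matrix(NA_real_, nrow = prod(d), ncol = prod(k))
  col <- 1L
  for (dz in seq_len(k[3]) - 1L)
    for (dy in seq_len(k[2]) - 1L)
      for (dx in seq_len(k[1]) - 1L) {
        m[, col] <- padded[dx + seq_len(d[1]),
                           dy + seq_len(d[2]),
                           dz + seq_len(d[3])]
        col <- col + 1L
      }
  m
}

#' Binary erosion with a centered structuring element
#'
#' Standard full-footprint erosion: a voxel survives iff every voxel under
#' the centered footprint is set. Voxels outside the volume are treated as
#' background, so masks shrink at the volume edge. The default
#' `c(3, 3, 1)` footprint is the in-plane element used to strip PET
#' blooming and boundary artefacts from BAT ROIs (the `1` applies to the
#' axial z axis).
#'
#' @param mask a [binary_mask].
#' @param footprint integer length-3, odd per-axis extents.
#' @return The eroded [binary_mask].
#' @examples
#' m <- binary_mask(array(TRUE, dim = c(5, 5, 1)), spacing = c(2, 2, 2))
#' sum(erode_mask(m, c(3, 3, 1))$values)  # 5x5 square erodes to 3x3 = 9
#' @export
erode_mask <- function(mask, footprint = c(3, 3, 1)) {
  stopifnot(inherits(mask, "binary_mask"))
  k <- check_odd_kernel(footprint, "footprint")
  v <- mask$values
  d <- dim(v)
  r <- (k - 1L) %/% 2L
  padded <- array(FALSE, d + 2L * r)
  padded[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3])] <- v
  out <- array(TRUE, d)
  for (dz in seq_len(k[3]) - 1L)
    for (dy in seq_len(k[2]) - 1L)
      for (dx in seq_len(k[1]) - 1L)
        out <- out & padded[dx + seq_len(d[1]),
                            dy + seq_len(d[2]),
                            dz + seq_len(d[3])]
  binary_mask(out, mask$spacing)
}

# validity-aware 3D median with reflect padding; NA marks invalid voxels,
# which are excluded from every neighborhood
median_filter_values <- function(v, k) {
  d <- dim(v)
  r <- (k - 1L) %/% 2L
  m <- neighborhood_matrix(reflect_pad(v, r), d, k)
  out <- apply(m, 1L, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_  # all-invalid neighborhoods stay invalid
  array(out, d)
}
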