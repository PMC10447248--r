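# Brute-force voxel-loop oracles, kept deliberately naive and independent
# of the package's vectorized implementations.

reflect_index <- function(i, n) {
  # scipy-style 'reflect' (edge duplicated): ... 2 1 | 1 2 ... n | n n-1 ...
  if (i < 1) return(1 - i)
  if (i > n) return(2 * n + 1 - i)
  i
}

brute_median_filter <- function(v, k) {
  d <- dim(v)
  r <- (k - 1L) %/% 2L
  out <- array(NA_real_, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    vals <- c()
    for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
      vals <- c(vals, v[reflect_index(x + dx, d[1]),
                        reflect_index(y + dy, d[2]),
                        reflect_index(z + dz, d[3])])
    }
    out[x, y, z] <- stats::median(vals, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

brute_erode <- function(v, fp) {
  d <- dim(v)
  r <- (fp - 1L) %/% 2L
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    keep <- TRUE
    for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      inside <- xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
        zz >= 1 && zz <= d[3]
      if (!inside || !v[xx, yy, zz]) { keep <- FALSE; break }
    }
    out[x, y, z] <- keep
  }
  out
}

brute_roi_summary <- function(vol, labels, lab) {
  vals <- c()
  d <- dim(vol)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3]))
    if (labels[x, y, z] == lab) vals <- c(vals, vol[x, y, z])
  list(mean = mean(vals), max = max(vals), n = length(vals))
}

random_mask <- function(d, p = 0.5) array(stats::runif(prod(d)) < p, d)

# small two-depot phantom for fast end-to-end tests
tiny_phantom_spec <- function(seed = 1L, bat_suv = 4, ...) {
  comps <- list(
    compartment("body", "body", "box", lo = c(1, 1, 1), hi = c(16, 16, 8),
                ff = 20, suv = 0.5, hu = 20),
    compartment("scv_fat", "wat", center = c(5, 5, 4), radii = c(5, 5, 4),
                ff = 70, suv = 0.5, hu = -100),
    compartment("para_fat", "wat", center = c(12, 12, 4), radii = c(4, 4, 4),
                ff = 70, suv = 0.5, hu = -100),
    compartment("scv", "bat", center = c(5, 5, 4), radii = c(3, 3, 2),
                ff = 70, suv = bat_suv, hu = -100, group = "supraclavicular"),
    compartment("para", "bat", center = c(12, 12, 4), radii = c(2, 2, 2),
                ff = 70, suv = bat_suv, hu = -100, group = "paraspinal")
  )
  phantom_spec(shape = c(16, 16, 8), spacing = c(3, 3, 3),
               compartments = comps,
               subject = subject_scan(65, 1.70, "female", 75),
               seed = seed, ...)
}

tiny_depot_regions <- function(spacing = c(3, 3, 3)) {
  v <- array(0L, c(16, 16, 8))
  v[1:8, 1:8, ] <- 1L
  v[9:16, 9:16, ] <- 2L
  label_map(v, c("1" = "supraclavicular", "2" = "paraspinal"), spacing)
}

# study-conditions noise used in noisy-recovery checks: PET sigma is 5% of
# the programmed depot SUV (4.0), MR sigma 2 signal units, CT sigma 10 HU
study_noise <- function(bat_suv = 4.0)
  list(fat = 2, water = 2, pet = 0.05 * bat_suv, ct = 10)
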