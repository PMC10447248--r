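# Synthetic co-registered Dixon/PET/CT phantoms with ground-truth labels.
# Compartments are ellipsoids or boxes rasterized on the voxel lattice;
# later compartments overwrite earlier ones. Dixon fat/water signals are
# constructed so the fat-fraction equation reproduces the programmed FF
# (fat = FF, water = 100 - FF in arbitrary units), and PET is stored as
# activity in kBq/ml derived from the programmed SUV target through the
# subject's dose and (lean) body mass, so the SUV arithmetic is exercised
# rather than bypassed.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a phantom compartment
#'
#' @param name compartment name (unique within a spec).
#' @param tissue tissue class: `"bat"`, `"wat"`, `"muscle"`, `"brain"` or
#'   `"body"`.
#' @param shape `"ellipsoid"` (needs `center`, `radii`, in voxel indices)
#'   or `"box"` (needs `lo`, `hi`, inclusive voxel index corners).
#' @param center,radii ellipsoid center and semi-axes, voxels.
#' @param lo,hi box corners, voxels.
#' @param ff programmed fat fraction, percent in [0, 100].
#' @param suv programmed SUV target (interpretation set by the spec's
#'   `suv_scale`), g/ml.
#' @param hu programmed CT radiodensity, HU.
#' @param group depot-group name for BAT compartments (e.g.
#'   `"supraclavicular"`, `"paraspinal"`); ignored otherwise.
#' @return A compartment definition list.
#' @export
compartment <- function(name, tissue, shape = c("ellipsoid", "box"),
                        center = NULL, radii = NULL, lo = NULL, hi = NULL,
                        ff, suv, hu, group = NULL) {
  shape <- match.arg(shape)
  tissue <- match.arg(tissue, c("bat", "wat", "muscle", "brain", "body"))
  if (ff < 0 || ff > 100) stop("FF must lie in [0, 100]", call. = FALSE)
  if (suv < 0) stop("SUV must be >= 0", call. = FALSE)
  if (shape == "ellipsoid" && (is.null(center) || is.null(radii)))
    stop("ellipsoid needs center and radii", call. = FALSE)
  if (shape == "box" && (is.null(lo) || is.null(hi)))
    stop("box needs lo and hi corners", call. = FALSE)
  list(name = name, tissue = tissue, shape = shape, center = center,
       radii = radii, lo = lo, hi = hi, ff = ff, suv = suv, hu = hu,
       group = group)
}

rasterize_compartment <- function(comp, shape3) {
  if (comp$shape == "ellipsoid") {
    cx <- comp$center; rr <- comp$radii
    ix <- ((seq_len(shape3[1]) - cx[1]) / rr[1])^2
    iy <- ((seq_len(shape3[2]) - cx[2]) / rr[2])^2
    iz <- ((seq_len(shape3[3]) - cx[3]) / rr[3])^2
    outer(outer(ix, iy, `+`), iz, `+`) <= 1
  } else {
    lo <- pmax(comp$lo, 1); hi <- pmin(comp$hi, shape3)
    m <- array(FALSE, shape3)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
}

#' Phantom specification
#'
#' @param shape grid extents, voxels.
#' @param spacing voxel size, mm.
#' @param compartments list of [compartment()] definitions; later entries
#'   overwrite earlier ones where they overlap (a warning is logged).
#' @param subject a [subject_scan] providing dose and masses for the SUV
#'   arithmetic.
#' @param noise named list of additive Gaussian sigmas per modality:
#'   `fat`, `water` (arbitrary MR units), `pet` (SUV units), `ct` (HU).
#' @param suv_scale `"lean"` (default) or `"bw"`: the mass scale on which
#'   compartment SUV targets are programmed. The MRI branch thresholds on
#'   SUV_lean, the CT branch on SUV_bw.
#' @param seed integer RNG seed; generation is deterministic given it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, compartments, subject,
                         noise = list(fat = 0, water = 0, pet = 0, ct = 0),
                         suv_scale = c("lean", "bw"), seed = 1L) {
  suv_scale <- match.arg(suv_scale)
  noise <- utils::modifyList(list(fat = 0, water = 0, pet = 0, ct = 0), noise)
  if (any(unlist(noise) < 0)) stop("noise sigmas must be >= 0", call. = FALSE)
  nm <- vapply(compartments, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("compartment names must be unique", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 compartments = compartments, subject = subject,
                 noise = noise, suv_scale = suv_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default study-like phantom
#'
#' A 48 x 48 x 24 torso-and-neck grid at 2.5 mm isotropic spacing: an air
#' background, a lean body compartment (FF 20%, SUV 0.5, HU +20), left and
#' right supraclavicular and one paraspinal active BAT depot (FF 70%, SUV
#' 4.0, HU -100), a subcutaneous WAT depot (FF 85%, SUV 0.5, HU -100), a
#' muscle block (FF 5%, SUV 0.8, HU +40) and a brain blob with avid uptake
#' (FF 5%, SUV 6, HU +40). The subject mirrors the imaging cohort: 65 kg,
#' 1.70 m, 75 MBq injected dose.
#'
#' @param seed RNG seed.
#' @param noise per-modality sigmas, as in [phantom_spec()].
#' @param bat_suv,bat_ff programmed BAT SUV target and fat fraction.
#' @param suv_scale mass scale of the SUV targets.
#' @param sex subject sex.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(seed = 1L,
                                 noise = list(fat = 0, water = 0,
                                              pet = 0, ct = 0),
                                 bat_suv = 4.0, bat_ff = 70,
                                 suv_scale = "lean", sex = "female") {
  # each BAT depot is embedded in a surrounding adipose shell (2 voxels
  # thicker on every semi-axis) of matched fat fraction: supraclavicular
  # and paraspinal BAT sit inside fat depots in vivo, and the matched FF
  # makes the programmed depot FF an exact fixed point of the median
  # filter so ground truth stays analytic
  comps <- list(
    compartment("body", "body", "box", lo = c(3, 3, 1), hi = c(46, 46, 24),
                ff = 20, suv = 0.5, hu = 20),
    compartment("muscle", "muscle", "box", lo = c(40, 30, 4), hi = c(46, 44, 18),
                ff = 5, suv = 0.8, hu = 40),
    compartment("wat", "wat", center = c(10, 36, 8), radii = c(5, 5, 5),
                ff = 85, suv = 0.5, hu = -100),
    compartment("brain", "brain", center = c(24, 24, 22), radii = c(8, 8, 2.5),
                ff = 5, suv = 6, hu = 40),
    compartment("scv_left_fat", "wat", center = c(14, 14, 14),
                radii = c(7, 6, 5), ff = bat_ff, suv = 0.5, hu = -100),
    compartment("scv_right_fat", "wat", center = c(34, 14, 14),
                radii = c(7, 6, 5), ff = bat_ff, suv = 0.5, hu = -100),
    compartment("paraspinal_fat", "wat", center = c(24, 34, 10),
                radii = c(6, 6, 7), ff = bat_ff, suv = 0.5, hu = -100),
    compartment("scv_left", "bat", center = c(14, 14, 14), radii = c(5, 4, 3),
                ff = bat_ff, suv = bat_suv, hu = -100,
                group = "supraclavicular"),
    compartment("scv_right", "bat", center = c(34, 14, 14), radii = c(5, 4, 3),
                ff = bat_ff, suv = bat_suv, hu = -100,
                group = "supraclavicular"),
    compartment("paraspinal", "bat", center = c(24, 34, 10), radii = c(4, 4, 5),
                ff = bat_ff, suv = bat_suv, hu = -100,
                group = "paraspinal")
  )
  phantom_spec(shape = c(48, 48, 24), spacing = c(2.5, 2.5, 2.5),
               compartments = comps,
               subject = subject_scan(65, 1.70, sex, 75),
               noise = noise, suv_scale = suv_scale, seed = seed)
}

# depot search regions: anterior half of the grid for the SCV group,
# posterior half for paraspinal; disjoint by construction
default_depot_regions <- function(shape3, spacing) {
  v <- array(0L, shape3)
  half <- shape3[2] %/% 2L
  v[, seq_len(half), ] <- 1L
  v[, (half + 2L):shape3[2], ] <- 2L
  label_map(v, c("1" = "supraclavicular", "2" = "paraspinal"), spacing)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Generate a co-registered phantom bundle
#'
#' Rasterizes the compartments, builds Dixon fat/water signals whose
#' fat-fraction equation reproduces the programmed FF exactly at zero
#' noise, converts SUV targets to PET activity (kBq/ml) through the
#' subject's injected dose and mass, assigns HU values, adds per-modality
#' additive Gaussian noise (intensities clamped at 0 for MR and PET), and
#' emits the ground-truth label map plus default depot search regions.
#' Outside every compartment is air: zero MR signal (fat fraction
#' undefined), zero activity, -1000 HU.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_bundle`: `fat`, `water`, `pet`, `ct`
#'   ([volume3d]), `truth` ([label_map], legend = depot group for BAT
#'   compartments, compartment name otherwise), `depot_regions`
#'   ([label_map]), `brain_mask` ([binary_mask]), `subject`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ff <- array(NA_real_, d)    # NA = air, no MR signal
  suv <- array(0, d)
  hu <- array(-1000, d)
  labels <- array(0L, d)
  legend <- character(0)
  overlap_log <- character(0)
  for (i in seq_along(spec$compartments)) {
    comp <- spec$compartments[[i]]
    m <- rasterize_compartment(comp, d)
    n_over <- sum(labels[m] != 0L)
    if (n_over > 0)  # painter's algorithm: later compartment wins
      overlap_log <- c(overlap_log,
                       sprintf("%s overwrites %d voxels", comp$name, n_over))
    ff[m] <- comp$ff
    suv[m] <- comp$suv
    hu[m] <- comp$hu
    labels[m] <- i
    legend[as.character(i)] <- comp$group %||% comp$name
  }

  mass_kg <- if (spec$suv_scale == "lean") compute_lbm(spec$subject)
             else spec$subject$weight
  act_per_suv <- (spec$subject$injected_dose * 1000) / (mass_kg * 1000)
  fat_sig <- ifelse(is.na(ff), 0, ff)
  water_sig <- ifelse(is.na(ff), 0, 100 - ff)
  pet_act <- suv * act_per_suv

  with_seed(spec$seed, {
    n <- prod(d)
    if (spec$noise$fat > 0)
      fat_sig <- pmax(fat_sig + stats::rnorm(n, 0, spec$noise$fat), 0)
    if (spec$noise$water > 0)
      water_sig <- pmax(water_sig + stats::rnorm(n, 0, spec$noise$water), 0)
    if (spec$noise$pet > 0)
      pet_act <- pmax(pet_act +
                        stats::rnorm(n, 0, spec$noise$pet * act_per_suv), 0)
    if (spec$noise$ct > 0)
      hu <- hu + stats::rnorm(n, 0, spec$noise$ct)
  })

  truth <- label_map(labels, legend, spec$spacing)
  brain_idx <- which(vapply(spec$compartments, `[[`, character(1),
                            "tissue") == "brain")
  brain_mask <- binary_mask(array(labels %in% brain_idx, d), spec$spacing)
  structure(list(
    fat = volume3d(array(fat_sig, d), spec$spacing, "arbitrary-MR"),
    water = volume3d(array(water_sig, d), spec$spacing, "arbitrary-MR"),
    pet = volume3d(array(pet_act, d), spec$spacing, "kBq/ml"),
    ct = volume3d(array(hu, d), spec$spacing, "HU"),
    truth = truth, depot_regions = default_depot_regions(d, spec$spacing),
    brain_mask = brain_mask, subject = spec$subject, spec = spec,
    log = overlap_log
  ), class = "phantom_bundle")
}

#' Segmentation accuracy against ground truth
#'
#' Dice coefficient `2|A n B| / (|A| + |B|)` and relative volume error per
#' depot group, computed on the pre-erosion masks (erosion intentionally
#' shrinks masks below truth).
#'
#' @param truth ground-truth [label_map] (as in a `phantom_bundle`).
#' @param seg a `bat_segmentation`.
#' @return Data frame with columns `group`, `dice`,
#'   `volume_error_pct` (100 * (recovered - truth) / truth).
#' @export
evaluate_recovery <- function(truth, seg) {
  stopifnot(inherits(truth, "label_map"), inherits(seg, "bat_segmentation"))
  rows <- lapply(names(seg$groups), function(g) {
    if (!g %in% truth$legend)
      return(data.frame(group = g, dice = NA_real_,
                        volume_error_pct = NA_real_))
    tm <- label_mask(truth, g)$values
    validate_geometry(list(list(values = tm, spacing = truth$spacing),
                           seg$groups[[g]]$pre))
    sm <- seg$groups[[g]]$pre$values
    inter <- sum(tm & sm)
    data.frame(group = g,
               dice = if (sum(tm) + sum(sm) == 0) 1 else
                 2 * inter / (sum(tm) + sum(sm)),
               volume_error_pct = 100 * (sum(sm) - sum(tm)) / sum(tm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Crossover study simulation specification
#'
#' Models a placebo/treatment crossover on BAT imaging: per subject a pair
#' of phantoms sharing anatomy, with the treated arm's BAT SUV and depot
#' volume scaled down multiplicatively and its fat fraction shifted up.
#'
#' @param n_subjects number of simulated subjects.
#' @param prevalence probability a subject carries active BAT (inactive
#'   subjects get BAT depots at background SUV).
#' @param suv_effect multiplicative SUV factor under treatment (0.5 halves
#'   uptake; 1 = no effect).
#' @param volume_effect multiplicative depot-volume factor (radii scaled
#'   by its cube root).
#' @param ff_shift additive fat-fraction change under treatment, percent.
#' @param seed integer RNG seed.
#' @return A list of class `study_sim_spec`.
#' @export
study_sim_spec <- function(n_subjects = 15L, prevalence = 13 / 15,
                           suv_effect = 0.5, volume_effect = 1.0,
                           ff_shift = 5, seed = 1L) {
  stopifnot(n_subjects >= 1, prevalence >= 0, prevalence <= 1,
            suv_effect >= 0, volume_effect >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 prevalence = prevalence, suv_effect = suv_effect,
                 volume_effect = volume_effect, ff_shift = ff_shift,
                 seed = as.integer(seed)),
            class = "study_sim_spec")
}

scale_bat_compartments <- function(spec, suv_factor = 1, radius_factor = 1,
                                   ff_shift = 0, suv_override = NULL) {
  spec$compartments <- lapply(spec$compartments, function(comp) {
    if (comp$tissue != "bat") return(comp)
    comp$suv <- if (!is.null(suv_override)) suv_override
                else comp$suv * suv_factor
    comp$ff <- min(100, max(0, comp$ff + ff_shift))
    if (comp$shape == "ellipsoid") comp$radii <- comp$radii * radius_factor
    comp
  })
  spec
}

#' Simulate a placebo/treated crossover imaging cohort
#'
#' For each subject, draws active-BAT status with the programmed
#' prevalence and a small anatomical jitter of depot radii, then emits a
#' placebo-arm and a treated-arm phantom sharing that anatomy. In the
#' treated arm the BAT SUV and depot radii are scaled per the sim spec
#' and the fat fraction shifted. Inactive subjects carry BAT depots at
#' background SUV (0.5) in both arms. Fully reproducible given the seed.
#'
#' @param sim a [study_sim_spec()].
#' @param base a [phantom_spec()] for the placebo arm (e.g.
#'   [default_phantom_spec()]).
#' @return A list of per-subject lists: `placebo`, `treated`
#'   (`phantom_bundle`), `active` (logical).
#' @export
simulate_study <- function(sim, base = default_phantom_spec()) {
  stopifnot(inherits(sim, "study_sim_spec"), inherits(base, "phantom_spec"))
  with_seed(sim$seed, {
    active <- stats::runif(sim$n_subjects) < sim$prevalence
    jitter <- stats::runif(sim$n_subjects, 0.9, 1.1)
    seeds <- sample.int(2^30, 2 * sim$n_subjects)
    lapply(seq_len(sim$n_subjects), function(i) {
      placebo_spec <- scale_bat_compartments(
        base, radius_factor = jitter[i],
        suv_override = if (!active[i]) 0.5 else NULL)
      treated_spec <- scale_bat_compartments(
        placebo_spec,
        suv_factor = if (active[i]) sim$suv_effect else 1,
        radius_factor = if (active[i]) sim$volume_effect^(1 / 3) else 1,
        ff_shift = if (active[i]) sim$ff_shift else 0)
      placebo_spec$seed <- seeds[2 * i - 1]
      treated_spec$seed <- seeds[2 * i]
      list(placebo = generate_phantom(placebo_spec),
           treated = generate_phantom(treated_spec),
           active = active[i])
    })
  })
}
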