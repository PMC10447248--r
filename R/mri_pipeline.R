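#' PET threshold mask on the lean-mass SUV scale
#'
#' Applies the BARCIST BAT criterion: voxels with SUV_lean at or above the
#' threshold (default 1.2 g/ml) are kept; the boundary value is included.
#'
#' @param suv_lean [volume3d] with units `SUV-g/ml`.
#' @param threshold SUV_lean cut, g/ml (> 0).
#' @return A [binary_mask].
#' @export
pet_threshold_mask <- function(suv_lean, threshold = 1.2) {
  stopifnot(inherits(suv_lean, "volume3d"))
  if (suv_lean$units != "SUV-g/ml")
    stop("unit error: expected an SUV map (SUV-g/ml)", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("parameter error: SUV threshold must be > 0", call. = FALSE)
  binary_mask(array(suv_lean$values >= threshold, dim(suv_lean$values)),
              suv_lean$spacing)
}

#' Remove excluded regions from a mask
#'
#' Models the manual removal of ROIs overlapping structures such as the
#' brain: the exclusion is supplied as a mask and subtracted
#' (`mask AND NOT exclusion`).
#'
#' @param mask,exclusion co-registered [binary_mask] objects.
#' @return A [binary_mask].
#' @export
apply_exclusions <- function(mask, exclusion) {
  stopifnot(inherits(mask, "binary_mask"), inherits(exclusion, "binary_mask"))
  validate_geometry(list(mask, exclusion))
  binary_mask(mask$values & !exclusion$values, mask$spacing)
}

#' Intersect the adipose and PET threshold masks
#'
#' Voxels meeting both the fat-fraction and PET criteria are the BAT
#' candidates.
#'
#' @param adipose,pet co-registered [binary_mask] objects.
#' @return A [binary_mask].
#' @export
intersect_candidates <- function(adipose, pet) {
  stopifnot(inherits(adipose, "binary_mask"), inherits(pet, "binary_mask"))
  validate_geometry(list(adipose, pet))
  binary_mask(adipose$values & pet$values, adipose$spacing)
}

#' Partition BAT candidate voxels into depot groups
#'
#' Cervical, supraclavicular and axillary depots are conventionally tagged
#' together as one supraclavicular (SCV) group, with paraspinal BAT tagged
#' separately. The depot definition is a [label_map] of anatomical search
#' regions; candidate voxels falling outside every region are reported as
#' unassigned, never silently dropped into a group.
#'
#' @param candidates [binary_mask] of BAT candidate voxels.
#' @param depots [label_map] whose legend values are depot-group names
#'   (e.g. `"supraclavicular"`, `"paraspinal"`); a label map assigns at
#'   most one group per voxel, so groups cannot overlap.
#' @return An object of class `bat_segmentation` holding one pre-erosion
#'   [binary_mask] per group (`$groups`), the unassigned mask
#'   (`$unassigned`), and a provenance list. Erosion is added by
#'   [erode_segmentation()].
#' @export
tag_depots <- function(candidates, depots) {
  stopifnot(inherits(candidates, "binary_mask"), inherits(depots, "label_map"))
  validate_geometry(list(candidates, depots))
  group_names <- unique(unname(depots$legend))
  groups <- lapply(group_names, function(g) {
    region <- label_mask(depots, g)
    list(pre = intersect_candidates(candidates, region), post = NULL)
  })
  names(groups) <- group_names
  assigned <- Reduce(`|`, lapply(groups, function(g) g$pre$values))
  structure(list(
    groups = groups,
    unassigned = binary_mask(candidates$values & !assigned,
                             candidates$spacing),
    spacing = candidates$spacing,
    provenance = list(depot_groups = group_names)
  ), class = "bat_segmentation")
}

#' Erode every depot-group mask of a segmentation
#'
#' Applies [erode_mask()] per group with the in-plane (3,3,1) footprint by
#' default, retaining the pre-erosion masks so metrics can be reported
#' both ways.
#'
#' @param seg a `bat_segmentation` from [tag_depots()].
#' @param footprint odd per-axis structuring element extents.
#' @return The segmentation with `$groups[[g]]$post` filled in.
#' @export
erode_segmentation <- function(seg, footprint = c(3, 3, 1)) {
  stopifnot(inherits(seg, "bat_segmentation"))
  seg$groups <- lapply(seg$groups, function(g) {
    g$post <- erode_mask(g$pre, footprint)
    g
  })
  seg$provenance$erosion_footprint <- as.integer(footprint)
  seg
}

#' @export
print.bat_segmentation <- function(x, ...) {
  cat("<bat_segmentation>\n")
  for (g in names(x$groups)) {
    pre <- sum(x$groups[[g]]$pre$values)
    post <- if (is.null(x$groups[[g]]$post)) NA else sum(x$groups[[g]]$post$values)
    cat(sprintf("  %-18s pre %5d voxels, post-erosion %s\n", g, pre,
                ifelse(is.na(post), "-", post)))
  }
  cat(sprintf("  unassigned %d voxels\n", sum(x$unassigned$values)))
  invisible(x)
}

mask_metrics_row <- function(mask_values, spacing, suv_values, ff_values,
                             group, eroded) {
  n <- sum(mask_values)
  vox_ml <- prod(spacing) / 1000
  if (n == 0) {
    return(data.frame(group = group, eroded = eroded, voxel_count = 0L,
                      suv_mean = NA_real_, volume_ml = 0,
                      total_uptake = 0, fat_fraction_pct = NA_real_,
                      stringsAsFactors = FALSE))
  }
  suv_mean <- mean(suv_values[mask_values])
  vol <- n * vox_ml
  data.frame(group = group, eroded = eroded, voxel_count = as.integer(n),
             suv_mean = suv_mean, volume_ml = vol,
             total_uptake = suv_mean * vol,
             fat_fraction_pct = mean(ff_values[mask_values], na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' BAT metrics per depot group
#'
#' For each depot group (and all groups combined), computes SUV_mean (g/ml,
#' arithmetic mean over the mask), BAT volume (voxel count times voxel
#' volume, ml), total uptake (SUV_mean times volume) and mean fat fraction
#' (%). Metrics are reported for the pre-erosion masks and, when present,
#' the post-erosion masks. An empty group is reported with volume 0 and an
#' undefined (`NA`) SUV_mean rather than 0, so it cannot bias group
#' averages.
#'
#' @param seg a `bat_segmentation`.
#' @param suv SUV [volume3d] used for SUV_mean (body-weight or lean scale).
#' @param ffm a `fat_fraction_map`.
#' @return A data frame with columns `group`, `eroded`, `voxel_count`,
#'   `suv_mean`, `volume_ml`, `total_uptake`, `fat_fraction_pct`.
#' @export
compute_metrics <- function(seg, suv, ffm) {
  stopifnot(inherits(seg, "bat_segmentation"), inherits(suv, "volume3d"),
            inherits(ffm, "fat_fraction_map"))
  validate_geometry(c(lapply(seg$groups, function(g) g$pre),
                      list(suv, ffm)))
  rows <- list()
  for (phase in c("pre", "post")) {
    masks <- lapply(seg$groups, function(g) g[[phase]])
    if (any(vapply(masks, is.null, logical(1)))) next
    eroded <- phase == "post"
    for (g in names(masks))
      rows[[length(rows) + 1L]] <-
        mask_metrics_row(masks[[g]]$values, seg$spacing, suv$values,
                         ffm$values, g, eroded)
    combined <- Reduce(`|`, lapply(masks, function(m) m$values))
    rows[[length(rows) + 1L]] <-
      mask_metrics_row(combined, seg$spacing, suv$values, ffm$values,
                       "combined", eroded)
  }
  do.call(rbind, rows)
}

#' Per-label summary of a volume over manually drawn ROIs
#'
#' Mean, max and voxel count of a volume (typically an SUV map) within
#' each labeled region, e.g. reference muscle ROIs (pectoralis major,
#' psoas major, sternocleidomastoid, longus colli, trapezius) and
#' subcutaneous WAT.
#'
#' @param volume a [volume3d].
#' @param rois a [label_map] of regions.
#' @param labels optional subset of legend names to summarize; an unknown
#'   name is an error.
#' @return A data frame with columns `label`, `name`, `mean`, `max`,
#'   `voxel_count`.
#' @export
roi_summary <- function(volume, rois, labels = NULL) {
  stopifnot(inherits(volume, "volume3d"), inherits(rois, "label_map"))
  validate_geometry(list(volume, rois))
  if (is.null(labels)) labels <- unique(unname(rois$legend))
  unknown <- setdiff(labels, rois$legend)
  if (length(unknown))
    stop("definition error: label not in legend: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rows <- lapply(labels, function(nm) {
    lab_vals <- as.integer(names(rois$legend)[rois$legend == nm])
    sel <- rois$values %in% lab_vals
    n <- sum(sel)
    data.frame(label = paste(lab_vals, collapse = "+"), name = nm,
               mean = if (n) mean(volume$values[sel]) else NA_real_,
               max = if (n) max(volume$values[sel]) else NA_real_,
               voxel_count = as.integer(n), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full PET-MRI BAT quantification pipeline
#'
#' Deterministic composition of the semi-automated analysis:
#' fat fraction -> median filter -> adipose mask (FF >= 50%);
#' SUV_lean -> PET mask (>= 1.2 g/ml); mask intersection; brain/other
#' exclusions; depot tagging; (3,3,1) in-plane erosion; metrics reported
#' both pre- and post-erosion.
#'
#' @param fat,water Dixon fat and water [volume3d] (arbitrary MR units).
#' @param pet PET [volume3d]: either activity in kBq/ml (converted using
#'   `subject`) or a pre-computed SUV map in `SUV-g/ml` (then taken as the
#'   lean-scale map and used for both thresholding and reporting).
#' @param subject a [subject_scan].
#' @param depots depot-region [label_map]; see [tag_depots()].
#' @param exclusions optional [binary_mask] of voxels to remove (e.g.
#'   brain).
#' @param config a [bat_config()].
#' @return A list with elements `segmentation` (`bat_segmentation`),
#'   `metrics` (data frame from [compute_metrics()]), `ffm`, `adipose`,
#'   `pet_mask`, `suv_bw`, `suv_lean`, and `provenance` (all parameters
#'   used).
#' @export
run_mri_pipeline <- function(fat, water, pet, subject, depots,
                             exclusions = NULL, config = bat_config()) {
  config <- validate_config(config)
  vols <- list(fat, water, pet, depots)
  if (!is.null(exclusions)) vols <- c(vols, list(exclusions))
  validate_geometry(vols)

  if (pet$units == "kBq/ml") {
    suv_bw <- compute_suv_bw(pet, subject)
    suv_lean <- compute_suv_lean(pet, subject)
  } else if (pet$units == "SUV-g/ml") {
    suv_bw <- suv_lean <- pet
  } else stop("unit error: PET volume must be kBq/ml or SUV-g/ml",
              call. = FALSE)

  ffm <- compute_fat_fraction(fat, water)
  ffm <- median_filter_ffm(ffm, config$median_kernel)
  adipose <- adipose_mask(ffm, config$ff_threshold_pct)
  pet_mask <- pet_threshold_mask(suv_lean, config$suv_lean_threshold)
  candidates <- intersect_candidates(adipose, pet_mask)
  if (!is.null(exclusions))
    candidates <- apply_exclusions(candidates, exclusions)
  seg <- tag_depots(candidates, depots)
  if (config$apply_erosion)
    seg <- erode_segmentation(seg, config$erosion_footprint)
  suv_report <- if (config$suv_scale == "bw") suv_bw else suv_lean
  metrics <- compute_metrics(seg, suv_report, ffm)
  provenance <- c(unclass(config),
                  list(suv_input_units = pet$units,
                       lbm_kg = compute_lbm(subject),
                       lbm_formula = "Janmahasatian",
                       n_unassigned = sum(seg$unassigned$values)))
  seg$provenance <- utils::modifyList(seg$provenance, provenance)
  list(segmentation = seg, metrics = metrics, ffm = ffm, adipose = adipose,
       pet_mask = pet_mask, suv_bw = suv_bw, suv_lean = suv_lean,
       provenance = provenance)
}
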