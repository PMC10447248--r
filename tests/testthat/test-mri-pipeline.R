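sp <- c(2, 2, 2)
mk_mask <- function(vals) binary_mask(vals, sp)

test_that("PET thresholding keeps the BARCIST boundary inclusive", {
  suv <- volume3d(array(c(1.2, 1.1999, 0, 3), c(2, 2, 1)), sp, "SUV-g/ml")
  m <- pet_threshold_mask(suv, 1.2)
  expect_true(m$values[1, 1, 1])
  expect_false(m$values[2, 1, 1])
  expect_true(m$values[2, 2, 1])
  expect_error(pet_threshold_mask(suv, 0), "parameter error")
  expect_error(pet_threshold_mask(volume3d(array(1, c(2, 2, 1)), sp, "HU")),
               "unit error")

  # exhaustive voxel-scan oracle on a random map
  set.seed(21)
  vals <- array(runif(16^3, 0, 3), c(16, 16, 16))
  got <- pet_threshold_mask(volume3d(vals, sp, "SUV-g/ml"), 1.2)$values
  expect_identical(sum(got), sum(vals >= 1.2))
  expect_identical(got, array(vals >= 1.2, dim(vals)))
})

test_that("exclusion masks subtract and intersection is a logical AND", {
  set.seed(31)
  a <- mk_mask(random_mask(c(10, 10, 5)))
  b <- mk_mask(random_mask(c(10, 10, 5)))
  empty <- mk_mask(array(FALSE, c(10, 10, 5)))

  expect_identical(apply_exclusions(a, empty)$values, a$values)
  expect_identical(sum(apply_exclusions(a, a)$values), 0L)
  expect_identical(intersect_candidates(a, empty)$values, empty$values)
  expect_identical(intersect_candidates(a, a)$values, a$values)
  expect_identical(intersect_candidates(a, b)$values, a$values & b$values)
  expect_error(intersect_candidates(a, mk_mask(random_mask(c(10, 10, 6)))),
               "geometry error")
})

test_that("erosion matches Minkowski geometry and the brute-force oracle", {
  pt <- array(FALSE, c(5, 5, 3)); pt[3, 3, 2] <- TRUE
  expect_identical(sum(erode_mask(mk_mask(pt), c(3, 3, 1))$values), 0L)

  sq <- array(FALSE, c(7, 7, 3)); sq[2:6, 2:6, 2] <- TRUE
  er <- erode_mask(mk_mask(sq), c(3, 3, 1))$values
  expect_identical(sum(er), 9L)
  expect_true(all(er[3:5, 3:5, 2]))

  set.seed(17)
  for (fp in list(c(3L, 3L, 1L), c(3L, 3L, 3L), c(5L, 3L, 1L))) {
    v <- random_mask(c(10, 10, 5), p = 0.7)
    expect_identical(erode_mask(mk_mask(v), fp)$values, brute_erode(v, fp))
  }
})

test_that("erosion shrinks monotonically", {
  set.seed(23)
  v <- random_mask(c(12, 12, 6), p = 0.8)
  e1 <- erode_mask(mk_mask(v), c(3, 3, 1))
  e2 <- erode_mask(e1, c(3, 3, 1))
  expect_true(all(v[e1$values]))         # erosion subset of input
  expect_true(all(e1$values[e2$values])) # double subset of single
})

test_that("depot tagging partitions candidates without losing voxels", {
  d <- c(16, 16, 8)
  regions <- tiny_depot_regions(sp)
  set.seed(41)
  cand <- binary_mask(random_mask(d, 0.3), sp)
  seg <- tag_depots(cand, regions)
  n_groups <- sum(vapply(seg$groups, function(g) sum(g$pre$values),
                         integer(1)))
  expect_identical(n_groups + sum(seg$unassigned$values),
                   sum(cand$values))
  # group masks are disjoint subsets of the candidates
  overlap <- seg$groups$supraclavicular$pre$values &
    seg$groups$paraspinal$pre$values
  expect_false(any(overlap))
  expect_true(all(cand$values[seg$groups$supraclavicular$pre$values]))

  # all candidates inside one region
  inside <- array(FALSE, d); inside[2:5, 2:5, 2:5] <- TRUE
  seg2 <- tag_depots(binary_mask(inside, sp), regions)
  expect_identical(seg2$groups$supraclavicular$pre$values, inside)
  expect_identical(sum(seg2$groups$paraspinal$pre$values), 0L)
})

test_that("metrics follow count x voxel-volume and mean-SUV arithmetic", {
  d <- c(10, 10, 4)
  vals <- array(FALSE, d); vals[1:10, 1:10, 1] <- TRUE  # 100 voxels
  regions <- label_map(array(1L, d), c("1" = "supraclavicular"), sp)
  seg <- tag_depots(binary_mask(vals, sp), regions)
  suv <- volume3d(array(3, d), sp, "SUV-g/ml")
  fat <- volume3d(array(60, d), sp, "arbitrary-MR")
  water <- volume3d(array(40, d), sp, "arbitrary-MR")
  ffm <- compute_fat_fraction(fat, water)
  m <- compute_metrics(seg, suv, ffm)
  row <- m[m$group == "supraclavicular" & !m$eroded, ]
  expect_equal(row$volume_ml, 100 * 8 / 1000)  # 0.8 ml at 2x2x2 mm
  expect_equal(row$suv_mean, 3)
  expect_equal(row$total_uptake, 2.4)
  expect_equal(row$fat_fraction_pct, 60)
  expect_equal(row$total_uptake, row$suv_mean * row$volume_ml)

  # empty group: volume 0 and undefined (not zero) SUV_mean
  none <- tag_depots(binary_mask(array(FALSE, d), sp), regions)
  m0 <- compute_metrics(none, suv, ffm)
  expect_equal(m0$volume_ml, c(0, 0))
  expect_true(all(is.na(m0$suv_mean)))
})

test_that("ROI summaries match per-label brute-force aggregation", {
  d <- c(8, 8, 4)
  set.seed(51)
  vol <- volume3d(array(runif(prod(d), 0, 5), d), sp, "SUV-g/ml")
  labs <- array(sample(0:3, prod(d), replace = TRUE), d)
  rois <- label_map(labs, c("1" = "pectoralis", "2" = "psoas",
                            "3" = "trapezius"), sp)
  out <- roi_summary(vol, rois)
  for (lab in 1:3) {
    want <- brute_roi_summary(vol$values, labs, lab)
    row <- out[out$label == lab, ]
    expect_equal(row$mean, want$mean)
    expect_equal(row$max, want$max)
    expect_identical(row$voxel_count, as.integer(want$n))
  }
  # uniform volume: mean = max everywhere
  u <- volume3d(array(2.5, d), sp, "SUV-g/ml")
  outu <- roi_summary(u, rois)
  expect_equal(outu$mean, outu$max)
  expect_error(roi_summary(vol, rois, labels = "deltoid"),
               "definition error")
})

test_that("full MRI pipeline recovers phantom truth at zero noise", {
  bundle <- generate_phantom(tiny_phantom_spec(seed = 3))
  res <- run_mri_pipeline(bundle$fat, bundle$water, bundle$pet,
                          bundle$subject, tiny_depot_regions(c(3, 3, 3)),
                          exclusions = bundle$brain_mask)
  rec <- evaluate_recovery(bundle$truth, res$segmentation)
  expect_equal(rec$dice, c(1, 1))
  expect_equal(rec$volume_error_pct, c(0, 0))
  m <- res$metrics
  # targets are programmed on the lean scale; on the default body-weight
  # reporting scale SUV_mean comes out scaled by weight / LBM
  w_over_lbm <- bundle$subject$weight / compute_lbm(bundle$subject)
  pre <- m[m$group == "combined" & !m$eroded, ]
  expect_equal(pre$suv_mean, 4 * w_over_lbm)
  expect_equal(pre$fat_fraction_pct, 70)
  post <- m[m$group == "combined" & m$eroded, ]
  expect_lte(post$voxel_count, pre$voxel_count)
  expect_equal(post$suv_mean, pre$suv_mean)  # uniform depot SUV
  # post-erosion masks nest inside pre-erosion masks
  for (g in res$segmentation$groups)
    expect_true(all(g$pre$values[g$post$values]))
  # lean-scale reporting recovers the programmed target directly
  res_lean <- run_mri_pipeline(bundle$fat, bundle$water, bundle$pet,
                               bundle$subject, tiny_depot_regions(c(3, 3, 3)),
                               config = bat_config(suv_scale = "lean"))
  expect_equal(res_lean$metrics$suv_mean[1], 4)
})

test_that("pipeline stages only ever remove voxels and runs are deterministic", {
  bundle <- generate_phantom(tiny_phantom_spec(seed = 4))
  regions <- tiny_depot_regions(c(3, 3, 3))
  res1 <- run_mri_pipeline(bundle$fat, bundle$water, bundle$pet,
                           bundle$subject, regions)
  res2 <- run_mri_pipeline(bundle$fat, bundle$water, bundle$pet,
                           bundle$subject, regions)
  expect_identical(res1$metrics, res2$metrics)

  cand <- sum(vapply(res1$segmentation$groups,
                     function(g) sum(g$pre$values), integer(1))) +
    sum(res1$segmentation$unassigned$values)
  expect_lte(cand, sum(res1$adipose$values))
  expect_lte(cand, sum(res1$pet_mask$values))

  # BAT programmed below the SUV_lean threshold yields an empty result
  cold <- generate_phantom(tiny_phantom_spec(seed = 4, bat_suv = 1.0))
  res0 <- run_mri_pipeline(cold$fat, cold$water, cold$pet, cold$subject,
                           regions)
  expect_true(all(res0$metrics$volume_ml == 0))
  expect_true(all(is.na(res0$metrics$suv_mean)))
})

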