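test_that("EE trace averaging discards the first 5 minutes", {
  t <- seq(0.5, 15, by = 0.5)
  expect_equal(ee_from_trace(t, rep(1500, length(t))), 1500)

  ee <- ifelse(t <= 5, 9999, 1500)
  expect_equal(ee_from_trace(t, ee), 1500)

  # brute-force windowed mean on a random trace
  set.seed(71)
  ee <- runif(length(t), 1200, 2000)
  manual <- mean(ee[t > 5 & t <= 15])
  expect_equal(ee_from_trace(t, ee), manual)

  expect_error(ee_from_trace(seq(0.5, 10, 0.5), rep(1500, 20)), "data error")
})

test_that("condition EE is the mean of per-trace values", {
  t <- seq(1, 15)
  mk <- function(id, val, cond)
    data.frame(trace_id = id, time_min = t, ee_kcal_day = val,
               condition = cond)
  traces <- rbind(mk("a", 1400, "warm"), mk("b", 1554, "warm"),
                  mk("c", 1600, "cold"))
  expect_equal(condition_ee(traces, "warm"), 1477)
  expect_equal(condition_ee(traces, "cold"), 1600)
  three <- rbind(traces, mk("d", 1700, "cold"), mk("e", 1500, "cold"))
  expect_equal(condition_ee(three, "cold"), 1600)
  expect_error(condition_ee(traces, "hot"), "data error")
})

test_that("CIT is cold minus warm and antisymmetric", {
  expect_equal(compute_cit(1477, 1635), 158)
  expect_equal(compute_cit(1500, 1500), 0)
  expect_equal(compute_cit(1897, 1984), 87)
  set.seed(72)
  for (i in 1:10) {
    w <- runif(1, 1200, 2200); k <- runif(1, 1200, 2200)
    expect_equal(compute_cit(w, k), -compute_cit(k, w))
  }
})

test_that("thermal summaries average laterally then across images", {
  obs <- data.frame(
    image_id = c(1, 1, 1),
    condition = "warm",
    roi = c("scv_left", "scv_right", "sternal"),
    t_mean = c(35.0, 35.8, 34.0),
    t_max = c(35.5, 36.2, 34.5))
  s <- thermal_condition_summary(obs, "warm")
  expect_equal(s$scv_mean, 35.4)
  expect_equal(s$sternal_mean, 34.0)

  obs2 <- rbind(obs, within(obs, {
    image_id <- 2
    t_mean <- c(35.1, 35.3, 33.8)  # SCV mean 35.2
  }))
  obs2$t_mean[4:6] <- c(35.1, 35.3, 33.8)
  s2 <- thermal_condition_summary(obs2, "warm")
  expect_equal(s2$scv_mean, mean(c(35.4, 35.2)))
  expect_equal(s2$n_images, 2)

  # brute-force double mean on random observation sets
  set.seed(73)
  imgs <- lapply(1:6, function(i)
    data.frame(image_id = i, condition = "cold",
               roi = c("scv_left", "scv_right", "sternal"),
               t_mean = runif(3, 30, 36), t_max = runif(3, 31, 37)))
  all_obs <- do.call(rbind, imgs)
  want <- mean(vapply(imgs, function(im) mean(im$t_mean[1:2]), numeric(1)))
  expect_equal(thermal_condition_summary(all_obs, "cold")$scv_mean, want)

  expect_error(thermal_condition_summary(obs, "cold"), "data error")
  bad <- obs; bad$t_mean[1] <- 60
  expect_error(thermal_condition_summary(bad, "warm"), "data error")
})

test_that("temperature changes and differentials reproduce printed rows", {
  expect_equal(cold_induced_change(35.4, 34.4), -1.0)
  expect_equal(cold_induced_change(33.6, 31.0), -2.6)
  expect_equal(cold_induced_change(34, 34), 0)
  expect_equal(temperature_differential(34.4, 32.7), 1.7)
  expect_equal(temperature_differential(35.4, 34.3), 1.1)
  expect_equal(temperature_differential(33, 33), 0)
})

ocr_trace <- function(basal = c(10, 10, 10), na = rep(14, 6),
                      olig = c(6, 6, 6), fccp = 20, rot = c(2, 2, 2)) {
  phases <- c(rep("basal", length(basal)), rep("noradrenaline", length(na)),
              rep("oligomycin", length(olig)), rep("fccp", length(fccp)),
              rep("rotenone", length(rot)))
  data.frame(cycle = seq_along(phases), ocr = c(basal, na, olig, fccp, rot),
             phase = phases)
}

test_that("OCR metrics subtract non-mitochondrial respiration as specified", {
  m <- ocr_metrics(ocr_trace())
  expect_equal(m$non_mito, 2)
  expect_equal(m$basal, 8)
  expect_equal(m$na_stimulated, 12)
  expect_equal(m$uncoupled, 4)
  expect_equal(m$maximal, 18)

  # programmed plateau values are recovered minus non-mito
  m2 <- ocr_metrics(ocr_trace(basal = c(9, 10, 11), na = c(11:15, 30),
                              olig = c(5, 6, 7, 99), fccp = c(25, 1),
                              rot = c(1, 3)))
  expect_equal(m2$non_mito, 2)
  expect_equal(m2$basal, 10 - 2)
  expect_equal(m2$na_stimulated, 30 - 2)   # sixth post-NA cycle
  expect_equal(m2$uncoupled, 6 - 2)        # first three post-oligomycin
  expect_equal(m2$maximal, 25 - 2)         # first post-FCCP

  # all-equal trace collapses to zero after subtraction
  flat <- ocr_metrics(ocr_trace(basal = c(5, 5, 5), na = rep(5, 6),
                                olig = c(5, 5, 5), fccp = 5, rot = c(5, 5)))
  expect_equal(unlist(flat[-1]), c(basal = 0, na_stimulated = 0,
                                   uncoupled = 0, maximal = 0))
})

test_that("OCR metrics are invariant to a constant offset", {
  set.seed(74)
  tr <- ocr_trace(basal = runif(4, 8, 12), na = runif(6, 10, 16),
                  olig = runif(3, 4, 7), fccp = runif(1, 18, 22),
                  rot = runif(3, 1, 3))
  m <- ocr_metrics(tr)
  tr2 <- tr; tr2$ocr <- tr2$ocr + 7.3
  m2 <- ocr_metrics(tr2)
  for (k in c("basal", "na_stimulated", "uncoupled", "maximal"))
    expect_equal(m2[[k]], m[[k]])
})

test_that("OCR contract errors fire on malformed traces", {
  expect_error(ocr_metrics(ocr_trace(na = rep(14, 5))), "data error")
  tr <- ocr_trace()
  expect_error(ocr_metrics(tr[tr$phase != "fccp", ]), "missing phase")
  shuffled <- ocr_trace()
  shuffled$phase[2] <- "oligomycin"
  expect_error(ocr_metrics(shuffled), "out of order")
})

test_that("percent-of-basal scaling behaves", {
  m <- ocr_metrics(ocr_trace())
  p <- ocr_percent_basal(m, basal_vehicle = m$basal)
  expect_equal(p$basal, 100)
  expect_equal(p$uncoupled, 100 * m$uncoupled / m$basal)
  expect_equal(ocr_percent_basal(list(x = 0), 8)$x, 0)
  expect_error(ocr_percent_basal(m, 0), "data error")
})

test_that("derived rows from printed group means match the published table", {
  means <- data.frame(group = c("normal", "obese"),
                      ee_warm = c(1477, 1897), ee_cold = c(1635, 1984),
                      scv_warm = c(35.4, 34.7), scv_cold = c(34.4, 33.4),
                      sternal_warm = c(34.3, 33.6),
                      sternal_cold = c(32.7, 31.0))
  out <- derive_physiology_rows(means)
  nw <- out[out$group == "normal", ]
  ob <- out[out$group == "obese", ]
  expect_equal(nw$cit, 158)
  expect_equal(nw$scv_change, -1.0)
  expect_equal(ob$sternal_change, -2.6)
  expect_equal(nw$differential_warm, 1.1)
  expect_equal(nw$differential_cold, 1.7)
  # published rounding exceptions: group-mean arithmetic gives 87 (obese
  # CIT, printed 86) and -1.6 (normal-weight sternal change, printed -1.7)
  expect_equal(ob$cit, 87)
  expect_equal(nw$sternal_change, -1.6)
})
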