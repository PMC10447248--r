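# Indirect-calorimetry, thermal-imaging and extracellular-flux (OCR)
# metric computations. Inputs are plain data frames mirroring the CSV
# layouts documented per function.

#' Energy expenditure from a single ventilated-hood trace
#'
#' A measurement lasts 15 min: the first 5 min are discarded as
#' equilibration and the mean over the final 10 min is recorded.
#'
#' @param time_min sample times from the start of the measurement, min.
#' @param ee_kcal_day energy-expenditure samples, kcal/day.
#' @return Mean EE over the (5, 15] min window, kcal/day.
#' @export
ee_from_trace <- function(time_min, ee_kcal_day) {
  stopifnot(length(time_min) == length(ee_kcal_day))
  if (max(time_min) < 15)
    stop("data error: EE trace must span at least 15 min", call. = FALSE)
  keep <- time_min > 5 & time_min <= 15
  if (!any(keep))
    stop("data error: no samples in the 5-15 min window", call. = FALSE)
  mean(ee_kcal_day[keep])
}

#' Condition-level energy expenditure
#'
#' EE per condition is the mean of the per-trace values obtained under
#' that condition (two measurements per condition in the study design;
#' any number >= 1 is accepted).
#'
#' @param traces data frame with columns `time_min`, `ee_kcal_day`,
#'   `condition` (`"warm"`/`"cold"`) and a trace identifier `trace_id`.
#' @param condition which condition to summarize.
#' @return Mean EE, kcal/day.
#' @export
condition_ee <- function(traces, condition) {
  sel <- traces[traces$condition == condition, , drop = FALSE]
  if (!nrow(sel))
    stop("data error: no traces for condition ", condition, call. = FALSE)
  per_trace <- vapply(split(sel, sel$trace_id),
                      function(tr) ee_from_trace(tr$time_min, tr$ee_kcal_day),
                      numeric(1))
  mean(per_trace)
}

#' Cold-induced thermogenesis
#'
#' CIT is the mean EE measured in the cold room minus the mean EE in the
#' warm room; it may be negative.
#'
#' @param ee_warm,ee_cold condition-level EE, kcal/day.
#' @return CIT, kcal/day.
#' @examples
#' compute_cit(1477, 1635)  # 158
#' @export
compute_cit <- function(ee_warm, ee_cold) ee_cold - ee_warm

#' Thermal-imaging condition summary
#'
#' Per image, the supraclavicular (SCV) temperature is the unweighted mean
#' of the left and right ROI means; the condition-level value is the mean
#' over images of those per-image means ("mean of means"). Sternal values
#' aggregate the same way. ROI maxima are summarized alongside but are not
#' part of the headline SCV/sternal means.
#'
#' @param observations data frame with columns `image_id`, `condition`,
#'   `roi` (`"scv_left"`, `"scv_right"`, `"sternal"`), `t_mean`, `t_max`
#'   in degrees Celsius.
#' @param condition which condition to summarize.
#' @return One-row data frame: `condition`, `n_images`, `scv_mean`,
#'   `sternal_mean`, `scv_left_mean`, `scv_right_mean`, `scv_max`,
#'   `sternal_max`.
#' @export
thermal_condition_summary <- function(observations, condition) {
  obs <- observations[observations$condition == condition, , drop = FALSE]
  if (!nrow(obs))
    stop("data error: no thermal observations for condition ", condition,
         call. = FALSE)
  if (any(obs$t_mean <= -10 | obs$t_mean >= 45))
    stop("data error: implausible skin temperature outside (-10, 45) C",
         call. = FALSE)
  per_image <- lapply(split(obs, obs$image_id), function(im) {
    roi_val <- function(r, col) {
      v <- im[[col]][im$roi == r]
      if (!length(v)) NA_real_ else mean(v)
    }
    scv_sides <- c(roi_val("scv_left", "t_mean"), roi_val("scv_right", "t_mean"))
    if (all(is.na(scv_sides)))
      stop("data error: image ", im$image_id[1], " has no SCV ROI",
           call. = FALSE)
    data.frame(scv = mean(scv_sides, na.rm = TRUE),
               sternal = roi_val("sternal", "t_mean"),
               scv_left = scv_sides[1], scv_right = scv_sides[2],
               scv_max = mean(c(roi_val("scv_left", "t_max"),
                                roi_val("scv_right", "t_max")), na.rm = TRUE),
               sternal_max = roi_val("sternal", "t_max"))
  })
  per_image <- do.call(rbind, per_image)
  data.frame(condition = condition, n_images = nrow(per_image),
             scv_mean = mean(per_image$scv),
             sternal_mean = mean(per_image$sternal, na.rm = TRUE),
             scv_left_mean = mean(per_image$scv_left, na.rm = TRUE),
             scv_right_mean = mean(per_image$scv_right, na.rm = TRUE),
             scv_max = mean(per_image$scv_max, na.rm = TRUE),
             sternal_max = mean(per_image$sternal_max, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Cold-induced change in a temperature
#' @param warm,cold condition-level temperatures, degrees C.
#' @return `cold - warm`, degrees C (negative when skin cools).
#' @examples
#' cold_induced_change(35.4, 34.4)  # -1.0
#' @export
cold_induced_change <- function(warm, cold) cold - warm

#' Supraclavicular-sternal temperature differential
#' @param scv,sternal condition-level temperatures, degrees C.
#' @return `scv - sternal`, degrees C.
#' @examples
#' temperature_differential(34.4, 32.7)  # 1.7
#' @export
temperature_differential <- function(scv, sternal) scv - sternal

OCR_PHASES <- c("basal", "noradrenaline", "oligomycin", "fccp", "rotenone")

#' Respirometry metrics from an extracellular-flux (Seahorse) trace
#'
#' The trace is a sequence of measurement cycles labeled by injection
#' phase, in the fixed order basal -> noradrenaline -> oligomycin -> FCCP
#' -> rotenone/antimycin A. Non-mitochondrial respiration is the mean OCR
#' of the cycles after rotenone/antimycin and is subtracted from every
#' other metric:
#' basal = mean of the last `basal_cycles` pre-noradrenaline cycles;
#' noradrenaline-stimulated = the 6th post-noradrenaline cycle;
#' uncoupled = mean of the first 3 post-oligomycin cycles;
#' maximal = the first post-FCCP cycle.
#'
#' @param trace data frame with columns `cycle` (ordered index), `ocr`
#'   (pmol O2/min) and `phase`, one of `"basal"`, `"noradrenaline"`,
#'   `"oligomycin"`, `"fccp"`, `"rotenone"`.
#' @param basal_cycles how many pre-injection cycles enter the basal mean
#'   (default 3, the last three before noradrenaline).
#' @param stimulated_cycle which post-noradrenaline cycle is reported
#'   (default 6).
#' @return Named list: `non_mito`, `basal`, `na_stimulated`, `uncoupled`,
#'   `maximal` (all but `non_mito` are non-mitochondrial-subtracted).
#' @export
ocr_metrics <- function(trace, basal_cycles = 3L, stimulated_cycle = 6L) {
  stopifnot(all(c("cycle", "ocr", "phase") %in% names(trace)))
  trace <- trace[order(trace$cycle), , drop = FALSE]
  bad <- setdiff(unique(trace$phase), OCR_PHASES)
  if (length(bad))
    stop("data error: unknown phase label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  idx <- match(trace$phase, OCR_PHASES)
  if (is.unsorted(idx))
    stop("data error: injection phases out of order", call. = FALSE)
  miss <- setdiff(OCR_PHASES, trace$phase)
  if (length(miss))
    stop("data error: missing phase: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ocr_in <- function(ph) trace$ocr[trace$phase == ph]
  basal_all <- ocr_in("basal")
  if (length(basal_all) < basal_cycles)
    stop("data error: need >= ", basal_cycles, " pre-injection cycles",
         call. = FALSE)
  na_all <- ocr_in("noradrenaline")
  if (length(na_all) < stimulated_cycle)
    stop("data error: need >= ", stimulated_cycle,
         " cycles after noradrenaline", call. = FALSE)
  olig <- ocr_in("oligomycin")
  if (length(olig) < 3)
    stop("data error: need >= 3 cycles after oligomycin", call. = FALSE)
  non_mito <- mean(ocr_in("rotenone"))
  list(
    non_mito = non_mito,
    basal = mean(utils::tail(basal_all, basal_cycles)) - non_mito,
    na_stimulated = na_all[stimulated_cycle] - non_mito,
    uncoupled = mean(olig[1:3]) - non_mito,
    maximal = ocr_in("fccp")[1] - non_mito
  )
}

#' Express OCR metrics as percent of vehicle basal respiration
#' @param metrics list from [ocr_metrics()] (or any named numeric list).
#' @param basal_vehicle basal OCR of the vehicle condition (> 0).
#' @return The metrics scaled to percent of `basal_vehicle`.
#' @export
ocr_percent_basal <- function(metrics, basal_vehicle) {
  if (!is.numeric(basal_vehicle) || basal_vehicle <= 0)
    stop("data error: vehicle basal OCR must be > 0", call. = FALSE)
  lapply(metrics, function(m) 100 * m / basal_vehicle)
}

#' Derived physiology rows from condition-level group means
#'
#' Convenience wrapper applying [compute_cit()], [cold_induced_change()]
#' and [temperature_differential()] to a table of condition means, as used
#' for group-level summaries (EE in warm/cold, SCV and sternal skin
#' temperatures in warm/cold).
#'
#' @param means data frame with columns `group`, `ee_warm`, `ee_cold`,
#'   `scv_warm`, `scv_cold`, `sternal_warm`, `sternal_cold`.
#' @return Data frame adding `cit`, `scv_change`, `sternal_change`,
#'   `differential_warm`, `differential_cold`, `differential_change`.
#' @export
derive_physiology_rows <- function(means) {
  within(means, {
    cit <- compute_cit(ee_warm, ee_cold)
    scv_change <- cold_induced_change(scv_warm, scv_cold)
    sternal_change <- cold_induced_change(sternal_warm, sternal_cold)
    differential_warm <- temperature_differential(scv_warm, sternal_warm)
    differential_cold <- temperature_differential(scv_cold, sternal_cold)
    differential_change <- differential_cold - differential_warm
  })
}
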