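#' Per-subject scan metadata
#'
#' Scalars needed for SUV normalization of a PET activity map: body weight,
#' height, sex and injected tracer dose. No radioactive-decay correction is
#' applied to the dose; acquisitions are assumed to follow a fixed uptake
#' protocol (here, 60 min post injection).
#'
#' @param weight body weight, kg (> 0).
#' @param height height, m (> 0).
#' @param sex `"male"` or `"female"`.
#' @param injected_dose injected 18F-FDG dose, MBq (> 0).
#' @return An object of class `subject_scan`.
#' @examples
#' s <- subject_scan(weight = 65, height = 1.70, sex = "female",
#'                   injected_dose = 75)
#' compute_lbm(s)
#' @export
subject_scan <- function(weight, height, sex, injected_dose) {
  if (!is.numeric(weight) || weight <= 0) stop("weight must be > 0 kg", call. = FALSE)
  if (!is.numeric(height) || height <= 0) stop("height must be > 0 m", call. = FALSE)
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(injected_dose) || injected_dose <= 0)
    stop("injected dose must be > 0 MBq", call. = FALSE)
  bmi <- weight / height^2
  if (bmi <= 10 || bmi >= 80)
    stop(sprintf("implausible BMI %.1f kg/m^2 from weight/height", bmi),
         call. = FALSE)
  structure(list(weight = weight, height = height, sex = sex,
                 injected_dose = injected_dose, bmi = bmi),
            class = "subject_scan")
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("<subject_scan> %s, %.1f kg, %.2f m (BMI %.1f), %.0f MBq\n",
              x$sex, x$weight, x$height, x$bmi, x$injected_dose))
  invisible(x)
}

#' Janmahasatian lean body mass
#'
#' LBM in kg from weight and BMI, as prescribed by the BARCIST consensus
#' for lean-mass SUV normalization:
#' male `9270 W / (6680 + 216 BMI)`, female `9270 W / (8780 + 244 BMI)`.
#'
#' @param subject a [subject_scan].
#' @return Lean body mass, kg.
#' @export
compute_lbm <- function(subject) {
  stopifnot(inherits(subject, "subject_scan"))
  if (subject$sex == "male") {
    9270 * subject$weight / (6680 + 216 * subject$bmi)
  } else {
    9270 * subject$weight / (8780 + 244 * subject$bmi)
  }
}

suv_from_activity <- function(pet, subject, mass_kg) {
  stopifnot(inherits(subject, "subject_scan"))
  if (!inherits(pet, "volume3d") || pet$units != "kBq/ml")
    stop("unit error: PET volume must carry units kBq/ml", call. = FALSE)
  dose_kbq <- subject$injected_dose * 1000   # MBq -> kBq
  mass_g   <- mass_kg * 1000                 # kg  -> g
  volume3d(pet$values / (dose_kbq / mass_g), pet$spacing, "SUV-g/ml")
}

#' Body-weight standardized uptake value
#'
#' `SUV_bw = activity / (injected dose / body weight)` with the dose in kBq
#' and the weight in grams, giving SUV in g/ml.
#'
#' @param pet PET activity-concentration [volume3d] in kBq/ml.
#' @param subject a [subject_scan].
#' @return A [volume3d] with units `SUV-g/ml`.
#' @export
compute_suv_bw <- function(pet, subject)
  suv_from_activity(pet, subject, subject$weight)

#' Lean-body-mass standardized uptake value
#'
#' As [compute_suv_bw()] but normalized to Janmahasatian lean body mass
#' ([compute_lbm()]); the scale on which the BARCIST BAT threshold
#' (SUV_lean >= 1.2 g/ml) is defined.
#'
#' @inheritParams compute_suv_bw
#' @return A [volume3d] with units `SUV-g/ml`.
#' @export
compute_suv_lean <- function(pet, subject)
  suv_from_activity(pet, subject, compute_lbm(subject))
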