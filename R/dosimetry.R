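#' Beam-delivery arithmetic
#'
#' Accounting of how much sub-terahertz radiation actually reaches and is
#' deposited in the sample: reflective loss at the entrance window,
#' Beer-Lambert absorption over the liquid path, and the time-integrated
#' dose. The absorption coefficient is a user input (the often-quoted
#' 83 cm^-1 is for H2O at 25 degC and 0.1 THz; D2O differs).
#'
#' @param reflection_loss Fraction of incident power lost to reflection, in
#'   `[0, 1)`.
#' @param alpha Absorption coefficient (cm^-1), >= 0.
#' @param pathlength_cm Sample path length (cm), >= 0.
#' @param power_density Power density at the sample surface (mW/cm^2).
#' @param duration_min Exposure duration (minutes).
#' @return `transmitted_fraction()` and `absorbed_fraction()` return
#'   fractions in `[0, 1]`; `delivered_dose()` returns J/cm^2.
#' @examples
#' transmitted_fraction(0.40) # 0.60
#' absorbed_fraction(83, 0.039) # ~0.96
#' delivered_dose(90, 12) # 64.8 J/cm^2
#' @name dosimetry
NULL

#' @rdname dosimetry
#' @export
transmitted_fraction <- function(reflection_loss) {
  if (any(reflection_loss < 0 | reflection_loss >= 1)) {
    stop("`reflection_loss` must be in [0, 1)", call. = FALSE)
  }
  1 - reflection_loss
}

#' @rdname dosimetry
#' @export
absorbed_fraction <- function(alpha, pathlength_cm) {
  if (any(alpha < 0) || any(pathlength_cm < 0)) {
    stop("`alpha` and `pathlength_cm` must be non-negative", call. = FALSE)
  }
  1 - exp(-alpha * pathlength_cm)
}

#' @rdname dosimetry
#' @export
delivered_dose <- function(power_density, duration_min) {
  if (any(power_density < 0) || any(duration_min < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  (power_density / 1000) * (duration_min * 60)
}

#' Summarise beam delivery for a set of exposures
#'
#' @param power_density Incident power density (mW/cm^2) per exposure.
#' @param duration_min Exposure durations (minutes).
#' @inheritParams dosimetry
#' @return Tibble with the transmitted and absorbed fractions and the
#'   surface and absorbed dose (J/cm^2) per exposure.
#' @export
beam_summary <- function(power_density, duration_min, reflection_loss = 0.40,
                         alpha = 83, pathlength_cm = 0.039) {
  tf <- transmitted_fraction(reflection_loss)
  af <- absorbed_fraction(alpha, pathlength_cm)
  tibble::tibble(
    power_density = power_density,
    duration_min = duration_min,
    transmitted_fraction = tf,
    absorbed_fraction = af,
    surface_dose_j_cm2 = delivered_dose(power_density, duration_min),
    absorbed_dose_j_cm2 =
      delivered_dose(power_density, duration_min) * af
  )
}
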