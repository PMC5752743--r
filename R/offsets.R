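#' Published maturity-offset equation coefficients
#'
#' The coefficients of the five maturity-offset prediction equations, stored
#' to full printed precision. Moore-1 is the recommended pair (boys: age x
#' sitting height; girls: age x stature), Moore-2 the alternative boys'
#' equation (age x stature), and Mirwald the original sex-specific
#' equations using leg length, sitting height, age, mass and the
#' mass-by-stature ratio (mass kg / stature cm x 100).
#'
#' @format A named list, one element per `equation_id` in
#'   `moore1_boys`, `moore2_boys`, `moore1_girls`, `mirwald_boys`,
#'   `mirwald_girls`.
#' @export
offset_coefficients <- list(
  moore1_girls = c(intercept = -7.709133, age_stature = 0.0042232),
  moore1_boys  = c(intercept = -8.128741, age_sitting_height = 0.0070346),
  moore2_boys  = c(intercept = -7.999994, age_stature = 0.0036124),
  mirwald_boys = c(intercept = -9.236,
                   leg_sitting = 0.0002708,
                   age_leg = -0.001663,
                   age_sitting = 0.007216,
                   mass_stature_ratio = 0.02292),
  mirwald_girls = c(intercept = -9.376,
                    leg_sitting = 0.0001882,
                    age_leg = 0.0022,
                    age_sitting = 0.005841,
                    age_mass = -0.002658,
                    mass_stature_ratio = 0.07693)
)

#' Applicable equations per sex
#' @param sex "M" or "F".
#' @return Character vector of equation ids.
#' @export
equations_for_sex <- function(sex) {
  switch(sex,
         M = c("moore1_boys", "moore2_boys", "mirwald_boys"),
         F = c("moore1_girls", "mirwald_girls"),
         abort(paste0("unknown sex: ", sex), class = "phvalid_input_error"))
}

# calibration range of the source equations; outside it predictions are
# still returned, flagged, because evaluating that extrapolation is the
# whole point of the validation
age_range_flag <- function(age) age < 8 | age > 18

check_anthro <- function(age, stature = NULL, sitting_height = NULL,
                         mass = NULL) {
  if (!is.null(stature) && !is.null(sitting_height) &&
      any(sitting_height >= stature | sitting_height <= 0)) {
    abort("need 0 < sitting_height < stature",
          class = "phvalid_input_error")
  }
  if (!is.null(mass) && any(mass <= 0)) {
    abort("mass must be positive", class = "phvalid_input_error")
  }
  if (any(age_range_flag(age))) {
    warn("age outside the equations' calibration range [8, 18]; prediction returned anyway",
         class = "phvalid_age_range_warning")
  }
  invisible(TRUE)
}

#' Moore-1 maturity offset, girls
#'
#' `offset = -7.709133 + 0.0042232 * (age * stature)`, years.
#'
#' @param age Chronological age, years.
#' @param stature Stature, cm.
#' @return Maturity offset in years (negative before PHV). Vectorised.
#' @export
moore1_girls <- function(age, stature) {
  check_anthro(age)
  b <- offset_coefficients$moore1_girls
  b[["intercept"]] + b[["age_stature"]] * (age * stature)
}

#' Moore-1 maturity offset, boys
#'
#' `offset = -8.128741 + 0.0070346 * (age * sitting_height)`, years.
#'
#' @param age Chronological age, years.
#' @param sitting_height Sitting height, cm.
#' @return Maturity offset in years. Vectorised.
#' @export
moore1_boys <- function(age, sitting_height) {
  check_anthro(age)
  b <- offset_coefficients$moore1_boys
  b[["intercept"]] + b[["age_sitting_height"]] * (age * sitting_height)
}

#' Moore-2 maturity offset, boys (alternative equation)
#'
#' `offset = -7.999994 + 0.0036124 * (age * stature)`, years.
#'
#' @inheritParams moore1_girls
#' @return Maturity offset in years. Vectorised.
#' @export
moore2_boys <- function(age, stature) {
  check_anthro(age)
  b <- offset_coefficients$moore2_boys
  b[["intercept"]] + b[["age_stature"]] * (age * stature)
}

#' Mirwald maturity offset, boys
#'
#' The original four-term boys' equation on leg length x sitting height,
#' age x leg length, age x sitting height and the mass-by-stature ratio
#' (x 100). Leg length and the ratio are derived internally from the raw
#' inputs.
#'
#' @param age Chronological age, years.
#' @param stature Stature, cm.
#' @param sitting_height Sitting height, cm.
#' @param mass Body mass, kg.
#' @return Maturity offset in years. Vectorised.
#' @export
mirwald_boys <- function(age, stature, sitting_height, mass) {
  check_anthro(age, stature, sitting_height, mass)
  b <- offset_coefficients$mirwald_boys
  leg <- stature - sitting_height
  ratio <- mass / stature * 100
  b[["intercept"]] +
    b[["leg_sitting"]] * (leg * sitting_height) +
    b[["age_leg"]] * (age * leg) +
    b[["age_sitting"]] * (age * sitting_height) +
    b[["mass_stature_ratio"]] * ratio
}

#' Mirwald maturity offset, girls
#'
#' The original five-term girls' equation; adds an age x mass term to the
#' boys' structure.
#'
#' @inheritParams mirwald_boys
#' @return Maturity offset in years. Vectorised.
#' @export
mirwald_girls <- function(age, stature, sitting_height, mass) {
  check_anthro(age, stature, sitting_height, mass)
  b <- offset_coefficients$mirwald_girls
  leg <- stature - sitting_height
  ratio <- mass / stature * 100
  b[["intercept"]] +
    b[["leg_sitting"]] * (leg * sitting_height) +
    b[["age_leg"]] * (age * leg) +
    b[["age_sitting"]] * (age * sitting_height) +
    b[["age_mass"]] * (age * mass) +
    b[["mass_stature_ratio"]] * ratio
}

#' Predicted age at PHV from a maturity offset
#'
#' Predicted APHV is chronological age minus the maturity offset, exactly,
#' so `predicted_aphv(age, offset) + offset == age` always holds.
#'
#' @param age Chronological age at prediction, years.
#' @param offset Maturity offset, years.
#' @return Predicted age at PHV, years.
#' @export
predicted_aphv <- function(age, offset) age - offset

#' Leg length and leg-to-sitting-height ratio
#'
#' Leg (subischial) length is stature minus sitting height; the ratio is
#' reported in percent of sitting height.
#'
#' @param stature Stature, cm.
#' @param sitting_height Sitting height, cm; must be below stature.
#' @return A tibble with `leg_length` (cm) and `leg_sitting_ratio_pct`.
#' @export
derived_ratios <- function(stature, sitting_height) {
  if (any(sitting_height >= stature | sitting_height <= 0)) {
    abort("need 0 < sitting_height < stature",
          class = "phvalid_input_error")
  }
  leg <- stature - sitting_height
  tibble(leg_length = leg,
         leg_sitting_ratio_pct = 100 * leg / sitting_height)
}

apply_one_equation <- function(eq, age, stature, sitting_height, mass) {
  switch(eq,
         moore1_girls = moore1_girls(age, stature),
         moore1_boys = moore1_boys(age, sitting_height),
         moore2_boys = moore2_boys(age, stature),
         mirwald_boys = mirwald_boys(age, stature, sitting_height, mass),
         mirwald_girls = mirwald_girls(age, stature, sitting_height, mass),
         abort(paste0("unknown equation_id: ", eq),
               class = "phvalid_input_error"))
}

#' Apply all sex-appropriate offset equations to a visit table
#'
#' Evaluates every applicable prediction equation at every visit and
#' returns the table in long format, one row per visit x equation, with the
#' maturity offset, predicted APHV and an out-of-calibration-range flag
#' (predictions outside age 8-18 are kept, flagged, never refused).
#'
#' @param visits Data frame with `subject_id`, `sex` ("M"/"F"),
#'   `age_years`, `stature_cm`, `sitting_height_cm`, `mass_kg`.
#' @return A tibble: the input columns plus `equation`, `offset`,
#'   `predicted_aphv`, `age_out_of_range`.
#' @examples
#' v <- tibble::tibble(subject_id = "b1", sex = "M", age_years = 14,
#'   stature_cm = 160, sitting_height_cm = 82, mass_kg = 50)
#' add_offset_predictions(v)
#' @export
add_offset_predictions <- function(visits) {
  stopifnot(all(c("subject_id", "sex", "age_years", "stature_cm",
                  "sitting_height_cm", "mass_kg") %in% names(visits)))
  visits <- as_tibble(visits)
  out <- visits |>
    mutate(equation = purrr::map(.data$sex, equations_for_sex)) |>
    tidyr::unnest("equation")
  out$offset <- suppressWarnings(purrr::pmap_dbl(
    list(out$equation, out$age_years, out$stature_cm,
         out$sitting_height_cm, out$mass_kg),
    apply_one_equation))
  out |>
    mutate(predicted_aphv = predicted_aphv(.data$age_years, .data$offset),
           age_out_of_range = age_range_flag(.data$age_years))
}
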