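#' Canonical category levels for cohort tables
#'
#' The cohort format is one row per participant with a fixed set of
#' categorical risk-factor columns. This function returns the allowed levels
#' for each, in reference-first order (the reference level is the one that
#' carries weight zero in the traditional risk score and acts as baseline in
#' categorical model terms).
#'
#' @return Named list of character vectors, one per categorical column.
#' @export
#' @examples
#' cohort_levels()$hair_color
cohort_levels <- function() {
  list(
    sex = c("female", "male"),
    hair_color = c("dark", "light_brown", "fair_blonde", "red"),
    eye_color = c("brown_black", "green_hazel", "blue_grey"),
    skin_color = c("olive_dark", "medium", "fair"),
    freckling = c("none", "few", "some", "many"),
    photosensitivity = c("never_burn", "sometimes_burn", "usually_burn", "always_burn"),
    nevus_density = c("none", "few", "some", "many"),
    sunbed_use = c("none", "s1_10", "gt10"),
    blistering_sunburn_child = c("none", "one_plus"),
    vacation_sun_q = c("q1", "q2", "q3", "q4"),
    kc_history = c("no", "yes"),
    family_history = c("none", "one_plus"),
    ancestry = c("british", "north_european", "south_east_european", "mixed_european")
  )
}

# traditional risk-factor columns (excludes demographics / design factors)
traditional_factors <- function() {
  c("hair_color", "eye_color", "skin_color", "freckling", "photosensitivity",
    "nevus_density", "sunbed_use", "blistering_sunburn_child",
    "vacation_sun_q", "kc_history", "family_history")
}

# fixed cohort CSV column order (before the dose_* block)
cohort_base_columns <- function() {
  c("id", "status", "age", "sex", "center", "ancestry",
    "hair_color", "eye_color", "skin_color", "freckling",
    "photosensitivity", "nevus_density", "sunbed_use",
    "blistering_sunburn_child", "vacation_sun_q", "kc_history",
    "family_history")
}
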