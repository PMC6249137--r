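#' @importFrom rlang %||% .data abort warn enquo as_name
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows bind_cols pull count left_join across all_of row_number n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats glm binomial plogis qlogis rbinom rnorm runif quantile
#'   pchisq qnorm pnorm coef vcov logLik predict sd lm residuals
#'   model.matrix setNames
NULL

# column presence check with a module-labelled error
check_cols <- function(data, cols, where = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      where, paste(missing, collapse = ", ")
    ), class = "melrisk_missing_column")
  }
  invisible(data)
}

# half-up rounding for display percentages (base round() is half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# validate a categorical column against its allowed levels
check_levels <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "unrecognized %s level(s): %s (allowed: %s)",
      what, paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ), class = "melrisk_bad_level")
  }
  invisible(x)
}

dose_col <- function(snp_id) {
  if (length(snp_id) == 0) return(character(0))
  paste0("dose_", snp_id)
}
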