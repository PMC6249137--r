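#' Classify participants as sun-sensitive
#'
#' A participant has the sun-sensitive phenotype if they report any of:
#' freckles (few, some or many), red hair, or skin that usually or always
#' burns. This phenotype decides which stratified MC1R odds ratio applies in
#' [polygenic_score()].
#'
#' @param cohort A cohort tibble with `freckling`, `hair_color` and
#'   `photosensitivity` columns.
#' @return Logical vector, one element per row of `cohort`.
#' @export
#' @examples
#' ch <- tibble::tibble(
#'   freckling = c("none", "many"), hair_color = c("red", "dark"),
#'   photosensitivity = c("never_burn", "sometimes_burn")
#' )
#' sun_sensitive(ch)   # TRUE TRUE: red hair alone qualifies, so do freckles
sun_sensitive <- function(cohort) {
  check_cols(cohort, c("freckling", "hair_color", "photosensitivity"),
             where = "cohort")
  lv <- cohort_levels()
  check_levels(cohort$freckling, lv$freckling, "freckling")
  check_levels(cohort$hair_color, lv$hair_color, "hair_color")
  check_levels(cohort$photosensitivity, lv$photosensitivity, "photosensitivity")
  cohort$freckling %in% c("few", "some", "many") |
    cohort$hair_color == "red" |
    cohort$photosensitivity %in% c("usually_burn", "always_burn")
}

#' Compute a polygenic risk score from external weights
#'
#' The score for participant i is
#' \deqn{S_i = \sum_j (d_{ij} - c_j)\,\ln \mathrm{OR}_{ij}}
#' where \eqn{d_{ij}} is the effect-allele dosage, \eqn{c_j = 2\,\mathrm{eaf}_j}
#' when `center = TRUE` (else 0), and \eqn{\mathrm{OR}_{ij}} is the per-allele
#' odds ratio: the sun-sensitive or non-sensitive stratified value for MC1R
#' SNPs when `stratify_mc1r = TRUE` (chosen per participant via
#' [sun_sensitive()]), otherwise the overall value. Centering shifts every
#' participant by the same constant, so ranks, tertiles and all downstream
#' discrimination metrics are unaffected by it.
#'
#' @param cohort Cohort tibble with a `dose_<snp_id>` column per manifest SNP.
#' @param manifest A validated weights manifest (see [read_weights_manifest()]).
#' @param pathway Optional pathway label; restricts scoring to SNPs whose
#'   pathway set contains it. SNPs may contribute to several pathway scores.
#' @param mc1r_only If `TRUE`, restrict to MC1R SNPs (overrides `pathway`).
#' @param stratify_mc1r Use phenotype-stratified MC1R odds ratios.
#' @param center Subtract expected dosage `2 * eaf` before weighting.
#' @param name Name of the added score column; defaults to `prs_<pathway>` or
#'   `prs_overall` / `prs_mc1r`.
#' @return `cohort` with the score column appended.
#' @export
polygenic_score <- function(cohort, manifest, pathway = NULL,
                            mc1r_only = FALSE, stratify_mc1r = FALSE,
                            center = TRUE, name = NULL) {
  manifest <- validate_weights(manifest)
  sub <- subset_manifest(manifest, pathway = pathway, mc1r_only = mc1r_only)
  if (nrow(sub) == 0) {
    abort("no SNPs left after pathway restriction", class = "melrisk_validation_error")
  }
  cols <- dose_col(sub$snp_id)
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("cohort is missing dosage column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "melrisk_missing_column")
  }
  D <- as.matrix(cohort[cols])
  if (any(!is.finite(D)) || any(D < 0 | D > 2)) {
    abort("dosages must be finite values in [0, 2]", class = "melrisk_validation_error")
  }
  if (center) D <- sweep(D, 2, 2 * sub$eaf)

  w_overall <- log(sub$or_overall)
  if (stratify_mc1r) {
    mc1r <- isTRUE_vec(sub$is_mc1r)
    if (any(mc1r & (is.na(sub$or_sun_sensitive) | is.na(sub$or_not_sensitive)))) {
      abort("stratify_mc1r = TRUE but a stratified odds ratio is absent",
            class = "melrisk_validation_error")
    }
    ss <- sun_sensitive(cohort)
    W <- matrix(w_overall, nrow = nrow(D), ncol = ncol(D), byrow = TRUE)
    for (j in which(mc1r)) {
      W[, j] <- ifelse(ss, log(sub$or_sun_sensitive[j]), log(sub$or_not_sensitive[j]))
    }
    score <- rowSums(D * W)
  } else {
    score <- drop(D %*% w_overall)
  }

  name <- name %||% paste0(
    "prs_", if (mc1r_only) "mc1r" else pathway %||% "overall"
  )
  cohort[[name]] <- score
  cohort
}

#' Example traditional risk-factor weights
#'
#' A per-level log odds ratio table for the traditional melanoma risk factors
#' (reference levels carry weight zero). The hair-color, nevus-density,
#' keratinocyte-cancer and sunbed values follow per-study adjusted estimates
#' from the Australian case-control model; the remaining values are
#' illustrative defaults in the range reported by risk-factor meta-analyses.
#' For real analyses supply published meta-analysis weights in the same shape.
#'
#' @return Tibble with columns `factor`, `level`, `log_or`.
#' @export
default_traditional_weights <- function() {
  or <- function(f, lev, ors) tibble(factor = f, level = lev, log_or = log(ors))
  bind_rows(
    or("hair_color", c("dark", "light_brown", "fair_blonde", "red"),
       c(1, 1.01, 1.82, 2.76)),
    or("eye_color", c("brown_black", "green_hazel", "blue_grey"),
       c(1, 1.05, 1.39)),
    or("skin_color", c("olive_dark", "medium", "fair"), c(1, 1.35, 1.80)),
    or("freckling", c("none", "few", "some", "many"), c(1, 1.20, 1.45, 1.75)),
    or("photosensitivity",
       c("never_burn", "sometimes_burn", "usually_burn", "always_burn"),
       c(1, 1.20, 1.60, 2.00)),
    or("nevus_density", c("none", "few", "some", "many"),
       c(1, 1.19, 3.13, 5.36)),
    or("sunbed_use", c("none", "s1_10", "gt10"), c(1, 0.96, 1.79)),
    or("blistering_sunburn_child", c("none", "one_plus"), c(1, 1.40)),
    or("vacation_sun_q", c("q1", "q2", "q3", "q4"), c(1, 1.10, 1.20, 1.35)),
    or("kc_history", c("no", "yes"), c(1, 2.28)),
    or("family_history", c("none", "one_plus"), c(1, 1.74))
  )
}

#' Compute a traditional risk score from per-level weights
#'
#' Sums, over the traditional risk factors, the log odds ratio attached to
#' each participant's level. The result is a linear predictor on the log-odds
#' scale; it is a monotone transform of the predicted probability from the
#' corresponding logistic model, so tertile assignment and rank-based metrics
#' are identical whichever scale is used.
#'
#' @param cohort Cohort tibble containing every factor named in `weights`.
#' @param weights Tibble with columns `factor`, `level`, `log_or`
#'   (see [default_traditional_weights()]). Every level occurring in the
#'   cohort must be mapped; reference levels must be present with weight 0.
#' @param name Name of the added score column.
#' @return `cohort` with the score column appended.
#' @export
traditional_score <- function(cohort, weights = default_traditional_weights(),
                              name = "score_trad") {
  check_cols(weights, c("factor", "level", "log_or"), where = "traditional weights")
  factors <- unique(weights$factor)
  check_cols(cohort, factors, where = "cohort")
  score <- numeric(nrow(cohort))
  for (f in factors) {
    w <- weights[weights$factor == f, ]
    map <- setNames(w$log_or, w$level)
    lev <- as.character(cohort[[f]])
    bad <- setdiff(unique(lev), names(map))
    if (length(bad) > 0) {
      abort(sprintf("no weight for level(s) %s of factor %s",
                    paste(bad, collapse = ", "), f),
            class = "melrisk_validation_error")
    }
    score <- score + unname(map[lev])
  }
  cohort[[name]] <- score
  cohort
}
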