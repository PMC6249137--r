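#' Incremental-value evaluation of genetic scores over a traditional model
#'
#' Fits the base model (traditional risk score as a fixed-weight offset,
#' demographic covariates estimated freely) and, for each genetic score set
#' (MC1R only, each biological pathway, and all SNPs), the enhanced model
#' with the polygenic score added as a second offset. For every comparison it
#' reports both AUCs, the AUC change with its correlated-ROC chi-square
#' P-value, Hosmer-Lemeshow calibration P of the enhanced model, and the
#' event / nonevent / total continuous NRI with 95% CIs.
#'
#' @param cohort Cohort tibble.
#' @param manifest Weights manifest.
#' @param trad_weights Traditional per-level weights
#'   (see [default_traditional_weights()]).
#' @param spec A [model_spec()]; its forced covariates are estimated freely in
#'   every model.
#' @param score_sets Character vector naming which genetic score sets to
#'   evaluate; any of `"mc1r"`, the [pathway_labels()], `"all"`.
#' @param stratify_mc1r,center Passed to [polygenic_score()].
#' @param hl_groups Risk groups for the calibration test.
#' @return A `mel_evaluation` tibble: one row per score set with columns
#'   `model`, `auc`, `auc_lo`, `auc_hi`, `delta_auc`, `p_delta`, `hl_p`,
#'   `nri_event`, `nri_nonevent`, `nri_total` and CI columns, preceded by the
#'   base-model row. Attributes `base_fit` and `predictions` carry the fitted
#'   objects.
#' @export
evaluate_models <- function(cohort, manifest,
                            trad_weights = default_traditional_weights(),
                            spec = model_spec(),
                            score_sets = c("mc1r", pathway_labels(), "all"),
                            stratify_mc1r = TRUE, center = TRUE,
                            hl_groups = 10) {
  manifest <- validate_weights(manifest)
  cohort <- traditional_score(cohort, trad_weights, name = ".score_trad")
  base_fit <- fixed_weight_model(cohort, spec, scores = ".score_trad")
  p_base <- base_fit$fitted_prob
  y <- cohort[[spec$outcome]]
  base_auc <- auc_vec(p_base, y)

  rows <- list(tibble(
    model = "base_traditional",
    auc = base_auc$auc, auc_lo = base_auc$ci_lo, auc_hi = base_auc$ci_hi,
    delta_auc = NA_real_, p_delta = NA_real_,
    hl_p = hosmer_lemeshow_vec(p_base, y, g = hl_groups)$p,
    nri_event = NA_real_, nri_event_lo = NA_real_, nri_event_hi = NA_real_,
    nri_nonevent = NA_real_, nri_nonevent_lo = NA_real_, nri_nonevent_hi = NA_real_,
    nri_total = NA_real_, nri_total_lo = NA_real_, nri_total_hi = NA_real_
  ))
  preds <- list(base_traditional = p_base)

  for (set in score_sets) {
    sc <- switch(set,
      mc1r = polygenic_score(cohort, manifest, mc1r_only = TRUE,
                             stratify_mc1r = stratify_mc1r, center = center,
                             name = ".prs"),
      all = polygenic_score(cohort, manifest, stratify_mc1r = stratify_mc1r,
                            center = center, name = ".prs"),
      polygenic_score(cohort, manifest, pathway = set,
                      stratify_mc1r = stratify_mc1r, center = center,
                      name = ".prs")
    )
    fit <- fixed_weight_model(sc, spec, scores = c(".score_trad", ".prs"))
    p_new <- fit$fitted_prob
    a <- auc_vec(p_new, y)
    cmp <- compare_auc_vec(p_base, p_new, y)
    nri <- continuous_nri_vec(p_base, p_new, y)
    hl <- hosmer_lemeshow_vec(p_new, y, g = hl_groups)
    rows <- c(rows, list(tibble(
      model = paste0("plus_", set),
      auc = a$auc, auc_lo = a$ci_lo, auc_hi = a$ci_hi,
      delta_auc = cmp$delta_auc, p_delta = cmp$p, hl_p = hl$p,
      nri_event = nri$event, nri_event_lo = nri$event_ci[1],
      nri_event_hi = nri$event_ci[2],
      nri_nonevent = nri$nonevent, nri_nonevent_lo = nri$nonevent_ci[1],
      nri_nonevent_hi = nri$nonevent_ci[2],
      nri_total = nri$total, nri_total_lo = nri$total_ci[1],
      nri_total_hi = nri$total_ci[2]
    )))
    preds[[paste0("plus_", set)]] <- p_new
  }
  out <- bind_rows(rows)
  attr(out, "base_fit") <- base_fit
  attr(out, "predictions") <- preds
  attr(out, "status") <- y
  class(out) <- c("mel_evaluation", class(out))
  out
}

#' Write an evaluation report
#'
#' Writes the rounded human-readable TSV and, when `json_path` is given, a
#' JSON twin with every number unrounded plus the provenance fields.
#'
#' @param x A `mel_evaluation`.
#' @param path TSV output path.
#' @param json_path Optional JSON output path.
#' @param seed,config_hash Optional provenance recorded in the JSON twin.
#' @return `x`, invisibly.
#' @export
write_evaluation <- function(x, path, json_path = NULL, seed = NULL,
                             config_hash = NULL) {
  disp <- dplyr::mutate(as_tibble(x), dplyr::across(
    dplyr::where(is.numeric), ~ signif(.x, 4)))
  readr::write_tsv(disp, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      seed = seed, config_hash = config_hash,
      results = as_tibble(x)
    ), json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(x)
}

#' Tertile cross-tabulation report of polygenic versus traditional risk
#'
#' Computes the traditional and polygenic scores on a cohort, assigns
#' within-sample tertiles to each, cross-tabulates them and summarises
#' concordance and the two discordant cells. Optionally writes the TSV table
#' and its JSON twin (which records the seed and configuration hash).
#'
#' @inheritParams evaluate_models
#' @param out_tsv,out_json Optional output paths.
#' @param seed,config_hash Optional provenance recorded in the JSON twin.
#' @return A `crosstab_report` list: `crosstab` (a `crosstab3`),
#'   `concordance`, `discordant`, `seed`, `config_hash`.
#' @export
crosstab_report <- function(cohort, manifest,
                            trad_weights = default_traditional_weights(),
                            stratify_mc1r = TRUE, center = TRUE,
                            out_tsv = NULL, out_json = NULL,
                            seed = NULL, config_hash = NULL) {
  cohort <- traditional_score(cohort, trad_weights, name = ".score_trad")
  cohort <- polygenic_score(cohort, manifest, stratify_mc1r = stratify_mc1r,
                            center = center, name = ".prs")
  trad_t <- assign_tertiles(cohort$.score_trad)
  prs_t <- assign_tertiles(cohort$.prs)
  ct <- cross_tab(trad_t, prs_t)
  if (!is.null(out_tsv)) write_crosstab(ct, out_tsv, json_path = out_json)
  if (is.null(out_tsv) && !is.null(out_json)) {
    disc <- discordant_cells(ct)
    jsonlite::write_json(list(
      seed = seed, config_hash = config_hash,
      counts = ct$counts, n = ct$n, concordance = concordance(ct),
      low_trad_high_prs = disc$low_trad_high_prs,
      high_trad_low_prs = disc$high_trad_low_prs
    ), out_json, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  structure(list(
    crosstab = ct, concordance = concordance(ct),
    discordant = discordant_cells(ct),
    seed = seed, config_hash = config_hash
  ), class = "crosstab_report")
}

#' @export
print.crosstab_report <- function(x, ...) {
  print(x$crosstab)
  cat(sprintf("low traditional / high polygenic: %.1f%%; high traditional / low polygenic: %.1f%%\n",
              100 * x$discordant$low_trad_high_prs,
              100 * x$discordant$high_trad_low_prs))
  invisible(x)
}
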