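#' Pathway labels used in weights manifests
#' @return Character vector of the three recognised pathway labels.
#' @export
pathway_labels <- function() {
  c("pigmentation", "nevus", "telomere_senescence_other")
}

#' Read a per-SNP weights manifest
#'
#' A weights manifest is a TSV with one row per SNP and columns
#' `snp_id`, `gene`, `effect_allele`, `eaf` (effect-allele frequency),
#' `or_overall` (per-allele odds ratio), `or_sun_sensitive`,
#' `or_not_sensitive` (phenotype-stratified per-allele odds ratios, `NA`
#' except for MC1R variants), `is_mc1r` (logical) and `pathways`
#' (comma-joined subset of [pathway_labels()]).
#'
#' @param path Path to the TSV file.
#' @param paper_default If `TRUE`, additionally enforce the reference weight
#'   set structure: exactly 45 SNPs in 21 genes with pathway SNP counts
#'   31 (pigmentation), 13 (nevus), 9 (telomere/senescence/other);
#'   pathway membership may overlap.
#' @return A validated tibble with `pathways` parsed into a list column.
#' @export
read_weights_manifest <- function(path, paper_default = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("weights manifest not found: %s", path),
          class = "melrisk_config_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    gene = readr::col_character(),
    effect_allele = readr::col_character(),
    eaf = readr::col_double(),
    or_overall = readr::col_double(),
    or_sun_sensitive = readr::col_double(),
    or_not_sensitive = readr::col_double(),
    is_mc1r = readr::col_logical(),
    pathways = readr::col_character()
  ))
  raw$pathways <- stringr::str_split(raw$pathways, ",\\s*")
  validate_weights(raw, paper_default = paper_default)
}

#' Validate a weights manifest
#'
#' Checks uniqueness of SNP ids, frequency and odds-ratio ranges, that
#' stratified odds ratios are present for all MC1R rows and absent elsewhere,
#' and that every row carries a non-empty subset of [pathway_labels()].
#'
#' @param manifest A data frame shaped as in [read_weights_manifest()]
#'   (`pathways` may be a list column or comma-joined strings).
#' @inheritParams read_weights_manifest
#' @return The manifest as a validated tibble, invisibly identical in content.
#' @export
validate_weights <- function(manifest, paper_default = FALSE) {
  manifest <- as_tibble(manifest)
  required <- c("snp_id", "gene", "effect_allele", "eaf", "or_overall",
                "or_sun_sensitive", "or_not_sensitive", "is_mc1r", "pathways")
  check_cols(manifest, required, where = "weights manifest")
  if (!is.list(manifest$pathways)) {
    manifest$pathways <- stringr::str_split(as.character(manifest$pathways), ",\\s*")
  }

  fail <- function(rows, field, msg) {
    abort(sprintf("weights manifest: %s [row %s, field %s]",
                  msg, paste(rows, collapse = ", "), field),
          class = "melrisk_validation_error")
  }
  dup <- manifest$snp_id[duplicated(manifest$snp_id)]
  if (length(dup) > 0) {
    fail(which(manifest$snp_id %in% dup), "snp_id",
         paste("duplicate snp_id:", paste(unique(dup), collapse = ", ")))
  }
  bad <- which(is.na(manifest$eaf) | manifest$eaf < 0 | manifest$eaf > 1)
  if (length(bad) > 0) fail(bad, "eaf", "effect-allele frequency outside [0, 1]")
  bad <- which(is.na(manifest$or_overall) | manifest$or_overall <= 0)
  if (length(bad) > 0) fail(bad, "or_overall", "odds ratio must be > 0")

  mc1r <- isTRUE_vec(manifest$is_mc1r)
  strat_present <- !is.na(manifest$or_sun_sensitive) & !is.na(manifest$or_not_sensitive)
  bad <- which(mc1r & !strat_present)
  if (length(bad) > 0) {
    fail(bad, "or_sun_sensitive/or_not_sensitive",
         "MC1R rows require both stratified odds ratios")
  }
  bad <- which(!mc1r & (!is.na(manifest$or_sun_sensitive) | !is.na(manifest$or_not_sensitive)))
  if (length(bad) > 0) {
    fail(bad, "or_sun_sensitive/or_not_sensitive",
         "stratified odds ratios are only meaningful for MC1R rows")
  }
  bad <- which(mc1r & (manifest$or_sun_sensitive <= 0 | manifest$or_not_sensitive <= 0))
  if (length(bad) > 0) fail(bad, "or_sun_sensitive/or_not_sensitive", "odds ratio must be > 0")

  ok_path <- purrr::map_lgl(manifest$pathways, function(p) {
    length(p) > 0 && all(p %in% pathway_labels())
  })
  if (any(!ok_path)) {
    fail(which(!ok_path), "pathways",
         sprintf("pathways must be a non-empty subset of {%s}",
                 paste(pathway_labels(), collapse = ", ")))
  }

  if (paper_default) {
    n_snp <- nrow(manifest)
    n_gene <- dplyr::n_distinct(manifest$gene)
    counts <- vapply(pathway_labels(), function(lab) {
      sum(purrr::map_lgl(manifest$pathways, ~ lab %in% .x))
    }, integer(1))
    expected <- c(pigmentation = 31L, nevus = 13L, telomere_senescence_other = 9L)
    if (n_snp != 45L || n_gene != 21L || !identical(counts, expected)) {
      abort(sprintf(
        paste0("reference weight set must have 45 SNPs in 21 genes with ",
               "pathway SNP counts 31/13/9; got %d SNPs, %d genes, counts %s"),
        n_snp, n_gene, paste(counts, collapse = "/")
      ), class = "melrisk_validation_error")
    }
  }
  manifest
}

isTRUE_vec <- function(x) !is.na(x) & x

#' The default 45-SNP weights manifest
#'
#' Returns the weight set shipped with the package: 45 SNPs in 21 melanoma
#' susceptibility genes/loci, with pathway assignments (14 genes / 31 SNPs
#' pigmentation, 7 genes / 13 SNPs nevus, 5 genes / 9 SNPs
#' telomere/senescence/other; genes and SNPs may belong to several pathways)
#' and sun-sensitivity-stratified odds ratios for the eight MC1R coding
#' variants.
#'
#' The structure (SNP/gene/pathway counts, MC1R stratification) matches the
#' published melanoma weight set; the numeric effect-allele frequencies and
#' odds ratios are illustrative defaults, not the published meta-analysis
#' estimates, which live in supplementary material and should be supplied by
#' the user via [read_weights_manifest()] for real analyses. Rows whose
#' `snp_id` is not a published melanoma variant are synthetic placeholders
#' that keep the structural invariants satisfied.
#'
#' @return A validated weights manifest tibble.
#' @export
#' @examples
#' w <- default_weights()
#' nrow(w)                     # 45
#' sum(w$is_mc1r)              # 8
default_weights <- function() {
  read_weights_manifest(
    system.file("extdata", "weights_default.tsv", package = "melrisk"),
    paper_default = TRUE
  )
}

# restrict a manifest to one pathway (or MC1R rows); used by scoring/reports
subset_manifest <- function(manifest, pathway = NULL, mc1r_only = FALSE) {
  if (mc1r_only) {
    return(manifest[isTRUE_vec(manifest$is_mc1r), , drop = FALSE])
  }
  if (is.null(pathway)) return(manifest)
  if (!pathway %in% pathway_labels()) {
    abort(sprintf("unknown pathway '%s' (allowed: %s)", pathway,
                  paste(pathway_labels(), collapse = ", ")),
          class = "melrisk_validation_error")
  }
  keep <- purrr::map_lgl(manifest$pathways, ~ pathway %in% .x)
  manifest[keep, , drop = FALSE]
}
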