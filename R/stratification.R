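#' Assign tertiles of a risk score
#'
#' Cutpoints are the 1/3 and 2/3 quantiles of the input sample. Intervals are
#' half-open `[low, high)` with values exactly at a cutpoint assigned to the
#' upper category, so with distinct values the categories are exact thirds.
#'
#' @param x Finite numeric score, length >= 3.
#' @param cutpoints Optional externally supplied cutpoints (length 2).
#' @return Integer vector in `{1, 2, 3}`.
#' @export
#' @examples
#' table(assign_tertiles(1:9))   # 3 / 3 / 3
assign_tertiles <- function(x, cutpoints = NULL) {
  if (length(x) < 3) abort("need at least 3 values", class = "melrisk_validation_error")
  cutpoints <- cutpoints %||% quantile_cutpoints(x, 3)
  assign_categories(x, cutpoints)
}

#' Cross-tabulate traditional versus polygenic tertiles
#'
#' @param trad,prs Integer tertile vectors in `{1, 2, 3}` of equal length
#'   (rows of the table = traditional tertile, columns = polygenic tertile).
#' @return A `crosstab3`: 3x3 `counts`, full-precision `row_pct`, and `n`.
#' @export
cross_tab <- function(trad, prs) {
  if (length(trad) != length(prs)) {
    abort("tertile vectors must have equal length", class = "melrisk_validation_error")
  }
  if (!all(trad %in% 1:3) || !all(prs %in% 1:3)) {
    abort("tertile vectors must take values in {1, 2, 3}",
          class = "melrisk_validation_error")
  }
  counts <- table(factor(trad, 1:3), factor(prs, 1:3))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(trad = paste0("T", 1:3), prs = paste0("T", 1:3)))
  new_crosstab3(counts)
}

#' Construct a `crosstab3` from a 3x3 count matrix
#'
#' Useful for working directly with published cross-tabulation counts.
#'
#' @param counts 3x3 matrix of non-negative integers (rows = traditional
#'   tertile, columns = polygenic tertile).
#' @return A `crosstab3`.
#' @export
new_crosstab3 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("counts must be a 3x3 matrix of non-negative integers",
          class = "melrisk_validation_error")
  }
  storage.mode(counts) <- "integer"
  if (is.null(dimnames(counts))) {
    dimnames(counts) <- list(trad = paste0("T", 1:3), prs = paste0("T", 1:3))
  }
  row_tot <- rowSums(counts)
  row_pct <- sweep(counts, 1, pmax(row_tot, 1), "/") * 100
  structure(list(counts = counts, row_pct = row_pct, n = sum(counts)),
            class = "crosstab3")
}

#' @export
print.crosstab3 <- function(x, ...) {
  cat(sprintf("<crosstab3> n = %d (rows: traditional tertile, cols: polygenic tertile)\n",
              x$n))
  disp <- matrix(sprintf("%d (%d)", x$counts, round_half_up(x$row_pct)),
                 3, 3, dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  cat(sprintf("concordant: %.0f%%\n", 100 * round_half_up(concordance(x), 2)))
  invisible(x)
}

#' Tertile concordance
#'
#' Proportion of participants assigned the same tertile by both scores:
#' the diagonal sum over the total.
#'
#' @param ct A `crosstab3`.
#' @return Proportion in `[0, 1]`.
#' @export
concordance <- function(ct) {
  stopifnot(inherits(ct, "crosstab3"))
  if (ct$n == 0) abort("empty cross-tabulation", class = "melrisk_validation_error")
  sum(diag(ct$counts)) / ct$n
}

#' Discordant-cell row proportions
#'
#' The two clinically interesting discordant cells: participants in the
#' lowest traditional tertile but highest polygenic tertile (genetic
#' susceptibility without the phenotypic risk profile), and the converse, each
#' as a proportion of its traditional-tertile row.
#'
#' @param ct A `crosstab3`.
#' @return List with `low_trad_high_prs` and `high_trad_low_prs`.
#' @export
discordant_cells <- function(ct) {
  stopifnot(inherits(ct, "crosstab3"))
  row1 <- sum(ct$counts[1, ]); row3 <- sum(ct$counts[3, ])
  if (row1 == 0 || row3 == 0) {
    abort("empty traditional-tertile row", class = "melrisk_validation_error")
  }
  list(low_trad_high_prs = ct$counts[1, 3] / row1,
       high_trad_low_prs = ct$counts[3, 1] / row3)
}

#' Published tertile cross-tabulations from the two case-control studies
#'
#' The printed 3x3 cross-tabulations of traditional (rows) versus polygenic
#' (columns) risk-score tertiles from the Australian (n = 1,035) and Leeds
#' (n = 1,460) melanoma case-control studies, for reproducing the concordance
#' and discordant-cell arithmetic.
#'
#' @return Named list of two `crosstab3` objects (`australia`, `leeds`).
#' @export
#' @examples
#' round(100 * concordance(published_crosstabs()$australia))   # 59
published_crosstabs <- function() {
  list(
    australia = new_crosstab3(matrix(c(223, 91, 30,
                                       94, 160, 91,
                                       27, 94, 225), 3, 3, byrow = TRUE)),
    leeds = new_crosstab3(matrix(c(244, 138, 104,
                                   153, 209, 125,
                                   89, 140, 258), 3, 3, byrow = TRUE))
  )
}

#' Write / read a cross-tabulation report
#'
#' `write_crosstab()` writes a human-readable TSV mirroring the published
#' table layout (counts with row percentages in parentheses) and, when
#' `json_path` is given, a machine-readable JSON twin holding the unrounded
#' numbers. `read_crosstab()` reads the JSON twin back; the round trip
#' reproduces the counts exactly.
#'
#' @param ct A `crosstab3`.
#' @param path TSV output path.
#' @param json_path Optional JSON output path.
#' @return `ct`, invisibly.
#' @export
write_crosstab <- function(ct, path, json_path = NULL) {
  stopifnot(inherits(ct, "crosstab3"))
  cells <- matrix(sprintf("%d (%d)", ct$counts, round_half_up(ct$row_pct)), 3, 3)
  out <- tibble(
    traditional = paste0("tertile_", 1:3),
    prs_t1 = cells[, 1], prs_t2 = cells[, 2], prs_t3 = cells[, 3],
    total = sprintf("%d (100)", rowSums(ct$counts))
  )
  readr::write_tsv(out, path)
  if (!is.null(json_path)) {
    disc <- discordant_cells(ct)
    jsonlite::write_json(list(
      counts = ct$counts, row_pct = ct$row_pct, n = ct$n,
      concordance = concordance(ct),
      low_trad_high_prs = disc$low_trad_high_prs,
      high_trad_low_prs = disc$high_trad_low_prs
    ), json_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(ct)
}

#' @rdname write_crosstab
#' @export
read_crosstab <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  new_crosstab3(matrix(as.integer(t(obj$counts)), 3, 3, byrow = TRUE))
}
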