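#' Specify a logistic risk model
#'
#' @param outcome Name of the binary status column (1 = case).
#' @param forced Covariates always kept in the model (demographic and study
#'   design factors; typically age, sex, center, ancestry). Forced terms that
#'   are constant in a given cohort (e.g. a single recruitment center) are
#'   dropped at fit time and recorded on the fit.
#' @param candidates Risk-factor terms eligible for backward selection.
#' @param offsets Names of precomputed score columns entering the linear
#'   predictor with coefficient fixed at 1.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome = "status",
                       forced = c("age", "sex", "center", "ancestry"),
                       candidates = character(),
                       offsets = character()) {
  overlap <- intersect(forced, candidates)
  if (length(overlap) > 0) {
    abort(sprintf("terms cannot be both forced and candidate: %s",
                  paste(overlap, collapse = ", ")),
          class = "melrisk_config_error")
  }
  structure(list(outcome = outcome, forced = forced,
                 candidates = candidates, offsets = offsets),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s ~ forced(%s) + candidates(%s)%s\n",
              x$outcome, paste(x$forced, collapse = ", "),
              paste(x$candidates, collapse = ", "),
              if (length(x$offsets)) paste0(" + offset(", paste(x$offsets, collapse = " + "), ")")
              else ""))
  invisible(x)
}

build_formula <- function(spec, terms, offsets) {
  rhs <- c(terms, if (length(offsets)) paste0("offset(", offsets, ")"))
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + ")))
}

#' Fit a logistic risk model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) with the diagnostics a case-control risk
#' analysis needs: rows with missing values in any used column are rejected,
#' forced terms constant in the data are dropped (and recorded), collinear
#' terms raise an error naming them, and quasi-complete separation (fitted
#' probabilities at the 0/1 boundary) raises an explicit diagnostic rather
#' than returning a silently divergent fit. Offset terms enter the linear
#' predictor with coefficient fixed at 1.
#'
#' @param cohort Cohort tibble.
#' @param spec A [model_spec()].
#' @param terms Free model terms in addition to the forced covariates;
#'   defaults to `spec$candidates`.
#' @param offsets Offset columns; defaults to `spec$offsets`.
#' @return A `mel_fit` with elements `model` (the glm), `coefficients`,
#'   `vcov`, `fitted_prob`, `loglik`, `converged`, `dropped`, `terms_used`.
#' @export
fit_logistic <- function(cohort, spec = model_spec(), terms = spec$candidates,
                         offsets = spec$offsets) {
  all_terms <- unique(c(spec$forced, terms))
  used_cols <- unique(c(spec$outcome, all_terms, offsets))
  check_cols(cohort, used_cols, where = "cohort")
  y <- cohort[[spec$outcome]]
  if (!all(y %in% c(0, 1))) {
    abort("outcome must be coded 0/1", class = "melrisk_validation_error")
  }
  has_na <- vapply(cohort[used_cols], function(x) any(is.na(x)), logical(1))
  if (any(has_na)) {
    abort(sprintf("missing values in column(s): %s; filter to complete cases first",
                  paste(used_cols[has_na], collapse = ", ")),
          class = "melrisk_validation_error")
  }
  constant <- all_terms[vapply(cohort[all_terms],
                               function(x) dplyr::n_distinct(x) < 2, logical(1))]
  keep_terms <- setdiff(all_terms, constant)
  data <- as.data.frame(cohort[used_cols])
  for (v in keep_terms) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  }
  form <- build_formula(spec, keep_terms, offsets)
  # glm's boundary warning is superseded by the explicit separation check below
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = data,
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(is.na(coef(fit)))) {
    abort(sprintf("singular design: collinear term(s) %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "melrisk_singular_error")
  }
  eps <- 1e-10
  if (any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)) {
    abort("perfect or quasi-complete separation detected (fitted probabilities at the boundary)",
          class = "melrisk_separation_error")
  }
  structure(list(
    model = fit, spec = spec, terms_used = keep_terms, offsets = offsets,
    dropped = constant,
    coefficients = coef(fit), vcov = vcov(fit),
    fitted_prob = unname(fit$fitted.values),
    loglik = as.numeric(logLik(fit)),
    converged = fit$converged,
    n = nrow(data), n_case = sum(y == 1), n_control = sum(y == 0)
  ), class = "mel_fit")
}

#' @export
print.mel_fit <- function(x, ...) {
  cat(sprintf("<mel_fit> n = %d (%d cases), logLik = %.2f, converged: %s\n",
              x$n, x$n_case, x$loglik, x$converged))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Fit a model with published scores as fixed-weight offsets
#'
#' The primary analysis keeps externally published weights fixed: each score
#' enters the linear predictor with coefficient pinned to 1 (an offset), while
#' the intercept and the forced demographic covariates are estimated freely.
#' The fitted probabilities are the predicted risks used for AUC, NRI and
#' calibration. Set `refit = TRUE` to instead estimate a free coefficient per
#' score (the secondary, internally-derived analysis).
#'
#' @inheritParams fit_logistic
#' @param scores Character vector of score column names.
#' @param refit Estimate free coefficients for the scores instead of offsets.
#' @return A `mel_fit`.
#' @export
fixed_weight_model <- function(cohort, spec = model_spec(), scores,
                               refit = FALSE) {
  if (refit) {
    fit_logistic(cohort, spec, terms = c(spec$candidates, scores), offsets = character())
  } else {
    fit_logistic(cohort, spec, terms = spec$candidates, offsets = scores)
  }
}

# likelihood-ratio p-value for dropping one term from a fitted model
lr_drop_p <- function(cohort, spec, terms, offsets, full_fit, term) {
  reduced <- fit_logistic(cohort, spec, terms = setdiff(terms, term),
                          offsets = offsets)
  df <- length(full_fit$coefficients) - length(reduced$coefficients)
  stat <- 2 * (full_fit$loglik - reduced$loglik)
  pchisq(max(stat, 0), df = max(df, 1L), lower.tail = FALSE)
}

#' Backward selection with forced covariates
#'
#' Starting from the model with all candidate terms, repeatedly refits and
#' removes the candidate with the largest likelihood-ratio P-value at or above
#' `p_retain` (multi-level factors are tested jointly; ties broken in favour
#' of the candidate listed later), until every remaining candidate has
#' P < `p_retain`. Forced covariates are never dropped.
#'
#' @inheritParams fit_logistic
#' @param p_retain Retention threshold on the candidate P-value (default 0.20).
#' @return A `mel_selection`: list with the final `fit`, the `retained`
#'   candidates, and a `trace` tibble of removals (step, term, p).
#' @export
backward_select <- function(cohort, spec, p_retain = 0.20) {
  current <- spec$candidates
  trace <- tibble(step = integer(), dropped = character(), p = numeric())
  step <- 0L
  repeat {
    fit <- fit_logistic(cohort, spec, terms = current)
    active <- intersect(current, fit$terms_used)
    if (length(active) == 0) break
    pvals <- vapply(active, function(tm) {
      lr_drop_p(cohort, spec, current, spec$offsets, fit, tm)
    }, numeric(1))
    removable <- which(pvals >= p_retain)
    if (length(removable) == 0) break
    # largest P; ties -> later position in the candidate list
    worst_p <- max(pvals[removable])
    tied <- removable[pvals[removable] == worst_p]
    drop_term <- active[max(tied)]
    step <- step + 1L
    trace <- bind_rows(trace, tibble(step = step, dropped = drop_term,
                                     p = worst_p))
    current <- setdiff(current, drop_term)
  }
  final <- fit_logistic(cohort, spec, terms = current)
  structure(list(fit = final, retained = current, trace = trace,
                 p_retain = p_retain),
            class = "mel_selection")
}

#' @export
print.mel_selection <- function(x, ...) {
  cat(sprintf("<mel_selection> retained %d candidate(s): %s\n",
              length(x$retained), paste(x$retained, collapse = ", ")))
  if (nrow(x$trace)) print(x$trace, n = Inf)
  invisible(x)
}

#' Quantile cutpoints of a score
#'
#' @param x Numeric score.
#' @param k Number of categories.
#' @return `k - 1` interior quantiles.
#' @export
quantile_cutpoints <- function(x, k = 3) {
  unname(quantile(x, probs = seq_len(k - 1) / k, names = FALSE))
}

# assign quantile categories: half-open intervals [low, high), values exactly
# at a cutpoint go to the upper category
assign_categories <- function(x, cutpoints) {
  if (any(!is.finite(x))) {
    abort("score must be finite", class = "melrisk_validation_error")
  }
  cat <- findInterval(x, cutpoints) + 1L
  k <- length(cutpoints) + 1L
  sizes <- tabulate(cat, nbins = k)
  if (any(sizes == 0)) {
    abort(sprintf(
      "ties collapse category %s to empty (cutpoints: %s)",
      paste(which(sizes == 0), collapse = ", "),
      paste(signif(cutpoints, 6), collapse = ", ")
    ), class = "melrisk_degenerate_score")
  }
  cat
}

#' Categorical (tertile/decile) odds ratios with a trend test
#'
#' Cuts a score at quantiles of a reference sample, enters the category as
#' indicator terms (lowest category = reference) in a logistic model adjusted
#' for the spec's forced covariates, and adds a trend P-value from a model
#' with the category index as a single ordinal term (Wald test). Pass
#' precomputed `cutpoints` to categorise against a pooled or external
#' reference sample instead of the cohort itself.
#'
#' @param cohort Cohort tibble.
#' @param score Unquoted name of the score column.
#' @param spec A [model_spec()] supplying outcome and forced covariates; use
#'   `model_spec(forced = character())` for unadjusted odds ratios.
#' @param n_categories Number of quantile categories (3 = tertiles,
#'   10 = deciles).
#' @param cutpoints Optional numeric cutpoints overriding within-sample
#'   quantiles.
#' @return A `category_or_table` tibble (category, score range, case/control
#'   counts, adjusted OR with 95% CI) with attributes `trend_p` and
#'   `cutpoints`.
#' @export
category_or <- function(cohort, score, spec = model_spec(), n_categories = 3,
                        cutpoints = NULL) {
  score_vec <- dplyr::pull(cohort, {{ score }})
  cutpoints <- cutpoints %||% quantile_cutpoints(score_vec, n_categories)
  cat <- assign_categories(score_vec, cutpoints)
  data <- cohort
  data$.category <- factor(cat, levels = seq_len(n_categories))
  data$.category_index <- as.numeric(cat)

  fit_cat <- fit_logistic(data, spec, terms = ".category")
  fit_trend <- fit_logistic(data, spec, terms = ".category_index")
  td <- tidy(fit_trend)
  trend_p <- td$p.value[td$term == ".category_index"]

  cf <- fit_cat$coefficients
  se <- sqrt(diag(fit_cat$vcov))
  idx <- paste0(".category", seq(2, n_categories))
  or <- c(1, exp(cf[idx]))
  lo <- c(NA, exp(cf[idx] - 1.96 * se[idx]))
  hi <- c(NA, exp(cf[idx] + 1.96 * se[idx]))

  y <- data[[spec$outcome]]
  fcat <- factor(cat, levels = seq_len(n_categories))
  out <- tibble(
    category = seq_len(n_categories),
    range_lo = unname(vapply(split(score_vec, fcat), min, numeric(1))),
    range_hi = unname(vapply(split(score_vec, fcat), max, numeric(1))),
    n_case = unname(vapply(split(y, fcat), function(v) sum(v == 1), numeric(1))),
    n_control = unname(vapply(split(y, fcat), function(v) sum(v == 0), numeric(1))),
    or = unname(or), ci_lo = unname(lo), ci_hi = unname(hi)
  )
  attr(out, "trend_p") <- unname(trend_p)
  attr(out, "cutpoints") <- cutpoints
  class(out) <- c("category_or_table", class(out))
  out
}

#' Stratified k-fold cross-validated predictions and AUC
#'
#' Folds are stratified by case status; each participant's risk is predicted
#' by the model fit on the other `k - 1` folds, and the cross-validated AUC is
#' computed on the pooled out-of-fold predictions. With `k = n` this is
#' leave-one-out and the result no longer depends on the seed.
#'
#' @inheritParams fit_logistic
#' @param k Number of folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @return A `mel_cv`: list with `predictions` (tibble: row, fold, status,
#'   pred), `cv_auc` (an `auc_result`), and `train_auc` (apparent AUC of the
#'   model fit on all data).
#' @export
kfold_cv <- function(cohort, spec, k = 10, seed = 1) {
  n <- nrow(cohort)
  if (k < 2) abort("k must be >= 2", class = "melrisk_config_error")
  y <- cohort[[spec$outcome]]
  # shuffle within class, then deal fold labels cyclically across the
  # concatenated classes: class balance per fold, and k = n gives singletons
  withr::with_seed(seed, {
    ord <- unlist(lapply(unique(y), function(cls) sample(which(y == cls))))
  })
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  if (any(vapply(seq_len(k), function(f) sum(y[folds == f] == 1), numeric(1)) == 0) &&
      k < n) {
    abort("a fold contains no cases; use fewer, larger folds",
          class = "melrisk_config_error")
  }
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_logistic(cohort[!test, , drop = FALSE], spec)
    newdata <- as.data.frame(cohort[test, , drop = FALSE])
    for (v in fit$terms_used) {
      if (is.character(newdata[[v]])) newdata[[v]] <- factor(newdata[[v]])
    }
    pred[test] <- predict(fit$model, newdata = newdata, type = "response")
  }
  full <- fit_logistic(cohort, spec)
  structure(list(
    predictions = tibble(row = seq_len(n), fold = folds, status = y, pred = pred),
    cv_auc = auc_vec(pred, y),
    train_auc = auc_vec(full$fitted_prob, y),
    k = k, seed = seed
  ), class = "mel_cv")
}

#' @export
print.mel_cv <- function(x, ...) {
  cat(sprintf("<mel_cv> k = %d: CV AUC = %.3f (apparent %.3f)\n",
              x$k, x$cv_auc$auc, x$train_auc$auc))
  invisible(x)
}
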