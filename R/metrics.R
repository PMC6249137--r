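check_binary <- function(y) {
  if (!all(y %in% c(0, 1))) {
    abort("status must be coded 0/1", class = "melrisk_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort("both cases and controls are required", class = "melrisk_validation_error")
  }
  invisible(y)
}

# per-subject placement values (the correlated-ROC construction): v10[i] is
# the proportion of controls ranked below case i (ties count half), v01[j]
# the proportion of cases ranked above control j
placements <- function(pred, y) {
  x <- pred[y == 1]; z <- pred[y == 0]
  m <- length(x); n <- length(z)
  r <- rank(c(x, z), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(z, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Area under the ROC curve (vector interface)
#'
#' Mann-Whitney estimator: the proportion of case-control pairs in which the
#' case's predicted risk exceeds the control's, ties counting one half. The
#' 95% CI uses the correlated-ROC placement-variance estimator, which shares
#' its machinery with [compare_auc()].
#'
#' @param pred Numeric predicted risks (any monotone scale).
#' @param y Binary status (1 = case).
#' @return An `auc_result`: `auc`, `se`, `ci_lo`, `ci_hi`, `n_case`,
#'   `n_control`.
#' @export
auc_vec <- function(pred, y) {
  check_binary(y)
  pl <- placements(pred, y)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  se <- sqrt(v)
  structure(list(
    auc = pl$auc, se = se,
    ci_lo = max(0, pl$auc - 1.96 * se), ci_hi = min(1, pl$auc + 1.96 * se),
    n_case = pl$m, n_control = pl$n
  ), class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f), %d cases / %d controls\n",
              x$auc, x$ci_lo, x$ci_hi, x$n_case, x$n_control))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Data-frame interface to [auc_vec()].
#'
#' @param data A data frame.
#' @param truth Unquoted binary status column (1 = case).
#' @param estimate Unquoted predicted-risk column.
#' @return An `auc_result`.
#' @export
#' @examples
#' d <- tibble::tibble(status = c(1, 1, 0, 0), p = c(0.9, 0.4, 0.4, 0.1))
#' auc(d, status, p)   # 0.875
auc <- function(data, truth, estimate) {
  auc_vec(dplyr::pull(data, {{ estimate }}), dplyr::pull(data, {{ truth }}))
}

#' Compare two correlated AUCs on the same participants
#'
#' Paired correlated-ROC test: the variance of the AUC difference is computed
#' from the per-subject placement values of both models on the same sample,
#' the statistic \eqn{\chi^2 = \Delta AUC^2 / var} is referred to a chi-square
#' distribution with 1 degree of freedom. Because the AUC is rank-based, any
#' strictly monotone transform of either prediction vector leaves the result
#' unchanged.
#'
#' @param data A data frame.
#' @param truth Unquoted binary status column.
#' @param base,new Unquoted prediction columns for the base and enhanced model.
#' @return An `auc_comparison`: `auc_base`, `auc_new`, `delta_auc`, `chi2`,
#'   `p`.
#' @export
compare_auc <- function(data, truth, base, new) {
  compare_auc_vec(dplyr::pull(data, {{ base }}), dplyr::pull(data, {{ new }}),
                  dplyr::pull(data, {{ truth }}))
}

#' @rdname compare_auc
#' @param pred_base,pred_new,y Vector interface.
#' @export
compare_auc_vec <- function(pred_base, pred_new, y) {
  check_binary(y)
  stopifnot(length(pred_base) == length(y), length(pred_new) == length(y))
  a <- placements(pred_base, y)
  b <- placements(pred_new, y)
  d <- b$auc - a$auc
  v <- stats::var(b$v10 - a$v10) / a$m + stats::var(b$v01 - a$v01) / a$n
  if (v <= 0 || d == 0) {
    chi2 <- if (d == 0) 0 else Inf
  } else {
    chi2 <- d^2 / v
  }
  structure(list(
    auc_base = a$auc, auc_new = b$auc, delta_auc = d,
    var_delta = v, chi2 = chi2,
    p = pchisq(chi2, df = 1, lower.tail = FALSE)
  ), class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("dAUC = %.4f (%.4f -> %.4f), chi2 = %.3f, P = %.4g\n",
              x$delta_auc, x$auc_base, x$auc_new, x$chi2, x$p))
  invisible(x)
}

#' Category-free continuous net reclassification improvement
#'
#' The event (sensitivity) component is the net proportion of cases whose
#' predicted risk rises under the new model,
#' \eqn{P(\uparrow|case) - P(\downarrow|case)}; the nonevent (specificity)
#' component is the net proportion of controls whose risk falls. Ties count
#' to neither direction. The total is their sum. Per-component 95% CIs use
#' the asymptotic binomial-difference variance
#' \eqn{[p_\uparrow + p_\downarrow - (p_\uparrow - p_\downarrow)^2] / n};
#' the total CI treats the two components as independent.
#'
#' @param data A data frame.
#' @param truth Unquoted binary status column.
#' @param base,new Unquoted predicted-probability columns.
#' @return An `nri_result` with `event`, `nonevent`, `total`, standard errors
#'   and CIs.
#' @export
continuous_nri <- function(data, truth, base, new) {
  continuous_nri_vec(dplyr::pull(data, {{ base }}), dplyr::pull(data, {{ new }}),
                     dplyr::pull(data, {{ truth }}))
}

#' @rdname continuous_nri
#' @param p_base,p_new,y Vector interface.
#' @export
continuous_nri_vec <- function(p_base, p_new, y) {
  check_binary(y)
  stopifnot(length(p_base) == length(y), length(p_new) == length(y))
  comp <- function(sel, sign) {
    up <- mean(p_new[sel] > p_base[sel])
    dn <- mean(p_new[sel] < p_base[sel])
    est <- sign * (up - dn)
    se <- sqrt((up + dn - (up - dn)^2) / sum(sel))
    c(est = est, se = se)
  }
  ev <- comp(y == 1, +1)
  ne <- comp(y == 0, -1)
  tot <- ev[["est"]] + ne[["est"]]
  tot_se <- sqrt(ev[["se"]]^2 + ne[["se"]]^2)
  ci <- function(est, se) c(est - 1.96 * se, est + 1.96 * se)
  structure(list(
    event = ev[["est"]], event_se = ev[["se"]], event_ci = ci(ev[["est"]], ev[["se"]]),
    nonevent = ne[["est"]], nonevent_se = ne[["se"]],
    nonevent_ci = ci(ne[["est"]], ne[["se"]]),
    total = tot, total_se = tot_se, total_ci = ci(tot, tot_se)
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "continuous NRI: event %.3f (%.3f-%.3f), nonevent %.3f (%.3f-%.3f), total %.3f (%.3f-%.3f)\n",
    x$event, x$event_ci[1], x$event_ci[2],
    x$nonevent, x$nonevent_ci[1], x$nonevent_ci[2],
    x$total, x$total_ci[1], x$total_ci[2]
  ))
  invisible(x)
}

#' Odds ratio per adjusted standard deviation (OPERA)
#'
#' Scales a risk score by the standard deviation of its covariate-adjusted
#' residuals among controls (the controls approximate the reference
#' population), then reports the odds ratio per one adjusted-SD increase from
#' a logistic model of status on the scaled score plus the adjustment
#' covariates. The result is invariant to affine rescaling of the input
#' score. With no covariates it reduces to the OR per control-sample SD of
#' the raw score.
#'
#' @param data Cohort data frame.
#' @param score Unquoted score column.
#' @param truth Unquoted binary status column.
#' @param covars Character vector of adjustment covariates (default age, sex).
#' @param sd_sample `"controls"` (default) or `"all"`: the sample in which the
#'   adjusted SD is computed.
#' @return An `opera_result`: `or`, `ci_lo`, `ci_hi`, `log_or`, `se`,
#'   `adj_sd`.
#' @export
opera <- function(data, score, truth = status, covars = c("age", "sex"),
                  sd_sample = c("controls", "all")) {
  sd_sample <- match.arg(sd_sample)
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ truth }})
  check_binary(y)
  check_cols(data, covars, where = "cohort")
  ref <- if (sd_sample == "controls") y == 0 else rep(TRUE, length(y))
  if (length(covars) > 0) {
    dref <- as.data.frame(data[ref, covars, drop = FALSE])
    dref$.score <- s[ref]
    res <- residuals(lm(stats::as.formula(
      paste(".score ~", paste(covars, collapse = " + "))), data = dref))
    adj_sd <- sd(res)
  } else {
    adj_sd <- sd(s[ref])
  }
  if (!is.finite(adj_sd) || adj_sd <= max(1e-12, 1e-8 * sd(s[ref]))) {
    abort("degenerate score: zero adjusted standard deviation among the reference sample",
          class = "melrisk_degenerate_score")
  }
  dd <- as.data.frame(data[, covars, drop = FALSE])
  dd$.scaled <- s / adj_sd
  dd$.y <- y
  fit <- glm(stats::as.formula(
    paste(".y ~ .scaled", if (length(covars)) paste("+", paste(covars, collapse = " + ")) else "")),
    family = binomial(), data = dd)
  b <- coef(fit)[[".scaled"]]
  se <- sqrt(diag(vcov(fit)))[[".scaled"]]
  structure(list(
    or = exp(b), ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
    log_or = b, se = se, adj_sd = adj_sd, sd_sample = sd_sample
  ), class = "opera_result")
}

#' @export
print.opera_result <- function(x, ...) {
  cat(sprintf("OPERA = %.3f (95%% CI %.3f-%.3f), adjusted SD = %.4f (%s)\n",
              x$or, x$ci_lo, x$ci_hi, x$adj_sd, x$sd_sample))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Participants are ranked by predicted risk (stable sort on prediction then
#' position, so tied predictions stay together) and split into `g`
#' near-equal-size groups. The statistic is
#' \eqn{\sum_g (O_g - E_g)^2 / [E_g (1 - E_g/n_g)]} with observed and
#' expected case counts per group, referred to chi-square with `g - 2`
#' degrees of freedom. The statistic is invariant to the order of the input.
#'
#' @param data A data frame.
#' @param truth Unquoted binary status column.
#' @param estimate Unquoted predicted-probability column.
#' @param g Number of risk groups (default 10, i.e. deciles of risk).
#' @return An `hl_result`: `statistic`, `df`, `p` (`NA` when `g = 2`, a
#'   degenerate grouping with zero degrees of freedom), and the per-group
#'   `table`.
#' @export
hosmer_lemeshow <- function(data, truth, estimate, g = 10) {
  hosmer_lemeshow_vec(dplyr::pull(data, {{ estimate }}),
                      dplyr::pull(data, {{ truth }}), g = g)
}

#' @rdname hosmer_lemeshow
#' @param pred,y Vector interface.
#' @export
hosmer_lemeshow_vec <- function(pred, y, g = 10) {
  check_binary(y)
  n <- length(pred)
  if (n < 2 * g) {
    abort("need at least 2 observations per group", class = "melrisk_config_error")
  }
  ord <- order(pred, seq_along(pred))
  grp <- ceiling(seq_len(n) * g / n)
  tab <- tibble(
    group = seq_len(g),
    n_g = as.numeric(tabulate(grp, g)),
    observed = vapply(seq_len(g), function(k) sum(y[ord][grp == k]), numeric(1)),
    expected = vapply(seq_len(g), function(k) sum(pred[ord][grp == k]), numeric(1))
  )
  if (any(tab$expected <= 0 | tab$expected >= tab$n_g)) {
    abort("a risk group has expected count 0 or n; use fewer groups",
          class = "melrisk_config_error")
  }
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n_g)))
  df <- g - 2L
  p <- if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  structure(list(statistic = stat, df = df, p = p, table = tab),
            class = "hl_result")
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi2 = %.3f on %d df, P = %s\n",
              x$statistic, x$df,
              if (is.na(x$p)) "NA (degenerate grouping)" else sprintf("%.4g", x$p)))
  invisible(x)
}
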