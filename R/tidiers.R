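#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted logistic risk model
#'
#' @param x A `mel_fit`.
#' @param exponentiate Report odds ratios instead of log odds ratios.
#' @param ... Unused.
#' @return Tibble with term, estimate, std.error, statistic, p.value,
#'   conf.low, conf.high.
#' @export
tidy.mel_fit <- function(x, exponentiate = FALSE, ...) {
  cf <- x$coefficients
  se <- sqrt(diag(x$vcov))
  est <- cf; lo <- cf - 1.96 * se; hi <- cf + 1.96 * se
  if (exponentiate) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  tibble(
    term = names(cf), estimate = unname(est), std.error = unname(se),
    statistic = unname(cf / se),
    p.value = 2 * pnorm(abs(unname(cf / se)), lower.tail = FALSE),
    conf.low = unname(lo), conf.high = unname(hi)
  )
}

#' @rdname tidy.mel_fit
#' @export
glance.mel_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, AIC = x$model$aic, n = x$n,
    n_case = x$n_case, n_control = x$n_control,
    converged = x$converged
  )
}

#' @export
tidy.auc_result <- function(x, ...) {
  tibble(auc = x$auc, std.error = x$se, conf.low = x$ci_lo, conf.high = x$ci_hi,
         n_case = x$n_case, n_control = x$n_control)
}

#' @export
tidy.auc_comparison <- function(x, ...) {
  tibble(auc_base = x$auc_base, auc_new = x$auc_new, delta_auc = x$delta_auc,
         statistic = x$chi2, p.value = x$p)
}

#' @export
tidy.nri_result <- function(x, ...) {
  tibble(
    component = c("event", "nonevent", "total"),
    estimate = c(x$event, x$nonevent, x$total),
    std.error = c(x$event_se, x$nonevent_se, x$total_se),
    conf.low = c(x$event_ci[1], x$nonevent_ci[1], x$total_ci[1]),
    conf.high = c(x$event_ci[2], x$nonevent_ci[2], x$total_ci[2])
  )
}

#' @export
tidy.opera_result <- function(x, ...) {
  tibble(or = x$or, conf.low = x$ci_lo, conf.high = x$ci_hi,
         log_or = x$log_or, std.error = x$se, adj_sd = x$adj_sd)
}

#' @export
tidy.hl_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p)
}

#' @export
tidy.crosstab3 <- function(x, ...) {
  tidyr::expand_grid(trad_tertile = 1:3, prs_tertile = 1:3) |>
    mutate(count = as.vector(t(x$counts)),
           row_pct = as.vector(t(x$row_pct)))
}

#' @export
tidy.mel_selection <- function(x, ...) tidy(x$fit, ...)

#' @export
glance.mel_selection <- function(x, ...) {
  bind_cols(glance(x$fit), tibble(n_retained = length(x$retained),
                                  n_dropped = nrow(x$trace)))
}

#' @export
tidy.category_or_table <- function(x, ...) as_tibble(x)

#' Plot the incremental-value evaluation
#'
#' Side-by-side panels of the AUC change and the NRI components (with 95%
#' CIs) for every genetic score set added to the traditional base model.
#'
#' @param object A `mel_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mel_evaluation <- function(object, ...) {
  x <- as_tibble(object) |> filter(.data$model != "base_traditional")
  long <- bind_rows(
    tibble(model = x$model, metric = "AUC change", estimate = x$delta_auc,
           lo = NA_real_, hi = NA_real_),
    tibble(model = x$model, metric = "NRI (event)", estimate = x$nri_event,
           lo = x$nri_event_lo, hi = x$nri_event_hi),
    tibble(model = x$model, metric = "NRI (nonevent)", estimate = x$nri_nonevent,
           lo = x$nri_nonevent_lo, hi = x$nri_nonevent_hi),
    tibble(model = x$model, metric = "NRI (total)", estimate = x$nri_total,
           lo = x$nri_total_lo, hi = x$nri_total_hi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a tertile cross-tabulation as a shaded grid
#'
#' @param object A `crosstab3`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crosstab3 <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$prs_tertile),
                                  y = factor(.data$trad_tertile),
                                  fill = .data$row_pct)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d (%d%%)", .data$count, round_half_up(.data$row_pct)))) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", guide = "none") +
    ggplot2::labs(x = "polygenic risk tertile", y = "traditional risk tertile") +
    ggplot2::theme_minimal()
}

#' ROC curves for one or more prediction columns
#'
#' @param data A data frame.
#' @param truth Unquoted binary status column.
#' @param ... Unquoted prediction columns to draw, one curve each.
#' @return A ggplot object.
#' @export
plot_roc <- function(data, truth, ...) {
  y <- dplyr::pull(data, {{ truth }})
  check_binary(y)
  preds <- dplyr::select(as_tibble(data), ...)
  curves <- purrr::imap(preds, function(p, nm) {
    th <- sort(unique(p), decreasing = TRUE)
    tibble(
      model = nm,
      fpr = c(0, vapply(th, function(t) mean(p[y == 0] >= t), numeric(1))),
      tpr = c(0, vapply(th, function(t) mean(p[y == 1] >= t), numeric(1)))
    )
  }) |> bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, color = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, color = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
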