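spec0 <- model_spec(forced = character())   # unadjusted fits

test_that("logistic fit reproduces closed forms and the optimiser", {
  # intercept-only: everyone's fitted probability is the case fraction
  ch <- tibble::tibble(status = c(rep(1, 30), rep(0, 70)))
  fit <- fit_logistic(ch, spec0)
  expect_equal(unique(round(fit$fitted_prob, 12)), 0.3)

  # single binary exposure: odds ratio equals the 2x2 cross-product
  # (cases 317 vs 103, controls 135 vs 152 across the two exposure levels)
  ch2 <- tibble::tibble(
    status = c(rep(1, 317 + 103), rep(0, 135 + 152)),
    x = c(rep(1, 317), rep(0, 103), rep(1, 135), rep(0, 152))
  )
  fit2 <- fit_logistic(ch2, spec0, terms = "x")
  expect_equal(exp(fit2$coefficients[["x"]]), (317 * 152) / (103 * 135),
               tolerance = 1e-8)

  # matches a direct numerical maximisation of the log-likelihood
  withr::with_seed(8, {
    n <- 120
    d <- tibble::tibble(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    d$status <- rbinom(n, 1, plogis(-0.5 + 0.8 * d$x1 - 0.6 * d$x2))
  })
  fit3 <- fit_logistic(d, spec0, terms = c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  nll <- function(b) -sum(d$status * (X %*% b) - log1p(exp(X %*% b)))
  gr <- function(b) -drop(t(X) %*% (d$status - plogis(drop(X %*% b))))
  opt <- optim(c(0, 0, 0), nll, gr, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(unname(fit3$coefficients), opt$par, tolerance = 1e-6)

  # score equation: fitted probabilities average to the case fraction
  expect_equal(mean(fit3$fitted_prob), mean(d$status), tolerance = 1e-10)
})

test_that("an independent covariate leaves the exposure odds ratio unchanged", {
  withr::with_seed(21, {
    n <- 20000
    x <- rbinom(n, 1, 0.4)
    z <- rnorm(n)                       # independent of x
    y <- rbinom(n, 1, plogis(-1 + log(2) * x + 0.5 * z))
  })
  d <- tibble::tibble(status = y, x = x, z = z)
  crude <- fit_logistic(d, spec0, terms = "x")$coefficients[["x"]]
  adj <- fit_logistic(d, spec0, terms = c("x", "z"))$coefficients[["x"]]
  expect_lt(abs(adj - crude), 0.08)   # collapsible under independence (plus noise)
})

test_that("fit diagnostics catch missing data, separation and collinearity", {
  ch <- tibble::tibble(status = c(1, 0, 1, 0), x = c(1, 2, NA, 4))
  expect_error(fit_logistic(ch, spec0, terms = "x"), "complete cases",
               class = "melrisk_validation_error")

  sep <- tibble::tibble(status = c(rep(1, 20), rep(0, 20)),
                        x = c(rnorm(20, 5), rnorm(20, -5)))
  expect_error(fit_logistic(sep, spec0, terms = "x"),
               class = "melrisk_separation_error")

  withr::with_seed(3, dd <- tibble::tibble(status = rbinom(60, 1, 0.5),
                                           a = rnorm(60)))
  dd$b <- 2 * dd$a
  expect_error(fit_logistic(dd, spec0, terms = c("a", "b")),
               class = "melrisk_singular_error")

  # constant forced covariates (single-center study) are dropped, not fatal
  withr::with_seed(31, {
    d1 <- tibble::tibble(status = rbinom(200, 1, 0.4),
                         center = "leeds", age = runif(200, 20, 70))
  })
  fit <- fit_logistic(d1, model_spec(forced = c("age", "center")))
  expect_equal(fit$dropped, "center")
  expect_true("age" %in% names(fit$coefficients))
})

test_that("offset scores act as fixed-weight terms", {
  withr::with_seed(12, {
    n <- 800
    sc <- rnorm(n)
    d <- tibble::tibble(status = rbinom(n, 1, plogis(-0.3 + sc)),
                        score = sc, zero = 0)
  })
  base <- fit_logistic(d, spec0)
  with_zero <- fixed_weight_model(d, spec0, scores = "zero")
  expect_equal(with_zero$coefficients, base$coefficients, tolerance = 1e-10)

  with_score <- fixed_weight_model(d, spec0, scores = "score")
  expect_gt(with_score$loglik, base$loglik)

  # a refit on the true linear predictor has calibration slope ~ 1
  slope_fit <- fit_logistic(d, spec0, terms = "score")
  slope_se <- sqrt(diag(slope_fit$vcov))[["score"]]
  expect_lt(abs(slope_fit$coefficients[["score"]] - 1), 2.5 * slope_se)
  # refit mode estimates a free coefficient instead of pinning it at 1
  refit <- fixed_weight_model(d, spec0, scores = "score", refit = TRUE)
  expect_true("score" %in% names(refit$coefficients))
})

test_that("backward selection honours forced terms and the retention rule", {
  withr::with_seed(40, {
    n <- 2000
    d <- tibble::tibble(
      age = runif(n, 20, 70),
      sex = sample(c("female", "male"), n, TRUE),
      x_strong = rbinom(n, 1, 0.3),
      x_null1 = rnorm(n), x_null2 = rnorm(n),
      x_null3 = sample(c("u", "v", "w"), n, TRUE)
    )
    d$status <- rbinom(n, 1, plogis(-1 + log(3) * d$x_strong + 0.001 * d$age))
  })
  spec <- model_spec(forced = c("age", "sex"),
                     candidates = c("x_strong", "x_null1", "x_null2", "x_null3"))
  sel <- backward_select(d, spec)
  expect_true(all(c("age", "sex") %in% sel$fit$terms_used))
  expect_true("x_strong" %in% sel$retained)
  expect_true(all(sel$trace$p >= 0.20))

  # p_retain = 1 keeps the full model; p_retain = 0 strips all candidates
  expect_setequal(backward_select(d, spec, p_retain = 1.01)$retained,
                  spec$candidates)
  sel0 <- backward_select(d, spec, p_retain = 0)
  expect_length(sel0$retained, 0)
  expect_true(all(c("age", "sex") %in% sel0$fit$terms_used))

  # strong effect (OR 3) retained in nearly all replicates
  kept <- vapply(1:20, function(s) {
    withr::with_seed(400 + s, {
      dd <- tibble::tibble(age = runif(600, 20, 70),
                           x_strong = rbinom(600, 1, 0.3),
                           x_null = rnorm(600))
      dd$status <- rbinom(600, 1, plogis(-1 + log(3) * dd$x_strong))
    })
    "x_strong" %in% backward_select(
      dd, model_spec(forced = "age", candidates = c("x_strong", "x_null")))$retained
  }, logical(1))
  expect_gte(sum(kept), 19)
})

test_that("category odds ratios reproduce the cross-product and equal thirds", {
  # build a score whose tertiles reproduce printed tertile-1/tertile-3 counts
  n1_case <- 103; n1_ctrl <- 152; n3_case <- 317; n3_ctrl <- 135
  n2_case <- 158; n2_ctrl <- 170
  score <- c(rep(0, n1_case + n1_ctrl), rep(1, n2_case + n2_ctrl),
             rep(2, n3_case + n3_ctrl))
  y <- c(rep(1, n1_case), rep(0, n1_ctrl), rep(1, n2_case), rep(0, n2_ctrl),
         rep(1, n3_case), rep(0, n3_ctrl))
  d <- tibble::tibble(status = y, s = score)
  tab <- category_or(d, s, spec0, n_categories = 3, cutpoints = c(0.5, 1.5))
  expect_equal(tab$n_case, c(103, 158, 317))
  expect_equal(tab$or[1], 1)
  expect_equal(tab$or[3], (317 * 152) / (103 * 135), tolerance = 1e-8)
  expect_lt(attr(tab, "trend_p"), 1e-6)

  # distinct scores cut into exact thirds (1,035 participants)
  withr::with_seed(50, {
    d2 <- tibble::tibble(status = rbinom(1035, 1, 0.5), s = rnorm(1035))
  })
  t2 <- category_or(d2, s, spec0, n_categories = 3)
  expect_equal(t2$n_case + t2$n_control, rep(345, 3))

  # two categories at a threshold reproduce the dichotomised fit exactly
  d3 <- d
  d3$xbin <- as.integer(d3$s >= 1.5)
  t3 <- category_or(d3, s, spec0, n_categories = 2, cutpoints = 1.5)
  fit_bin <- fit_logistic(d3, spec0, terms = "xbin")
  expect_equal(log(t3$or[2]), fit_bin$coefficients[["xbin"]], tolerance = 1e-10)

  expect_error(category_or(tibble::tibble(status = rep(0:1, 5), s = rep(1, 10)),
                           s, spec0), class = "melrisk_degenerate_score")
})

test_that("stratified k-fold cross-validation corrects apparent optimism", {
  # partition contract: every participant tested exactly once
  withr::with_seed(60, {
    d <- tibble::tibble(status = rbinom(200, 1, 0.4), x = rnorm(200))
  })
  cv <- kfold_cv(d, model_spec(forced = character(), candidates = "x"),
                 k = 10, seed = 2)
  expect_equal(sort(cv$predictions$row), 1:200)
  expect_equal(dplyr::n_distinct(cv$predictions$fold), 10)
  folds_by_class <- table(cv$predictions$fold, cv$predictions$status)
  expect_true(all(folds_by_class[, 2] >= 1))

  # leave-one-out is seed-free
  small <- d[1:40, ]
  loo1 <- kfold_cv(small, model_spec(forced = character(), candidates = "x"),
                   k = 40, seed = 1)
  loo2 <- kfold_cv(small, model_spec(forced = character(), candidates = "x"),
                   k = 40, seed = 99)
  expect_equal(loo1$predictions$pred[order(loo1$predictions$row)],
               loo2$predictions$pred[order(loo2$predictions$row)])

  # 30 pure-noise predictors: apparent AUC inflated, CV AUC near 0.5
  withr::with_seed(61, {
    n <- 300
    noise <- as.data.frame(matrix(rnorm(n * 30), n))
    names(noise) <- paste0("v", 1:30)
    dn <- dplyr::bind_cols(tibble::tibble(status = rbinom(n, 1, 0.5)), noise)
  })
  cvn <- kfold_cv(dn, model_spec(forced = character(),
                                 candidates = paste0("v", 1:30)),
                  k = 10, seed = 3)
  expect_gt(cvn$train_auc$auc, 0.55)
  expect_lt(abs(cvn$cv_auc$auc - 0.5), 0.08)
})
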