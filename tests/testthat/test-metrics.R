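test_that("AUC equals the pair-enumeration oracle and handles edge cases", {
  d <- tibble::tibble(status = c(1, 1, 0, 0), p = c(0.9, 0.4, 0.4, 0.1))
  expect_equal(auc(d, status, p)$auc, 0.875)

  # perfect separation and all-ties
  expect_equal(auc_vec(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc_vec(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(auc_vec(1:4, rep(1, 4)), class = "melrisk_validation_error")

  withr::with_seed(70, {
    for (i in 1:50) {
      inst <- random_instance()
      expect_equal(auc_vec(inst$pred, inst$y)$auc, auc_oracle(inst$pred, inst$y))
    }
  })
})

test_that("AUC variance agrees with the reference correlated-ROC implementation", {
  withr::with_seed(71, {
    y <- rbinom(300, 1, 0.45)
    p <- plogis(rnorm(300) + y)
  })
  ours <- auc_vec(p, y)
  roc <- pROC::roc(y, p, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  expect_equal(ours$se^2, pROC::var(roc, method = "delong"), tolerance = 1e-12)
})

test_that("paired AUC comparison is rank-invariant and matches the bootstrap", {
  withr::with_seed(72, {
    y <- rbinom(200, 1, 0.5)
    base <- plogis(rnorm(200) + 0.8 * y)
    new <- plogis(base + rnorm(200, sd = 0.5) + 0.4 * y)
  })
  d <- tibble::tibble(status = y, base = base, new = new)

  same <- compare_auc(d, status, base, base)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p, 1)

  mono <- compare_auc_vec(base, qlogis(base), y)   # strictly monotone transform
  expect_equal(mono$delta_auc, 0)

  # paired test against pROC's DeLong implementation
  cmp <- compare_auc_vec(base, new, y)
  ref <- pROC::roc.test(pROC::roc(y, base, quiet = TRUE, direction = "<"),
                        pROC::roc(y, new, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(cmp$p, as.numeric(ref$p.value), tolerance = 1e-10)

  # variance of the AUC difference versus a 2,000-replicate bootstrap
  withr::with_seed(73, {
    boot <- vapply(1:2000, function(i) {
      idx <- sample.int(200, replace = TRUE)
      if (length(unique(y[idx])) < 2) return(NA_real_)
      auc_vec(new[idx], y[idx])$auc - auc_vec(base[idx], y[idx])$auc
    }, numeric(1))
  })
  expect_lt(abs(cmp$var_delta - var(boot, na.rm = TRUE)) / cmp$var_delta, 0.15)
})

test_that("paired AUC comparison p-value is uniform under the null", {
  pvals <- vapply(1:500, function(s) {
    withr::with_seed(7000 + s, {
      y <- c(rep(1, 50), rep(0, 50))
      a <- rnorm(100) + 0.5 * y   # two equally informative independent signals
      b <- rnorm(100) + 0.5 * y
    })
    compare_auc_vec(a, b, y)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("continuous NRI counts net movement with exact identities", {
  # hand enumeration: case deltas (+0.1, +0.2, -0.1); control deltas (-0.1, +0.05)
  y <- c(1, 1, 1, 0, 0)
  p0 <- c(0.5, 0.5, 0.5, 0.5, 0.5)
  p1 <- c(0.6, 0.7, 0.4, 0.4, 0.55)
  r <- continuous_nri_vec(p0, p1, y)
  expect_equal(r$event, 1 / 3)
  expect_equal(r$nonevent, 0)
  expect_equal(r$total, 1 / 3)

  same <- continuous_nri_vec(p0, p0, y)
  expect_equal(c(same$event, same$nonevent, same$total), c(0, 0, 0))

  withr::with_seed(80, {
    for (i in 1:50) {
      n <- sample(10:150, 1)
      yy <- c(1, 0, rbinom(n - 2, 1, 0.5))
      a <- runif(n); b <- runif(n)
      f <- continuous_nri_vec(a, b, yy)
      g <- continuous_nri_vec(b, a, yy)   # antisymmetry under model swap
      expect_equal(f$total, f$event + f$nonevent)
      expect_equal(c(g$event, g$nonevent, g$total),
                   -c(f$event, f$nonevent, f$total))
      expect_true(abs(f$event) <= 1 && abs(f$nonevent) <= 1 && abs(f$total) <= 2)
    }
  })
})

test_that("OPERA is scale-invariant and reduces to the control-SD odds ratio", {
  withr::with_seed(81, {
    n <- 2000
    d <- tibble::tibble(
      age = runif(n, 20, 70), sex = sample(c("female", "male"), n, TRUE),
      score = rnorm(n)
    )
    d$status <- rbinom(n, 1, plogis(-0.5 + 0.5 * d$score))
  })
  r1 <- opera(d, score)
  d2 <- dplyr::mutate(d, score = 7.3 * score)     # affine rescaling
  r2 <- opera(d2, score)
  expect_equal(r1$or, r2$or, tolerance = 1e-9)

  # with no covariates: OR per control-sample SD of the raw score
  r0 <- opera(d, score, covars = character(0))
  ctrl_sd <- sd(d$score[d$status == 0])
  ref <- glm(status ~ I(score / ctrl_sd), family = binomial(), data = d)
  expect_equal(r0$or, exp(coef(ref)[2]), ignore_attr = TRUE, tolerance = 1e-9)

  d$const <- 1
  expect_error(opera(d, const), class = "melrisk_degenerate_score")
})

test_that("Hosmer-Lemeshow matches hand arithmetic and is order-invariant", {
  # two groups of 50: (O, E) = (10, 8) and (20, 22)
  pred <- c(rep(8 / 50, 50), rep(22 / 50, 50))
  y <- c(rep(1, 10), rep(0, 40), rep(1, 20), rep(0, 30))
  r <- hosmer_lemeshow_vec(pred, y, g = 2)
  expect_equal(r$statistic, 4 / (8 * 0.84) + 4 / (22 * 0.56), tolerance = 1e-12)
  expect_true(is.na(r$p))    # g = 2 is a degenerate zero-df grouping

  # perfectly calibrated groups give statistic 0
  pred2 <- rep(c(0.1, 0.3, 0.5, 0.7), each = 10)
  y2 <- as.vector(vapply(c(1, 3, 5, 7), function(k) {
    c(rep(1, k), rep(0, 10 - k))
  }, numeric(10)))
  r2 <- hosmer_lemeshow_vec(pred2, y2, g = 4)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)

  withr::with_seed(82, idx <- sample.int(100))
  r3 <- hosmer_lemeshow_vec(pred[idx], y[idx], g = 2)
  expect_equal(r3$statistic, r$statistic)

  expect_error(hosmer_lemeshow_vec(runif(10), rep(0:1, 5), g = 10),
               class = "melrisk_config_error")
})
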