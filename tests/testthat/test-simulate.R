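test_that("genotypes follow Hardy-Weinberg proportions and are reproducible", {
  man <- tibble::tibble(snp_id = c("a", "b"), eaf = c(0, 0.3))
  d <- simulate_genotypes(10000, man, seed = 11)
  expect_true(all(d$dose_a == 0))                       # p = 0 forces zeros

  x <- d$dose_b
  expect_lt(abs(mean(x) - 0.6), 0.03)
  freqs <- tabulate(x + 1L, 3L) / length(x)
  hwe <- c(0.49, 0.42, 0.09)
  mc_se <- sqrt(hwe * (1 - hwe) / length(x))
  expect_true(all(abs(freqs - hwe) < 3 * mc_se))

  expect_identical(simulate_genotypes(500, man, seed = 7),
                   simulate_genotypes(500, man, seed = 7))
  man$eaf[1] <- NA
  expect_error(simulate_genotypes(10, man, seed = 1), "a",
               class = "melrisk_config_error")
})

test_that("phenotype generator honours the sex mix and null coupling", {
  man <- toy_manifest()
  d <- simulate_genotypes(10000, man, seed = 2)
  prof <- study_profile("p", 10, 10, c(18, 40), c(18, 45), prop_female = 0.60,
                        ancestry_distribution = c(british = 1))
  ph <- simulate_phenotypes(d, null_effects(), prof, seed = 3)
  expect_lt(abs(mean(ph$sex == "female") - 0.60), 0.02)
  expect_true(all(ph$age >= 18 & ph$age < 45))
  lv <- cohort_levels()
  for (v in c("hair_color", "freckling", "nevus_density", "vacation_sun_q")) {
    expect_true(all(ph[[v]] %in% c(lv[[v]], paste0("q", 1:4))))
  }
  # with zero coupling, phenotypes are independent of dosage on average
  pvals <- vapply(1:8, function(s) {
    dd <- simulate_genotypes(1500, man, seed = 100 + s)
    pp <- simulate_phenotypes(dd, null_effects(), prof, seed = 200 + s)
    suppressWarnings(stats::chisq.test(table(pp$hair_color, dd$dose_R151C))$p.value)
  }, numeric(1))
  expect_gt(mean(pvals), 0.2)
})

test_that("MC1R-phenotype coupling is recovered by a logistic refit", {
  man <- toy_manifest()
  eff <- true_effects(mc1r_coupling = list(red_hair = c(R151C = 1.0)))
  covered <- vapply(1:30, function(s) {
    d <- simulate_genotypes(5000, man, seed = 1000 + s)
    ph <- simulate_phenotypes(d, eff, test_profile(), seed = 2000 + s)
    fit <- glm((ph$hair_color == "red") ~ d$dose_R151C, family = binomial())
    ci <- coef(fit)[2] + c(-1.96, 1.96) * sqrt(diag(vcov(fit)))[2]
    ci[1] <= 1.0 && 1.0 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 25)   # nominal 95% coverage over 30 refits
  expect_error(
    simulate_phenotypes(simulate_genotypes(10, man, seed = 1),
                        true_effects(mc1r_coupling = list(red_hair = c(nope = 1))),
                        test_profile(), seed = 1),
    "nope", class = "melrisk_config_error")
})

test_that("case-control sampling preserves the per-allele odds ratio", {
  man <- toy_manifest()
  prof <- test_profile(200, 200, prevalence = 0.05)
  true_or <- 1.6
  eff <- true_effects(snp_log_or = c(rs1 = log(true_or)))
  covered <- vapply(1:30, function(s) {
    ch <- simulate_cohort(prof, man, eff, seed = 3000 + s, n_source = 12000)
    fit <- glm(status ~ dose_rs1, family = binomial(), data = ch)
    ci <- coef(fit)[2] + c(-1.96, 1.96) * sqrt(diag(vcov(fit)))[2]
    ci[1] <= log(true_or) && log(true_or) <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 25)

  # null model: refitted odds ratio CI covers 1 at the nominal rate
  covered0 <- vapply(1:30, function(s) {
    ch <- simulate_cohort(prof, man, null_effects(), seed = 5000 + s,
                          n_source = 12000)
    fit <- glm(status ~ dose_rs1, family = binomial(), data = ch)
    ci <- coef(fit)[2] + c(-1.96, 1.96) * sqrt(diag(vcov(fit)))[2]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered0), 25)
})

test_that("study profiles deliver their design quotas and age windows", {
  ch <- simulate_cohort(profile_australia(), toy_manifest(), seed = 9)
  expect_equal(sum(ch$status == 1), 578L)
  expect_equal(sum(ch$status == 0), 457L)
  expect_true(all(ch$age[ch$status == 1] < 40))
  expect_true(all(ch$age < 45))
  expect_equal(names(ch)[seq_along(melrisk:::cohort_base_columns())],
               melrisk:::cohort_base_columns())

  prof <- test_profile(5000, 5000, prevalence = 0.01)
  expect_error(simulate_cohort(prof, toy_manifest(), seed = 1, n_source = 5000),
               "larger source population", class = "melrisk_config_error")
})

test_that("generate_study is deterministic and honours the leeds profile", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- list(profile = list(
    name = "mini", n_cases = 60, n_controls = 60,
    age_range_cases = c(18, 60), age_range_controls = c(18, 60),
    prop_female = 0.5, ancestry_distribution = list(british = 1),
    center_distribution = list(a = 1), baseline_prevalence = 0.05
  ), n_source = 4000)
  generate_study(cfg, seed = 5, out_dir = dir1)
  generate_study(cfg, seed = 5, out_dir = dir2)
  expect_identical(readBin(file.path(dir1, "cohort.csv"), "raw", 1e7),
                   readBin(file.path(dir2, "cohort.csv"), "raw", 1e7))

  leeds <- generate_study(list(profile = "leeds"), seed = 3)$cohort
  expect_equal(sum(leeds$status == 1), 964L)
  expect_equal(sum(leeds$status == 0), 496L)
})
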