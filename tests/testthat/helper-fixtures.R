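# in-code fixtures shared across the suite

toy_manifest <- function() {
  tibble::tibble(
    snp_id = c("rs1", "rs2", "R151C"),
    gene = c("G1", "G2", "MC1R"),
    effect_allele = c("A", "A", "T"),
    eaf = c(0.5, 0.2, 0.1),
    or_overall = c(2.0, 1.5, 2.59),
    or_sun_sensitive = c(NA, NA, 2.5),
    or_not_sensitive = c(NA, NA, 1.5),
    is_mc1r = c(FALSE, FALSE, TRUE),
    pathways = list("pigmentation", "nevus", "pigmentation")
  )
}

# one participant at the reference level of every factor, replicated n times
reference_cohort <- function(n = 1) {
  lv <- cohort_levels()
  refs <- lapply(lv, function(x) rep(x[1], n))
  tibble::as_tibble(refs) |>
    dplyr::mutate(id = seq_len(n), status = 0L, age = 30, center = "c1",
                  .before = 1)
}

# small profile for fast simulation tests
test_profile <- function(n_cases = 150, n_controls = 150, prevalence = 0.05) {
  study_profile(
    name = "test", n_cases = n_cases, n_controls = n_controls,
    age_range_cases = c(18, 60), age_range_controls = c(18, 60),
    prop_female = 0.5,
    ancestry_distribution = c(british = 0.7, south_east_european = 0.3),
    center_distribution = c(a = 0.5, b = 0.5),
    baseline_prevalence = prevalence
  )
}

# O(n^2) pair-enumeration oracle for the AUC
auc_oracle <- function(pred, y) {
  cases <- pred[y == 1]; ctrls <- pred[y == 0]
  total <- 0
  for (x in cases) total <- total + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  total / (length(cases) * length(ctrls))
}

# random case-control prediction instance (with ties possible)
random_instance <- function(n_max = 200, ties = TRUE) {
  n <- sample(10:n_max, 1)
  y <- c(1, 0, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
  pred <- if (ties) sample(seq(0, 1, by = 0.05), n, replace = TRUE) else runif(n)
  list(pred = pred, y = y)
}
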