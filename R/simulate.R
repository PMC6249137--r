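#' Define a case-control study profile
#'
#' A study profile holds the design constants of a population-based
#' case-control study: quota of cases and controls, age eligibility windows,
#' sex mix, recruitment centers, ancestry mix and the baseline disease
#' prevalence used to anchor the simulated logistic disease model.
#'
#' @param name Profile label.
#' @param n_cases,n_controls Sampling quotas (> 0).
#' @param age_range_cases,age_range_controls Half-open eligibility intervals
#'   `[lo, hi)` in years.
#' @param prop_female Proportion female in `[0, 1]`.
#' @param ancestry_distribution Named proportions over ancestry categories
#'   (must sum to 1).
#' @param center_distribution Named proportions over recruitment centers.
#' @param baseline_prevalence Population disease prevalence in (0, 1) the
#'   simulated logistic intercept is solved against.
#' @return A `study_profile` list.
#' @export
study_profile <- function(name, n_cases, n_controls,
                          age_range_cases, age_range_controls,
                          prop_female = 0.5,
                          ancestry_distribution = c(british = 1),
                          center_distribution = c(center1 = 1),
                          baseline_prevalence = 0.01) {
  stopifnot(n_cases > 0, n_controls > 0,
            length(age_range_cases) == 2, length(age_range_controls) == 2)
  if (age_range_cases[1] >= age_range_cases[2] ||
      age_range_controls[1] >= age_range_controls[2]) {
    abort("age intervals must be non-empty", class = "melrisk_config_error")
  }
  if (prop_female < 0 || prop_female > 1) {
    abort("prop_female must lie in [0, 1]", class = "melrisk_config_error")
  }
  for (d in list(ancestry_distribution, center_distribution)) {
    if (is.null(names(d)) || abs(sum(d) - 1) > 1e-9 || any(d < 0)) {
      abort("category distributions must be named, non-negative and sum to 1",
            class = "melrisk_config_error")
    }
  }
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    abort("baseline_prevalence must lie in (0, 1)", class = "melrisk_config_error")
  }
  structure(list(
    name = name, n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    age_range_cases = as.numeric(age_range_cases),
    age_range_controls = as.numeric(age_range_controls),
    prop_female = prop_female,
    ancestry_distribution = ancestry_distribution,
    center_distribution = center_distribution,
    baseline_prevalence = baseline_prevalence
  ), class = "study_profile")
}

#' @export
print.study_profile <- function(x, ...) {
  cat(sprintf("<study_profile '%s'> %d cases / %d controls, %.0f%% female\n",
              x$name, x$n_cases, x$n_controls, 100 * x$prop_female))
  invisible(x)
}

#' Built-in study profiles
#'
#' `profile_australia()` emulates an early-onset multicenter study: 578 cases
#' and 457 controls, all cases diagnosed before age 40 and controls younger
#' than 45 at interview, 60% female, three recruitment centers, a mixed
#' European ancestry distribution. `profile_leeds()` emulates a single-center
#' study unrestricted by age: 964 cases and 496 controls aged 18-82, 60%
#' female, predominantly British ancestry.
#'
#' @return A [study_profile()].
#' @export
profile_australia <- function() {
  study_profile(
    name = "australia", n_cases = 578, n_controls = 457,
    age_range_cases = c(18, 40), age_range_controls = c(18, 45),
    prop_female = 0.60,
    ancestry_distribution = c(british = 0.68, north_european = 0.04,
                              south_east_european = 0.24, mixed_european = 0.04),
    center_distribution = c(sydney = 0.5, melbourne = 0.3, brisbane = 0.2),
    baseline_prevalence = 0.01
  )
}

#' @rdname profile_australia
#' @export
profile_leeds <- function() {
  study_profile(
    name = "leeds", n_cases = 964, n_controls = 496,
    age_range_cases = c(18, 82), age_range_controls = c(18, 82),
    prop_female = 0.60,
    ancestry_distribution = c(british = 0.977, north_european = 0.004,
                              south_east_european = 0.006, mixed_european = 0.013),
    center_distribution = c(leeds = 1),
    baseline_prevalence = 0.01
  )
}

#' Ground-truth effect sizes for the cohort generator
#'
#' @param snp_log_or Named numeric: per-allele log odds ratio on disease per
#'   SNP (absent SNPs default to 0).
#' @param pheno_log_or Named list of named numerics: per traditional factor, a
#'   log odds ratio per level (absent levels, including references, are 0).
#' @param mc1r_coupling Named list with optional elements `red_hair`,
#'   `freckling`, `photosensitivity`, each a named numeric of per-effect-allele
#'   log-odds increments to (respectively) the probability of red hair, of any
#'   freckling, and of usually/always burning, keyed by MC1R SNP id.
#' @return A `true_effects` list; `null_effects()` is the all-zero configuration.
#' @export
true_effects <- function(snp_log_or = numeric(), pheno_log_or = list(),
                         mc1r_coupling = list()) {
  ok_num <- function(x) is.numeric(x) && all(is.finite(x))
  if (!ok_num(snp_log_or) && length(snp_log_or) > 0) {
    abort("snp_log_or must be finite numeric", class = "melrisk_config_error")
  }
  if (length(pheno_log_or) > 0 && !all(vapply(pheno_log_or, ok_num, logical(1)))) {
    abort("pheno_log_or must contain finite numerics", class = "melrisk_config_error")
  }
  bad <- setdiff(names(mc1r_coupling), c("red_hair", "freckling", "photosensitivity"))
  if (length(bad) > 0) {
    abort(sprintf("unknown mc1r_coupling trait(s): %s", paste(bad, collapse = ", ")),
          class = "melrisk_config_error")
  }
  structure(list(snp_log_or = snp_log_or, pheno_log_or = pheno_log_or,
                 mc1r_coupling = mc1r_coupling),
            class = "true_effects")
}

#' @rdname true_effects
#' @export
null_effects <- function() true_effects()

#' Default ground-truth configuration for study-like simulations
#'
#' Builds a [true_effects()] object emulating a melanoma case-control study in
#' which the external weights are (attenuated) truth:
#' * per-allele SNP effects equal to `attenuation` times the manifest's log
#'   odds ratios — the attenuation (default 0.55) is chosen so that the
#'   polygenic score built from this manifest has an aggregate
#'   per-adjusted-SD odds ratio near 1.7, the magnitude reported for 40-50
#'   SNP melanoma scores in population-based case-control studies, rather
#'   than the stronger association the unattenuated weights would imply;
#' * phenotype effects equal to the traditional per-level weights, so the
#'   traditional risk score is a well-specified predictor;
#' * MC1R-phenotype coupling on the common red-hair-associated variants, so
#'   part of the genetic effect is mediated by the pigmentation phenotypes
#'   that the traditional model already measures.
#'
#' @param manifest Weights manifest supplying the SNP effects.
#' @param trad_weights Per-level traditional weights used as phenotype truth.
#' @param attenuation Multiplier on the manifest log odds ratios.
#' @return A [true_effects()] object.
#' @export
default_true_effects <- function(manifest = default_weights(),
                                 trad_weights = default_traditional_weights(),
                                 attenuation = 0.55) {
  pheno <- lapply(split(trad_weights, trad_weights$factor), function(w) {
    setNames(w$log_or, w$level)
  })
  coupling <- lapply(list(
    red_hair = c(R151C = 0.9, R160W = 0.7, D294H = 0.8),
    freckling = c(R151C = 0.6, V60L = 0.4),
    photosensitivity = c(V60L = 0.5, V92M = 0.4)
  ), function(cp) cp[names(cp) %in% manifest$snp_id])
  true_effects(
    snp_log_or = setNames(attenuation * log(manifest$or_overall),
                          manifest$snp_id),
    pheno_log_or = pheno,
    mc1r_coupling = coupling[lengths(coupling) > 0]
  )
}

#' Simulate genotype dosages in Hardy-Weinberg proportions
#'
#' Each dosage is drawn independently as the sum of two Bernoulli draws at the
#' SNP's effect-allele frequency, i.e. genotype classes occur with
#' probabilities \eqn{(q^2, 2pq, p^2)}. No linkage disequilibrium is
#' simulated.
#'
#' @param n Number of individuals.
#' @param manifest Weights manifest supplying `snp_id` and `eaf`.
#' @param seed Integer seed; identical seed gives an identical table.
#' @return Tibble of `dose_<snp_id>` columns with values in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(n, manifest, seed = 1) {
  check_cols(manifest, c("snp_id", "eaf"), where = "weights manifest")
  bad <- which(is.na(manifest$eaf) | manifest$eaf < 0 | manifest$eaf > 1)
  if (length(bad) > 0) {
    abort(sprintf("missing or invalid allele frequency for SNP(s): %s",
                  paste(manifest$snp_id[bad], collapse = ", ")),
          class = "melrisk_config_error")
  }
  withr::with_seed(seed, {
    D <- vapply(manifest$eaf, function(p) rbinom(n, 2L, p), integer(n))
  })
  D <- matrix(D, nrow = n)
  colnames(D) <- dose_col(manifest$snp_id)
  as_tibble(D)
}

# default marginal category frequencies for the phenotype generator;
# configurable placeholders for a fair-skinned European study population
default_phenotype_freqs <- function() {
  list(
    hair_color = c(dark = 0.45, light_brown = 0.30, fair_blonde = 0.20, red = 0.05),
    eye_color = c(brown_black = 0.30, green_hazel = 0.30, blue_grey = 0.40),
    skin_color = c(olive_dark = 0.20, medium = 0.45, fair = 0.35),
    freckling = c(none = 0.45, few = 0.30, some = 0.15, many = 0.10),
    photosensitivity = c(never_burn = 0.15, sometimes_burn = 0.45,
                         usually_burn = 0.25, always_burn = 0.15),
    nevus_density = c(none = 0.25, few = 0.40, some = 0.25, many = 0.10),
    sunbed_use = c(none = 0.70, s1_10 = 0.20, gt10 = 0.10),
    blistering_sunburn_child = c(none = 0.55, one_plus = 0.45),
    kc_history = c(no = 0.95, yes = 0.05),
    family_history = c(none = 0.90, one_plus = 0.10)
  )
}

# logistic shift of the probability of one "target" event, splitting the
# remaining mass over the other levels in their base proportions
shifted_category <- function(n, base, target_levels, other_levels,
                             base_target_p, shift) {
  p_target <- plogis(qlogis(base_target_p) + shift)
  u <- runif(n)
  is_target <- u < p_target
  out <- character(n)
  if (any(is_target)) {
    out[is_target] <- sample_levels(sum(is_target), base[target_levels])
  }
  if (any(!is_target)) {
    out[!is_target] <- sample_levels(sum(!is_target), base[other_levels])
  }
  out
}

sample_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs / sum(probs))
}

#' Simulate phenotypes with MC1R-coupled pigmentation traits
#'
#' Draws demographic covariates and traditional risk-factor phenotypes for
#' each row of a dosage table. Red hair, presence of freckling, and a
#' usually/always-burns photosensitivity response are coupled to MC1R
#' effect-allele dosage on the log-odds scale through
#' `effects$mc1r_coupling`: e.g. with coupling `c(R151C = 1)` on `red_hair`,
#' the log-odds of red hair increase by 1 per R151C allele, so a logistic
#' regression of red hair on R151C dosage recovers the coupling coefficient.
#' All other variables are drawn independently from `freqs`; vacation sun
#' exposure is a latent standard normal cut into quartiles.
#'
#' @param dosages Dosage table from [simulate_genotypes()].
#' @param effects A [true_effects()] object.
#' @param profile A [study_profile()].
#' @param seed Integer seed.
#' @param freqs Marginal category frequencies; see the package defaults.
#' @return Phenotype tibble (age, sex, center, ancestry and the traditional
#'   risk factors).
#' @export
simulate_phenotypes <- function(dosages, effects, profile, seed = 1,
                                freqs = default_phenotype_freqs()) {
  n <- nrow(dosages)
  coupling_snps <- unique(unlist(lapply(effects$mc1r_coupling, names))) %||% character(0)
  missing <- setdiff(dose_col(coupling_snps), names(dosages))
  if (length(missing) > 0) {
    abort(sprintf("mc1r_coupling references SNP(s) absent from the dosage table: %s",
                  paste(sub("^dose_", "", missing), collapse = ", ")),
          class = "melrisk_config_error")
  }
  coupling_shift <- function(trait) {
    cp <- effects$mc1r_coupling[[trait]]
    if (is.null(cp) || length(cp) == 0) return(rep(0, n))
    drop(as.matrix(dosages[dose_col(names(cp))]) %*% cp)
  }
  age_lo <- min(profile$age_range_cases[1], profile$age_range_controls[1])
  age_hi <- max(profile$age_range_cases[2], profile$age_range_controls[2])

  withr::with_seed(seed, {
    hair <- shifted_category(
      n, freqs$hair_color, "red",
      c("dark", "light_brown", "fair_blonde"),
      freqs$hair_color[["red"]], coupling_shift("red_hair")
    )
    freck <- shifted_category(
      n, freqs$freckling, c("few", "some", "many"), "none",
      sum(freqs$freckling[c("few", "some", "many")]), coupling_shift("freckling")
    )
    photo <- shifted_category(
      n, freqs$photosensitivity, c("usually_burn", "always_burn"),
      c("never_burn", "sometimes_burn"),
      sum(freqs$photosensitivity[c("usually_burn", "always_burn")]),
      coupling_shift("photosensitivity")
    )
    tibble(
      age = runif(n, age_lo, age_hi),
      sex = ifelse(runif(n) < profile$prop_female, "female", "male"),
      center = sample_levels(n, profile$center_distribution),
      ancestry = sample_levels(n, profile$ancestry_distribution),
      hair_color = hair,
      eye_color = sample_levels(n, freqs$eye_color),
      skin_color = sample_levels(n, freqs$skin_color),
      freckling = freck,
      photosensitivity = photo,
      nevus_density = sample_levels(n, freqs$nevus_density),
      sunbed_use = sample_levels(n, freqs$sunbed_use),
      blistering_sunburn_child = sample_levels(n, freqs$blistering_sunburn_child),
      vacation_sun_q = paste0("q", findInterval(
        rnorm(n), qnorm(c(0.25, 0.5, 0.75))) + 1L),
      kc_history = sample_levels(n, freqs$kc_history),
      family_history = sample_levels(n, freqs$family_history)
    )
  })
}

# solve the logistic intercept so that mean disease probability equals the
# target prevalence (bisection to 1e-8)
solve_intercept <- function(eta, prevalence, tol = 1e-8) {
  f <- function(a) mean(plogis(a + eta)) - prevalence
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    abort("cannot anchor intercept at the requested prevalence",
          class = "melrisk_numeric_error")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Sample a case-control cohort from a simulated source population
#'
#' Disease probability per individual follows a logistic model: intercept plus
#' additive per-allele SNP effects and per-level phenotype effects from
#' `effects`, with the intercept solved by bisection so that population
#' prevalence equals `profile$baseline_prevalence`. Disease status is drawn,
#' then exactly `n_cases` cases with age in the case eligibility window and
#' `n_controls` controls in the control window are sampled without
#' replacement. Because sampling depends only on outcome (and design age
#' windows), per-allele odds ratios in the sampled cohort remain unbiased.
#'
#' @param dosages,phenotypes Tables from the paired simulate calls (same rows).
#' @param effects A [true_effects()] object.
#' @param profile A [study_profile()].
#' @param seed Integer seed.
#' @return A cohort tibble (`id`, `status` with 1 = case, demographics,
#'   phenotypes, then `dose_*` columns) with attributes `intercept` and
#'   `linear_predictor` recording the generating model.
#' @export
simulate_outcome <- function(dosages, phenotypes, effects, profile, seed = 1) {
  stopifnot(nrow(dosages) == nrow(phenotypes))
  n <- nrow(dosages)
  eta <- numeric(n)
  if (length(effects$snp_log_or) > 0) {
    cols <- dose_col(names(effects$snp_log_or))
    check_cols(dosages, cols, where = "dosage table")
    eta <- eta + drop(as.matrix(dosages[cols]) %*% effects$snp_log_or)
  }
  for (f in names(effects$pheno_log_or)) {
    check_cols(phenotypes, f, where = "phenotype table")
    w <- effects$pheno_log_or[[f]]
    lev <- as.character(phenotypes[[f]])
    eta <- eta + ifelse(lev %in% names(w), unname(w[lev]), 0)
  }
  if (any(!is.finite(eta))) {
    abort("effects produce non-finite linear predictor", class = "melrisk_numeric_error")
  }
  alpha <- solve_intercept(eta, profile$baseline_prevalence)
  withr::with_seed(seed, {
    status <- rbinom(n, 1L, plogis(alpha + eta))
    in_case_win <- phenotypes$age >= profile$age_range_cases[1] &
      phenotypes$age < profile$age_range_cases[2]
    in_ctrl_win <- phenotypes$age >= profile$age_range_controls[1] &
      phenotypes$age < profile$age_range_controls[2]
    case_pool <- which(status == 1L & in_case_win)
    ctrl_pool <- which(status == 0L & in_ctrl_win)
    if (length(case_pool) < profile$n_cases || length(ctrl_pool) < profile$n_controls) {
      abort(sprintf(
        paste0("source population supplies %d eligible cases / %d controls but ",
               "the profile requests %d / %d; simulate a larger source population"),
        length(case_pool), length(ctrl_pool), profile$n_cases, profile$n_controls
      ), class = "melrisk_config_error")
    }
    keep <- c(sample(case_pool, profile$n_cases),
              sample(ctrl_pool, profile$n_controls))
  })
  cohort <- bind_cols(
    tibble(id = seq_along(keep), status = status[keep]),
    phenotypes[keep, , drop = FALSE],
    dosages[keep, , drop = FALSE]
  )
  cohort <- cohort[, c(cohort_base_columns(),
                       setdiff(names(cohort), cohort_base_columns()))]
  attr(cohort, "intercept") <- alpha
  attr(cohort, "linear_predictor") <- eta[keep]
  cohort
}

#' Simulate a complete case-control cohort in one call
#'
#' Convenience wrapper composing [simulate_genotypes()],
#' [simulate_phenotypes()] and [simulate_outcome()] on a source population of
#' `n_source` individuals.
#'
#' @inheritParams simulate_outcome
#' @param manifest Weights manifest (supplies SNP ids and allele frequencies).
#' @param n_source Source population size; must be large enough to meet the
#'   case/control quotas at the configured prevalence.
#' @param freqs Phenotype marginal frequencies.
#' @return Cohort tibble as from [simulate_outcome()].
#' @export
simulate_cohort <- function(profile, manifest,
                            effects = null_effects(), seed = 1,
                            n_source = 150000,
                            freqs = default_phenotype_freqs()) {
  dos <- simulate_genotypes(n_source, manifest, seed = seed)
  phe <- simulate_phenotypes(dos, effects, profile, seed = seed + 1L, freqs = freqs)
  simulate_outcome(dos, phe, effects, profile, seed = seed + 2L)
}

#' Generate a study from a configuration and write it to disk
#'
#' Reads a flat YAML configuration (or takes an equivalent list), simulates
#' the cohort, and writes `cohort.csv` plus a `truth.json` provenance sidecar
#' recording the seed, a hash of the resolved configuration, and the
#' ground-truth effects. Identical configuration and seed produce
#' byte-identical files.
#'
#' Recognised configuration keys: `profile` (`"australia"`, `"leeds"`, or a
#' list of [study_profile()] fields), `weights` (path to a manifest TSV, or
#' `"default"`), `n_source`, `seed`, and `effects` with optional sub-keys
#' `snp_log_or`, `pheno_log_or`, `mc1r_coupling`.
#'
#' @param config Path to a YAML file or a list.
#' @param seed Integer; overrides the seed in the config when given.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with `cohort`, `truth`, and output `paths`.
#' @export
generate_study <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "melrisk_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  profile <- resolve_profile(config$profile)
  manifest <- if (is.null(config$weights) || identical(config$weights, "default")) {
    default_weights()
  } else {
    read_weights_manifest(config$weights)
  }
  eff_cfg <- config$effects %||% list()
  effects <- true_effects(
    snp_log_or = unlist(eff_cfg$snp_log_or) %||% numeric(),
    pheno_log_or = lapply(eff_cfg$pheno_log_or %||% list(), unlist),
    mc1r_coupling = lapply(eff_cfg$mc1r_coupling %||% list(), unlist)
  )
  seed <- as.integer(seed %||% config$seed %||% 1L)
  n_source <- config$n_source %||% 150000
  cohort <- simulate_cohort(profile, manifest, effects, seed = seed,
                            n_source = n_source)
  truth <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    profile = unclass(profile),
    n_source = n_source,
    intercept = attr(cohort, "intercept"),
    effects = lapply(unclass(effects), function(x) {
      if (is.list(x)) lapply(x, as.list) else as.list(x)
    })
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(cohort = file.path(out_dir, "cohort.csv"),
                  truth = file.path(out_dir, "truth.json"))
    readr::write_csv(cohort, paths$cohort)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(cohort = cohort, truth = truth, paths = paths))
}

resolve_profile <- function(p) {
  if (inherits(p, "study_profile")) return(p)
  if (is.null(p) || identical(p, "australia")) return(profile_australia())
  if (identical(p, "leeds")) return(profile_leeds())
  if (is.list(p)) {
    p$ancestry_distribution <- unlist(p$ancestry_distribution)
    p$center_distribution <- unlist(p$center_distribution)
    return(do.call(study_profile, p))
  }
  abort(sprintf("unknown profile: %s", as.character(p)),
        class = "melrisk_config_error")
}

#' Read a cohort CSV written by [generate_study()]
#'
#' @param path Path to the cohort CSV.
#' @return Cohort tibble with `status` as integer and dosages as integers.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cohort file not found: %s", path), class = "melrisk_config_error")
  }
  cohort <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()))
  check_cols(cohort, cohort_base_columns(), where = "cohort CSV")
  cohort
}
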