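---
title: "Methods: polygenic and traditional melanoma risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic and traditional melanoma risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melrisk)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic cohort generator does
and does not emulate, and the numerical conventions adopted where the
methodology leaves genuine freedom.

## The scoring model

A polygenic risk score with *external* weights is a weighted dosage sum,

$$S_i = \sum_j (d_{ij} - c_j)\,\ln \mathrm{OR}_j,$$

with $d_{ij} \in [0, 2]$ the effect-allele dosage and $\mathrm{OR}_j$ a
per-allele odds ratio taken from a source outside the analysis data
(typically a meta-analysis of genome-wide association studies). Using
external weights is the primary design: estimating the weights in the same
data that the predictions are evaluated on overstates performance, and the
package treats internally refit weights (`fixed_weight_model(refit = TRUE)`,
`kfold_cv()`) as the secondary, cross-validated analysis.

**Centering** ($c_j = 2\,\mathrm{eaf}_j$, the dosage expected under
Hardy–Weinberg proportions) is on by default. It affects nothing rank-based —
tertiles, AUC, NRI, OPERA and concordance are provably invariant to it (this
is tested) — but it puts the score on an interpretable scale centered near
zero for an average-risk person, spanning negative and positive values the
way published score distributions do. The toggle exists because the choice
is cosmetic for inference but matters for reporting score ranges.

**MC1R stratification.** The association of *MC1R* variants with melanoma is
modified by pigmentation phenotype: relative risks are higher in people
*without* the sun-sensitive phenotype. The package therefore carries two
stratified odds ratios per *MC1R* variant and selects per participant: the
sun-sensitive OR when the participant has any of freckles (few/some/many),
red hair, or skin that usually/always burns, otherwise the non-sensitive OR.
*MC1R* rows are flagged explicitly in the manifest (`is_mc1r`) rather than
matched by gene symbol, so the stratification is a deliberate, visible
property of the weight set. When both stratified ORs equal the overall OR,
stratified and unstratified scoring coincide exactly (tested as an
invariant).

**Pathway scores** restrict the sum to the SNPs annotated to one biological
pathway. Assignments overlap (a gene can act through pigmentation and nevus
biology at once), so pathway SNP counts add to more than the total; the
shipped default manifest carries 45 SNPs in 21 genes with 31/13/9 SNPs in
the pigmentation / nevus / telomere-senescence-other pathways. The numeric
weights in that manifest are illustrative defaults — structurally valid,
plausible in magnitude, but not the published meta-analysis estimates, which
are supplementary material of the source studies and must be supplied by the
user for a real analysis. Placeholder rows are identified in the manifest
documentation.

The **traditional risk score** is the analogous linear predictor over
categorical risk-factor levels, $\sum_f \ln \mathrm{OR}_{f,\ell(i)}$, with
reference levels at zero. It is kept on the log-odds scale: the predicted
probability from the corresponding logistic model is a monotone transform,
so tertile assignment and every rank-based comparison are identical either
way.

## Model fitting

`fit_logistic()` is maximum-likelihood logistic regression (IRLS, through
`stats::glm`) wrapped with the diagnostics this design needs: missing values
are an error (the analyses are complete-case by construction, mirroring the
exclusion-based analytic datasets of such studies), collinear terms raise an
error naming them, and quasi-complete separation is detected by fitted
probabilities within $10^{-10}$ of the boundary and reported as an explicit
error rather than a silently divergent fit. Forced covariates that are
constant in a cohort — city of recruitment in a single-center study — are
dropped and recorded on the fit object instead of failing, since the same
model specification is meant to run on both study designs.

Fixed-weight scores enter as **offsets**: the coefficient is pinned at 1
while the intercept and demographic covariates (age, sex, center, ancestry —
ancestry as a self-reported categorical, included to limit confounding by
ethnicity) are refit freely. This was a genuinely open design point — the
alternative is refitting a free slope on the score — and the offset form was
chosen because it is the only one that actually *uses* the published weights
as weights; the free-slope form is available as `refit = TRUE` and is what
the cross-validated secondary analysis uses.

**Backward selection** (`backward_select()`) removes, at each step, the
candidate with the largest P-value at or above the retention threshold
(default `p_retain = 0.20`), never touching forced covariates, until all
remaining candidates fall below the threshold. P-values are likelihood-ratio
tests so that multi-level factors are tested jointly; ties break toward the
later-listed candidate. Whether the original procedure used Wald or LR tests
is not documented; LR was chosen because the joint test for factors is
otherwise ill-defined. The limiting behaviours are tested: `p_retain = 1`
keeps everything, `p_retain = 0` strips every candidate.

**Categorical odds ratios** (`category_or()`) cut a score at within-sample
quantiles (tertiles or deciles), enter indicators with the lowest category
as reference, and adjust for the forced covariates. The trend P is a Wald
test on the category index entered as a single ordinal term — the
conventional "P trend" — rather than on the continuous score; both
constructions are defensible and the ordinal one was chosen because it is a
statement about the categories actually reported. Cutpoints can be supplied
externally (`cutpoints =`) to categorise one study against pooled or
reference-sample quantiles; the default is within-sample, which reproduces
exact per-study thirds on distinct values.

**Quantile convention.** Categories are half-open intervals $[low, high)$
with boundary values assigned upward. On distinct values this yields equal
thirds (345/345/345 at $n = 1035$); published tables built with other
software show off-by-one splits (344/345/346), a pure convention difference.
For this reason all comparisons against published cross-tabulations are made
on the printed counts themselves, not on re-derived assignments.

## Evaluation metrics

**AUC** uses the Mann–Whitney estimator (ties count one half) with the
correlated-ROC placement-variance CI, and `compare_auc()` is the paired
version of the same construction: the variance of the AUC difference comes
from per-subject placement values of both models on the same sample and the
statistic $\Delta\mathrm{AUC}^2/\widehat{var}$ is referred to $\chi^2_1$.
One machinery serves both the single-model CI and the paired test, which is
why this variance estimator was chosen over binomial-style alternatives. The
implementation is checked three ways: exact equality with an exhaustive
pair-enumeration oracle, agreement with an independent reference
implementation (pROC), and agreement of the paired variance with a
2,000-replicate bootstrap.

**Continuous NRI** counts net movement: the event component is
$P(\uparrow\mid case) - P(\downarrow\mid case)$, the nonevent component the
mirror image among controls, and ties move neither way — the tie and CI
conventions follow the category-free NRI literature since the original
reports do not state them. Component CIs use the asymptotic
binomial-difference variance
$[p_\uparrow + p_\downarrow - (p_\uparrow - p_\downarrow)^2]/n$, and the
total CI treats the two components as independent (cases and controls are
disjoint samples). `total = event + nonevent` holds exactly, by
construction, and is asserted on every random instance in the tests.

**OPERA** answers "how strong is this risk factor per unit of its
population variation, net of covariates": regress the score on age and sex
*among controls*, take the SD of the residuals, and report the odds ratio
per one such SD from an adjusted logistic fit of the scaled score. Controls
(rather than the whole case-enriched sample) define the reference population
variation; a whole-sample option exists (`sd_sample = "all"`). The result is
invariant to affine rescaling of the score (tested).

**Hosmer–Lemeshow** uses equal-size groups of ranked predicted risk
(default $g = 10$), statistic
$\sum_g (O_g - E_g)^2 / [E_g(1 - E_g/n_g)]$, and $g - 2$ degrees of
freedom — the conventional choices, both configurable. Equal-size rather
than equal-width groups keeps expected counts away from zero in the skewed
risk distributions these models produce. With $g = 2$ the reference
distribution has zero degrees of freedom; the statistic is still returned
with `p = NA` and flagged as degenerate. The test's nominal type-I error
(rejection rate at $\alpha = 0.05$ within 0.03–0.07 under a correctly
specified model, 1,000 replicates of $n = 500$) is verified in the
acceptance suite.

## The synthetic cohort generator

The source studies deposit no individual-level data, so the generator exists
to make every downstream stage testable. It emulates:

- **Genotypes** in Hardy–Weinberg proportions at the manifest's allele
  frequencies, independent across SNPs.
- **Phenotypes** drawn from configurable marginal frequencies, with three
  pigmentation traits — red hair, presence of freckling, usually/always
  burning — coupled to *MC1R* dosage through per-allele log-odds increments,
  so that effect-modification machinery has something real to act on. The
  coupling is a logistic model in dosage, which is what makes the coupling
  coefficient recoverable by a logistic refit (tested at nominal CI
  coverage). Vacation sun exposure is a latent standard normal cut into
  quartiles.
- **Disease** from an additive-on-log-odds logistic model over SNP dosages
  and phenotype levels, with the intercept solved by bisection (tolerance
  $10^{-8}$) so population prevalence hits the profile's
  `baseline_prevalence` (default 0.01, a realistic cumulative melanoma
  risk scale for fair-skinned populations at the studied ages).
- **Ascertainment**: exact case/control quotas sampled without replacement
  within the profile's age windows — the Australia-like profile (578/457,
  60% female, three centers, mixed European ancestry) draws cases under 40
  and controls under 45, matching that study's early-onset design; the
  Leeds-like profile (964/496, one center, predominantly British ancestry)
  is age-unrestricted over 18–82. Because sampling depends only on outcome
  and design age windows, per-allele odds ratios are preserved in the
  sampled cohort (tested: refits on sampled cohorts are unbiased at nominal
  CI coverage).

`default_true_effects()` is the package's reference ground truth for
study-like simulations: per-allele effects equal to 0.55 times the
manifest's log odds ratios, phenotype effects equal to the example
traditional weights, and *MC1R*-phenotype coupling on the common red-hair
variants. The attenuation factor is the one substantive calibration: with
unattenuated weights the 45-SNP score would have an aggregate per-adjusted-SD
odds ratio near 3, far stronger than the 1.6–1.8 such scores show in real
case-control data; 0.55 places OPERA, the polygenic AUC (~0.68) and the
incremental AUC (~2–3 percentage points) in the empirically observed range.
A side effect worth knowing: because scoring uses the *unattenuated*
external weights while the generating truth is attenuated, fixed-weight
models are deliberately mis-scaled and the Hosmer–Lemeshow test often
rejects — the same overdispersion a real study sees when meta-analysis
weights overstate within-study effects.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, imputation dosage uncertainty, population stratification or family
structure, measurement error in self-reported phenotypes, and (by default)
missing data — an optional missingness switch is out of scope because the
analyses are complete-case. Phenotype marginal frequencies are configurable
placeholders, not estimates of any particular population. Passing tests on
these cohorts therefore demonstrate the *correctness of the machinery*
(estimators recover known truth; identities hold; designs are honoured),
not the real-data performance of melanoma risk models.

The directional pattern used as an end-to-end check — adding the polygenic
score to the traditional model raises the AUC and total NRI, with the
specificity (nonevent) component at least as large as the sensitivity
component — holds at the fixed test seed; the event/nonevent dominance
specifically is a modest asymmetry in real data and is seed-variable in the
generator, so only its fixed-seed realisation is asserted.

## Numerical choices and degenerate inputs

- Logistic fits: IRLS tolerance $10^{-10}$, 100 iterations maximum;
  separation threshold $10^{-10}$ on fitted probabilities.
- Intercept anchoring: bisection on $[-40, 40]$ to $10^{-8}$.
- Quantiles: type-7 sample quantiles; boundary values to the upper
  category; categories emptied by mass ties are an error naming the
  offending quantile, not a silent merge.
- OPERA declares a score degenerate when the adjusted SD is zero to within
  $10^{-8}$ relative tolerance.
- Tied predictions: AUC ties count one half; NRI ties count to neither
  direction; Hosmer–Lemeshow grouping sorts stably on (prediction,
  position) so group membership is deterministic.
- All randomness flows through explicit integer seeds
  (`withr::with_seed`), so identical seed and configuration give
  byte-identical outputs end to end, including written CSV/JSON.

## Problem sizes

The test suite and acceptance script are sized for quick, repeated runs:
simulated source populations of 5,000–200,000 with cohorts of a few hundred
to ~1,000 participants, 50-replicate coverage checks, 500-replicate identity
and uniformity sweeps, a 1,000-replicate calibration type-I-error study, and
a 2,000-replicate bootstrap cross-check of the paired AUC variance. These
sizes give Monte-Carlo error comfortably inside the asserted tolerances
while keeping the whole suite under half a minute.

## Known limitations

Allele harmonisation (strand flips, effect-allele mismatches against a
reference panel) is out of scope: dosages are assumed to already count the
manifest's effect allele. Non-integer imputed dosages are accepted in
$[0, 2]$ but not modelled further. Penalised regression, Firth correction,
categorical NRI, integrated discrimination improvement and decision-curve
analysis are deliberately not implemented. The between-study interaction
tests reported alongside such analyses are out of scope, as is any
absolute-risk (counselling-scale) output.
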