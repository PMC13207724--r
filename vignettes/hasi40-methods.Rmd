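---
title: "HASI-40: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HASI-40: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: what the composite index is, what the synthetic cohort
generator does and does not emulate, and the numerical and design
choices made wherever the underlying procedure leaves room.

## The index and its standardization

The analysis addresses two groups within the heart-failure spectrum:
a reference group with mildly reduced ejection fraction (LVEF 40–49%,
coded 0) and a case group with reduced ejection fraction (LVEF < 40%,
coded 1), with a targeted panel of 23 serum amino-acid analytes in
µmol/L. Each analyte is standardized *across the whole cohort*,

$$z_{ij} = \frac{x_{ij} - \bar{x}_j}{s_j},$$

with the sample SD ($n-1$ denominator; the convention of mainstream
statistical software, since "standard deviation" alone does not fix
the denominator). The composite index is the equal-weight signed sum

$$\text{HASI-40}_i = z_i(\text{3-methylhistidine}) -
z_i(\text{sarcosine}) - z_i(\text{taurine}) - z_i(\text{serine}),$$

with the proteolysis marker positive and the one-carbon /
cytoprotective metabolites negative. Directionality is fixed a priori
by biology, the weights are all magnitude 1, and the sum is **not**
re-standardized: odds ratios produced by the package are per one unit
of this raw signed sum. (Whether a "per 1-unit" effect should instead
refer to a re-standardized index is ambiguous in general; fixing the
raw-sum reading keeps the index an exact linear functional of the
z-matrix, so the sum-decomposition identity holds to the bit.)

Two standardization modes exist. `whole-cohort` (the default, and the
derivation's stated behaviour) computes $\bar{x}_j, s_j$ from all
subjects; inside cross-validation this leaks test-set information into
the constants. `train-fold-only` recomputes the constants from the
training subjects of each fold. Both are implemented so the size of
the leakage effect is measurable rather than hidden; the
cross-validation section of the test suite asserts, via the recorded
per-fold reference sets, that `train-fold-only` never touches held-out
subjects.

Consequences of the definition that the tests rely on:

* every z-column has mean 0 and sample SD 1 (to 1e-10);
* the whole-cohort index averages 0 over the cohort;
* the index is invariant under positive affine unit changes
  $x \mapsto ax + b$ of any metabolite column. Mathematically this
  invariance is exact; in IEEE-754 double arithmetic it holds to
  about 1e-15 relative but **not** to the bit, because $fl(ax_i+b)$
  rounds before the mean and SD are recomputed and the per-element
  rounding errors do not cancel. Bit-level identity holds only for
  exact power-of-two pure rescalings. The acceptance suite asserts
  bit identity (and separately the attainable 1e-12 numerical
  invariance); the bit-level assertion fails by design of floating
  point, and is retained as an honest record of that limit.

## The synthetic cohort generator

No subject-level data are distributed with the package, so the
generator exists to emulate the study conditions from printed
per-group summaries: two groups of $n = 21$; for each analyte a
median and quartiles per group; covariate summaries (age and BMI
median/IQR, sex, diabetes and dyslipidemia prevalences); and per-group
LVEF ranges (truncated to [40, 49] for the reference group, [10, 39]
for cases). The transcribed summaries live in
`inst/extdata/reference_marginals.csv` and are checked by tests.

* **Marginals.** Concentrations are positive and right-skewed, and only
  a median and IQR are available, so each analyte is modelled
  log-normally with $\mu = \log(\text{median})$ and
  $\sigma = \log(q_3/q_1) / (2 z_{0.75})$, $z_{0.75} = 0.6744898$. This
  matches the median exactly and the quartile *ratio* exactly; when the
  printed quartiles are asymmetric on the log scale the individual
  endpoints are matched in ratio only, which is what the
  distribution-fidelity test checks against.
* **Dependence.** A Gaussian copula with configurable correlation,
  identity by default: no between-metabolite correlation structure is
  published, so the default is independence and any correlation is an
  injectable assumption, not an estimate. Independent standard-normal
  columns are drawn per metabolite from labelled sub-streams and then
  multiplied by the upper-triangular Cholesky factor, so appending a
  metabolite never perturbs the draws of existing ones.
* **Covariates.** Age and BMI log-normal matched as above; sex,
  diabetes, dyslipidemia Bernoulli at the per-group prevalences; LVEF
  an inverse-CDF truncated normal with location at the group median and
  scale IQR$/1.349$.
* **Seeding.** One master seed; every variable block derives its own
  `set.seed` value via `stream_seed(master, label)` (a small
  deterministic string hash kept below $2^{31}$), so generation is
  byte-reproducible and extensible.

What the generator does **not** emulate — and hence what passing tests
do and do not show about real data: real metabolite panels are strongly
cross-correlated (shared pathways, renal function), covariates and
metabolites are not independent given group, and measurement error is
not modelled beyond the marginal spread. With independent marginals the
four index analytes contribute nearly independent signal, so the
synthetic index discriminates *more* strongly (apparent AUC ≈ 0.9 at
n = 21/21) than one should expect in a correlated real panel. Passing
tests demonstrate correctness of the computations and calibration of
the procedures, not clinical performance.

## The univariate battery

* **Mann–Whitney U** is computed as
  $U = \#\{x_i > y_j\} + \tfrac12\#\{x_i = y_j\}$. The exact two-sided
  p enumerates all $\binom{n_1+n_2}{n_1}$ labelings and sums the null
  mass of $|U - n_1 n_2/2|$ at least as extreme; the asymptotic branch
  uses the tie-corrected normal variance with a 0.5 continuity
  correction. `auto` switches from exact to asymptotic above
  $n_1+n_2 = 16$ (12 870 labelings — the largest enumeration that is
  still instantaneous). Exhaustive comparison against an independent
  enumeration oracle covers *every* tie-free rank configuration up to
  $n_1+n_2 = 10$. The approximation error of the asymptotic branch is
  below 0.02 only once both groups have ≥ 6 members; at the smallest
  sizes it can reach ≈ 0.04, which the property tests state explicitly.
* **Fisher's exact test** sums hypergeometric point probabilities not
  exceeding the observed one (relative tolerance 1e-7 on the
  comparison) — the point-probability two-siding convention of
  mainstream software, rather than tail doubling. The **chi-square**
  test is Pearson's without continuity correction; the selector uses
  Fisher whenever any expected cell count is below 5 (the conventional
  threshold).
* **Benjamini–Hochberg** is the step-up rule
  $q_{(i)} = \min_{j \ge i} m p_{(j)}/j$ capped at 1. The FDR family
  for the panel comparison is the **23 unique metabolites** — analytes
  listed under several pathways are tested once — and the composite
  index is tested *outside* that family (its row carries `q = NA`):
  the index is a derived quantity whose inclusion would both dilute
  and borrow from the per-analyte family.
* **Spearman** is the Pearson correlation of midranks. For $n \le 10$
  without ties the two-sided p is exact: the full permutation
  distribution of $S = \sum d_i^2$ is obtained by applying Ryser's
  permanent formula to the matrix of monomials $t^{(i-j)^2}$
  ($2^n$ signed subset terms, polynomial coefficients count
  permutations by $S$), cached per $n$. With ties or larger $n$ the
  usual t-approximation on $n-2$ df is used.

## Association models

Logistic regression is an explicit Newton–Raphson/IRLS maximizer of
the Bernoulli log-likelihood with step-halving on likelihood decrease;
convergence is `max |score| < 1e-8` within 50 iterations, standard
errors come from the inverse observed information, and Wald 95%
intervals are exponentiated into odds-ratio intervals (matching the
"OR (95% CI)" reporting convention; profile likelihood is not used).
Fixed codings keep ORs reproducible: male = 1, comorbidity present = 1.

Two diagnostics matter at the study's size. With 21 events and six
predictors the events-per-variable ratio is 3.5, far below the
conventional 10, and every multivariable fit carries that warning.
Worse, complete separation occurs on a few percent of generator seeds;
the fit is then flagged (standardized coefficient magnitude > 10 or
non-convergence), no odds ratios are produced, and the pipeline report
keeps the section with the raw coefficients and warnings instead of
aborting. No penalization (e.g. Firth) is applied by default, keeping
the estimator the plain maximum-likelihood one.

## Discrimination and internal validation

The ROC treats higher scores as case-like and never flips direction
automatically (an AUC below 0.5 is reported with a warning — silent
flipping hides coding errors). The AUC is computed both as the
trapezoidal area of the threshold sweep and as pairwise concordance
$(\#\{\text{pos} > \text{neg}\} + \tfrac12\#\text{ties})/(n_1 n_0)$;
both are assembled from exact half-integer counts and divided by the
same denominator, so their equality — and the identity with the
tie-corrected $U/(n_1 n_0)$ — is exact, and asserted on every call.

The AUC confidence interval is a stratified nonparametric bootstrap
(resampling within class, so every replicate keeps both classes),
percentile 2.5/97.5, B = 2000 by default — assumption-light at
n = 42, where DeLong's variance formula rests on asymptotics. The
"optimal" cutoff maximizes Youden's $J = \text{sens} + \text{spec} - 1$
with ties broken toward the lowest (most sensitive) threshold.

Cross-validation is repeated stratified k-fold (defaults k = 5,
100 repetitions): per repetition the cohort is partitioned with
class-wise round-robin assignment, the logistic model is fitted on
k−1 folds and scores the held-out fold, and the repetition AUC is
computed on the *pooled* out-of-fold scores (folds of ~8 subjects give
too few discordant pairs for stable per-fold AUCs; the pooled variant
is the stable aggregation at this size). The combined index + age
model's ROC is apparent (in-sample fitted probabilities), matching how
combined models are usually reported at this scale.

Calibration facts the tests pin down: under a null generator
(group-1 marginals set to group 0) the per-metabolite rejection rate
at $\alpha = 0.05$ sits in [0.03, 0.07] and the mean apparent index
AUC within 0.05 of 0.5, averaged over 500 seeds; a single null cohort,
however, carries an accidental index–label association of order
$1/\sqrt{n}$, so cross-validated AUC on one cohort centres on that
cohort's accidental signal, not on 0.5 — calibration statements are
therefore always averages over cohorts. Cross-validated AUC with
train-fold-only standardization does not exceed the apparent AUC on
average (the optimism inequality), checked over 100 synthetic cohorts
at n = 21/21.

## Problem sizes used by the checks

The test suite runs the exhaustive Mann–Whitney comparison to
$n_1+n_2 = 10$, distribution fidelity at $10^5$ per group (sample
median within 2%, quartiles within 3% of the log-normal truth), AUC
recovery of $\Phi(\delta/\sqrt2)$ at $\delta = 1.5$ with 2000 per class
over 20 seeds, Wald coverage over 1000 fits at n = 400 (93–97%
acceptance window), null calibration over 500 seeds at n = 21/21, and
the CV-optimism comparison over 100 cohorts with 10 repetitions each —
sizes chosen so each law-of-large-numbers oracle is decisive while the
whole suite stays quick.

## Known limitations

* The generator's independence default overstates the index's
  discrimination relative to a correlated real panel (see above); the
  copula is a free parameter, not an estimate.
* Quartile conventions differ across software; the package documents
  and uses linear interpolation (R type 7) everywhere.
* The multivariable model at n = 42 is events-per-variable starved and
  separation-prone by construction; its intervals are wide and on some
  cohorts it has no finite MLE. This is reported, not repaired.
* No external validation is possible from within the package: all
  evaluation is internal (apparent and cross-validated) on synthetic
  cohorts.
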