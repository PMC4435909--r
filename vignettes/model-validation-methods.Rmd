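---
title: "Methods: external validation of prevalent diabetes risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: external validation of prevalent diabetes risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevalid)
```

This vignette documents the statistical methods, the tunable parameters,
the numerical conventions and the deliberate design choices behind
`prevalid`: what is computed, and why each open choice was resolved the
way it was. The empirical behaviours quoted here (moment recovery,
recalibration bands, oracle agreement) are exactly the properties the
test suite computes; nothing beyond what the code verifies is claimed.

## The validation problem

A risk prediction model for *prevalent undiagnosed diabetes* maps
non-invasive predictors (age, sex, BMI, waist circumference, treatment
and family history, blood pressure, smoking) to a probability that an
oral glucose tolerance test would classify the participant as diabetic
under the WHO criteria — fasting plasma glucose ≥ 7.0 mmol/L and/or
2-hour glucose ≥ 11.1 mmol/L, both thresholds inclusive. External
validation evaluates a model *as published* on a cohort it was not
developed on. Two properties are measured separately, because they fail
independently under case-mix shift:

* **Discrimination** — ranking: do cases receive higher predicted risks
  than non-cases? Summarised by the concordance statistic.
* **Calibration** — absolute accuracy: does a predicted 20 % risk
  correspond to a 20 % observed frequency? Summarised by the E/O ratio
  and calibration curves.

## Model representation

Models are data files, not code: validation studies routinely transcribe
equations from publications, and transcription errors should be fixable
by editing a file. Each YAML spec declares an intercept on the logit
scale and predictor terms with one of three transforms: `identity`
(coefficient × value), `categorical` (a per-level contribution map,
which also encodes sex codings that differ between source models — a
classic source of silent validation bugs) and `binned`
(strictly increasing cut-points, one value per left-closed bin, for
point-score age/BMI bands). Integer point scores carry an additional
`score_to_lp` pair mapping the summed score onto the logit scale, so
that *every* model yields a probability through the same logistic link
— a requirement for intercept adjustment and E/O to be meaningful.

The five bundled files mirror the predictor structure of well-known
scores (Cambridge, Kuwaiti, Omani, Rotterdam, simplified Finnish), but
their numeric coefficients are **synthetic stand-ins**, flagged in the
filename and in a `synthetic_coefficients` field: the package does not
redistribute published equations, and an analysis of real data must
replace them with transcribed values. Units are fixed at load time
(years, kg/m², cm, mmHg, mmol/L); no automatic conversion is attempted.

## Eligibility and the analysis set

The cascade has a fixed stage order. Stage 1 removes participants with a
previously diagnosed diabetes (the outcome "undiagnosed diabetes" is
undefined for them). Stage 2 removes records with a missing outcome or a
missing value on any required predictor. One *common* analysis set is
built over the union of all validated models' predictors, rather than a
per-model complete-case set, so that model comparisons are paired on
identical subjects; a per-model mode would change n per model and break
the paired DeLong test.

Two conventions deserve note. A participant with one missing glucose
value and the other below threshold is *indeterminate* — diabetes cannot
be ruled out from a single normal measurement — and is treated as a
missing outcome (excluded at stage 2). A recorded BMI takes precedence
over the value derivable from height and weight; derivation fills gaps
only.

Subgroups follow the pre-specified axes: sex, age (<60 vs ≥60 years) and
BMI (<25 vs ≥25 kg/m²), with boundary values in the upper band.

## The performance block

For predictions $p_i$ and outcomes $y_i \in \{0,1\}$, $i = 1..n$:

**C-statistic.** $\hat c = \frac{\#\{\text{concordant}\} + \tfrac12
\#\{\text{tied}\}}{\#\{\text{case, non-case pairs}\}}$, computed via
midranks in $O(n \log n)$. The confidence interval uses the DeLong
structural-component variance; the same components give the paired test
for two models evaluated on identical subjects. A pairwise comparison
matrix with unadjusted p-values is emitted, plus a Bonferroni column
clearly labelled as a multiplicity extension. A paired-bootstrap
comparison (`method = "bootstrap"`) is available as a finite-sample
cross-check. The suite verifies the midrank implementation against an
$O(n^2)$ brute-force enumeration and against `pROC`.

**E/O ratio.** $E = \sum p_i$, $O = \sum y_i$, interval
$\mathrm{E/O}\cdot\exp(\pm z_{0.975}/\sqrt{O})$ on the log scale,
treating $O$ as Poisson. This is one of several "Poisson" dialects in
the literature; it is symmetric on the log scale (not in absolute
terms), strictly positive, and reduces sensibly at small $O$. The ratio
is also reported as signed over/underestimation percent,
$(\mathrm{E/O}-1)\cdot 100$ or $(1-\mathrm{E/O})\cdot 100$, with the
interval mapped by the same affine function.

**Brier score and Yates slope.** $\tfrac1n\sum (p_i-y_i)^2$ and
$\bar p_{y=1} - \bar p_{y=0}$. For a constant predictor at the event
rate the Brier score equals $\text{prev}(1-\text{prev})$, a useful
closed-form test anchor.

**Calibration curves.** Participants are ranked on predicted risk and
cut into `n_bins` equal-occupancy bins (deciles by default — "risk
percentile" grouping is ambiguous, and deciles are the common reading);
tied predictions never straddle a bin boundary, so a degenerate constant
predictor collapses to a single bin rather than fabricating spread. Each
bin reports mean predicted risk, observed rate and count; the sorted
predictions are returned as rug data for the frequency strip of a
calibration plot. The package exports plot *data*, not rendered figures.

**Threshold analysis.** The operating threshold maximises Youden's
$J = \text{sens} + \text{spec} - 1$ over all distinct predicted values,
with the classification rule *positive iff $p \ge t$* (the boundary
inclusive; published descriptions are typically silent on this, so the
convention is stated here and in the docs). Ties in $J$ resolve to the
lower threshold, i.e. the higher-sensitivity operating point —
defensible for a screening context where a missed case costs more than
a false positive. Sensitivity, specificity and correctly classified are
reported in percent; the accounting identity
$\text{correct} = \text{sens}\cdot\text{prev} +
\text{spec}\cdot(1-\text{prev})$ is exposed as a helper and verified at
every threshold in the tests.

**Display rounding.** Ratios and C to two decimals, Brier and Yates to
three, percentages to whole numbers; all internal values keep full
precision. Undefined cells (e.g. a zero-event subgroup) render as an
em-dash rather than a number, and the run continues.

## Recalibration-in-the-large

The correction factor is
$\delta = \ln\frac{\text{prev}/(1-\text{prev})}{\bar p/(1-\bar p)}$,
added to every linear predictor (for point scores, to the score-to-logit
intercept, so it acts on the logit scale). Because the shift is monotone,
the ranking — and hence the C-statistic, bit for bit — is unchanged;
the pipeline surfaces this invariance as a consistency check. One-shot
adjustment follows the published formula and does *not* exactly equalise
$\bar p$ and prevalence (the logistic is nonlinear); an iterated variant
exists behind `iterate = TRUE` and converges to
$|\bar p - \text{prev}| < 10^{-8}$ within a few steps, used as a
numerical cross-check only. The adjustment is fitted and evaluated on
the same data (in-sample, as is usual for this sensitivity analysis) and
the optimal threshold is re-estimated on the adjusted probabilities,
which is why original and adjusted thresholds differ in reports.

## Multiple imputation sensitivity stage

Complete-case validation can bias performance estimates when missingness
is informative. The sensitivity stage imputes the pre-exclusion roster
(stage-1 survivors) with chained equations: continuous variables by
normal linear models (residual variance drawn from its scaled inverse
chi-square, coefficients from their normal posterior, then a stochastic
draw per cell), binary variables by logistic models with
asymptotic-normal coefficient draws; 10 cycles, m = 5 completed
datasets, all reproducible from one seed. The outcome's glucose
measurements participate in the imputation model, and records whose
*outcome* was imputed are retained. Degenerate conditional fits
(separation in a sparse binary) fall back to marginal draws for that
cycle. Observed cells are never altered — the suite checks bitwise
equality — and with no missing data the stage reduces exactly to the
main analysis. Per-dataset C-statistics are pooled by their mean with
the min–max spread; no Rubin-rules variance pooling is attempted, since
the question asked is point-level stability, not pooled inference.

## The synthetic cohort generator

The generator emulates a community OGTT screening sample: n = 1256
invited, 78.7 % female, a prior-diagnosis fraction of 173/1256,
per-variable missingness tuned so roughly 32 % of undiagnosed records
fail complete-case filtering, and a screen-detected prevalence of 17.6 %
among the undiagnosed. Its defaults *are* the study conditions; they are
not adjusted per analysis.

**Covariates.** Continuous variables use per-sex marginals coupled by a
Gaussian copula. Age, BMI, waist, blood pressures and height are normal,
clamped to wide physiological ranges (e.g. age 15–95; the clamp
tail mass is well below half a Monte-Carlo standard error of the mean at
n = 10⁵, verified in the suite). Weight, HDL and triglycerides are
lognormal with moment-matched parameters (strictly positive,
right-skewed, no truncation bias). The rank-correlation matrix
(BMI–waist 0.8, SBP–DBP 0.7, age–SBP 0.35, BMI–weight 0.8, …) is a
design constant: published cohort profiles report marginals only, so
these values are field-plausible, configurable and explicitly *not*
data-derived. Binary covariates are thresholded latent normals with
exact per-sex prevalences; the four family-history indicators share a
family frailty (ρ = 0.5), and antihypertensive treatment correlates with
the systolic latent (ρ = 0.5).

**Outcome.** A latent diabetes liability
$s = (0.35\,Z_\text{age} + 0.50\,Z_\text{BMI} + 0.30\,Z_\text{waist} +
0.30\,Z_\text{family})/\text{sd}$ drives two glucose mixtures, and the
outcome label is produced by actually running the WHO classification on
the generated glucose values — the classifier is exercised on the
synthetic path, not bypassed with a Bernoulli label:

* *Fasting glucose* is a two-component lognormal mixture. The
  elevated-glycaemia component has fixed per-sex parameters
  (male 7.4 ± 1.6, female 8.5 ± 2.5 mmol/L) and a fixed per-sex
  membership probability (0.14 / 0.20) whose latent is correlated with
  $s$ (ρ = 0.75); the normoglycaemic component is then solved in closed
  form so the overall per-sex mean and SD equal the configured targets
  (5.4 ± 1.4 / 5.7 ± 2.0) *exactly*, for any outcome intercept.
* *2-h glucose* is a second mixture (normo 5.6 ± 1.5, elevated
  13.5 ± 3.5 mmol/L) whose membership follows a logistic model on $s$
  and the fasting-elevation flag. Its intercept is the calibration dial.

This separation is deliberate. A single latent intercept acting on the
fasting-glucose mixture weight cannot work: a normal or lognormal
fasting marginal with the female targets (mean 5.7, SD 2.0) already
places over 20 % of women above 7.0 mmol/L — more than the entire
target prevalence — and letting the mixture weight rebalance the
marginal makes prevalence *non-monotone* in the intercept, defeating
bisection. Fixing the fasting mixture and steering prevalence through
the 2-h channel keeps the marginal moments matched in closed form and
makes prevalence strictly monotone in the dial (in expectation, and
pathwise under common random numbers up to a negligible set), so
calibration is a clean bisection.

**Calibration.** `calibrate_outcome_intercept()` draws one fixed
calibration sample (n = 10⁵, fixed internal seed), bisects the intercept
on common random numbers until the bracket collapses, and errors if the
achieved prevalence misses the target by more than `tol` (default
0.005) or the bracket does not straddle the target. A zero tolerance is
rejected outright — a finite empirical sample cannot guarantee it.

**What the generator does not emulate.** Only printed marginals,
pairwise design correlations and the prevalence target are controlled;
the true cohort's joint distribution, its exact missingness mechanism,
and the published models' achieved performance values (C ≈ 0.64–0.68)
are not targets. Passing tests on synthetic cohorts therefore validate
the *pipeline's* correctness and statistical behaviour, not any claim
about how a particular published score performs on real data.

## Problem sizes and determinism

The test suite exercises: oracle equivalence of the concordance and
Youden scans on 1000 random instances (n ≤ 200) against brute-force
enumeration; recalibration of an engineered severely underestimating
model (E/O ≈ 0.26-scale shift δ = 1.4929 at n = 737) across 20 seeds;
generator moment recovery and prevalence calibration at n = 10⁵ (every
configured per-sex mean/SD within 3 Monte-Carlo SEs); and imputation
stability (pooled C within 0.02 of the complete-data C under 15 % MCAR
on two predictors at n = 1256). Every stochastic step — generation,
calibration, missingness, imputation, bootstrap — is reproducible from
explicit integer seeds, and identical inputs yield byte-identical
serialised reports.

## Known limitations

* Bundled coefficients are synthetic; conclusions about named published
  scores require transcribing the real equations into the spec files.
* The E/O interval is one defensible Poisson dialect; others (exact
  Poisson, delta-method on the ratio) give different tails at small O.
* One-shot intercept adjustment is in-sample; the adjusted E/O inherits
  the optimism of being fitted and evaluated on the same records.
* The imputation engine is a minimal chained-equations implementation
  (normal/logistic draws, no predictive mean matching, no interactions);
  it is adequate for MCAR/MAR sensitivity checks, not for MNAR.
* HbA1c and random-glucose diagnostic pathways, net-reclassification and
  decision-curve analyses are out of scope.
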