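---
title: "Latent profiles of cardiovascular risk: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent profiles of cardiovascular risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvlpa)
```

## The scientific problem

Global cardiovascular (CV) risk scores compress many continuous markers
into one number and hide the heterogeneity of pre-clinical risk. An
alternative is to let the joint distribution of the markers speak: model a
cohort as a finite mixture of latent subpopulations ("profiles" or
"classes") over seven continuous vascular-risk indicators — body-mass
index (kg/m²), carotid intima-media thickness (mm), LDL-C, HDL-C,
triglycerides and fasting glucose (mg/dL), and the integer Framingham
point score — and then ask whether the recovered classes relate to
demographics, genetics (APOE ε4), and cognitive performance in recently
menopausal women. `cvlpa` implements that full analysis and a calibrated
synthetic-cohort generator so every stage is testable without access to
any restricted cohort data.

## The latent profile model

For subject $i$ with indicator vector $y_i \in \mathbb{R}^7$ (z-scored on
the analysis sample), the $K$-class Gaussian latent profile model assumes

$$f(y_i) = \sum_{k=1}^K \pi_k \prod_{j \in \mathrm{obs}(i)}
  N(y_{ij};\, \mu_{jk}, \sigma^2_{jk}),$$

i.e. *local independence*: indicators are independent given class, so all
marginal association is attributed to class mixing. Missing cells simply
drop out of the product — this is full-information maximum likelihood and
is valid under missing-at-random. Estimation is EM (`fit_lpa()`):
posterior membership probabilities in the E-step, weighted means,
variances and mixing weights in the M-step, implemented in compiled code.

Numerical choices:

* **Starts.** 50 random initializations (class means drawn from random
  subjects, pooled variances), 20 burn-in EM iterations each, the best 5
  continued to convergence. Absolute log-likelihood gain below `1e-7`
  declares convergence; the iteration cap is 2000.
* **Variance structure.** The default is one residual variance per
  indicator shared across classes (`variance = "invariant"`), the common
  default of latent-profile software; `"varying"` frees a diagonal per
  class. The reported parameter counts of the original analysis are
  internally inconsistent across class counts, so the package prints its
  own count (`q`) transparently rather than forcing agreement.
* **Degenerate fits.** A component whose weight falls below $10^{-6}$
  marks the run as collapsed; the fit restarts from fresh initializations
  with a warning. Reported log-likelihoods are recomputed at the returned
  parameters, so monotonicity checks are exact.
* **Label switching.** Classes are always reordered so class 1 has the
  higher HDL-C mean (the "low-risk" profile); exact ties fall back to
  ascending triglycerides. All consumers (posteriors, odds ratios, distal
  tests) see the ordered labels.

`relative_entropy()` summarizes classification quality as
$1 - \sum_{ik} (-p_{ik}\ln p_{ik}) / (n \ln K)$; `bic()` is
$-2\ell + q\ln n$.

## How many classes? The bootstrap LRT

The classical comparison of $K-1$ vs $K$ classes has no usable analytic
null; the package uses the parametric bootstrap likelihood-ratio test
(`bootstrap_lrt()`): simulate `B` datasets from the fitted $(K-1)$-class
model (same $n$, same missingness mask), refit both models to each, and
report $p = (1 + \#\{LR_b \ge LR\})/(B+1)$. Each $K$-class fit includes a
start nested in the $(K-1)$-class solution (one component duplicated, its
weight split), which guarantees $LR \ge 0$.

`enumerate_classes()` walks upward from $K=1$ and accepts a richer
solution only if (a) its bootstrap LRT is significant, (b) every class
retains at least 5% of the sample, and (c) relative entropy does not fall
by more than `entropy_drop` (default 0.1) — the quantitative form of the
"classification quality must stay acceptable" criterion that applied
analyses use when they keep a smaller model despite a marginally
significant test. The full table is returned so the user can override the
selection on interpretability grounds.

A consequence worth knowing: on *fully calibrated* synthetic cohorts
(within-class correlations on, see below) the 3-vs-2 test is genuinely
significant and BIC slightly favors 3 classes, because a third component
helps absorb the residual within-class structure that local independence
ignores. The same thing happened in the motivating analysis, which kept
2 classes because the 3-class solution classified much more poorly. When
the generator is switched to local independence and the fitted family
contains the truth (class-varying variances), enumeration recovers
exactly 2 classes.

## Concomitant covariates

`fit_conditional()` replaces the shared mixing weight by a
subject-specific logistic prior for high-risk membership,
$\pi_i(\mathrm{high}) = \mathrm{logit}^{-1}(\gamma_0 + \gamma'x_i)$, with
covariates age (years), education (college degree or higher), ethnicity
(non-Hispanic Black and Hispanic vs the non-Hispanic White reference), and
APOE ε4 carriage. The M-step for $\gamma$ is a Newton-iterated weighted
logistic regression with the posteriors as fractional responses,
ridge-stabilized if the sub-problem separates. Standard errors come from
the numerically differentiated observed information at the optimum
(`stats::optimHess`), and `odds_ratios()` reports $e^\gamma$ with Wald 95%
limits, p-values, and the confidence-limit ratio. The education effect is
additionally printed in the low-risk direction ($e^{-\gamma}$), matching
how both directions are quoted in applied reports.

Covariate missingness is handled by complete-case analysis *for the
concomitant sub-model only*: subjects with missing covariates keep
contributing to the measurement part of the likelihood through a marginal
prior. Full joint FIML over covariates would require a model for their
joint distribution, which the analysis this package follows never
specifies.

## The cognitive measurement model

`fit_bifactor()` fits a bi-factor confirmatory factor model to 18 test
scores: one general factor loading on everything plus four orthogonal
specific factors (verbal learning & memory; auditory attention & working
memory; visual attention & executive function; speeded language & mental
flexibility) on disjoint subsets. With unit-variance orthogonal factors
the implied covariance is $\Sigma = \Lambda\Lambda' + \Theta$; the ML
discrepancy $F_{ML} = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| -
p$ is minimized by L-BFGS-B with analytic gradients. Loadings start from
the leading principal component (general) and per-domain residual
components (specific); non-convergent fits restart with jitter. Residual
variances are floored at `1e-3` and a Heywood case is reported by
indicator name. The exact 18-variable battery of the original study is
not public; the packaged structure (`default_bifactor_structure()`) is a
documented stand-in with the same shape, and is also the generator's true
measurement model.

`fit_indices()` reports $T=(n-1)F_{ML}$, CFI, TLI, RMSEA against the
diagonal-covariance baseline, and BIC. `factor_scores()` uses the
regression method $\hat\eta = \Lambda'\Sigma^{-1}(y-\bar y)$ by default
(scores shrink: sample variance ≤ 1 per factor); Bartlett scoring is
available for sensitivity analysis. Rows with any missing test score are
excluded and counted, mirroring the listwise analytic cognitive sample of
the motivating study.

## Distal outcomes

`run_distal_suite()` compares the five factor scores across classes. The
default assigns each subject to the modal class first — as the motivating
analysis did — and tests mean equality with the Wald chi-square
$(m_1-m_2)^2/(SE_1^2+SE_2^2)$ on 1 df; a posterior-weighted mode
quantifies sensitivity to classification error. No 3-step (BCH/ML)
correction is applied, so class-mean contrasts are mildly attenuated by
misclassification; this is a known property of the classify-then-analyze
approach, not a bug. The post-hoc `posterior_regression()` regresses each
outcome on the posterior high-risk probability adjusting for age and
education. Five outcomes are tested without multiplicity adjustment (the
motivating analysis reported unadjusted p-values); a Bonferroni column is
printed for transparency but does not drive the flags.

## Random-forest validation

`rf_cross_validate()` predicts the modal class labels from the seven
indicators with a 1000-tree random forest (bagged trees, `floor(sqrt(7))
= 2` candidate features per split, majority vote), reporting stratified
10-fold cross-validated accuracy, out-of-bag error, and permutation
importance (mean decrease accuracy). The forest is the `randomForest`
package's; this stage validates the class solution rather than
contributing methodology. Note the deliberate circularity: the forest
predicts labels that were themselves derived from the same indicators, so
the ~96% accuracy is a consistency check of class separability, not an
out-of-sample error of any clinical classifier.

## The synthetic cohort generator

`default_params()` encodes the study conditions the package is tested
under: $n=727$ women aged 42–58; two classes at 62%/38% prevalence;
class-conditional indicator means and SDs taken from the published
within-class table (e.g. BMI 24.80±3.88 vs 28.97±3.73, HDL-C 74.13±15.20
vs 51.22±9.80, triglycerides 66.73±25.74 vs 129.26±60.24); concomitant
log-odds ln(1.140) per year of age, ln(0.627) for college education,
ln(0.951)/ln(2.621) for non-Hispanic Black/Hispanic ethnicity, ln(1.521)
for APOE4; covariate marginals from the baseline table (age N(52.68,
2.60²) truncated to [42, 58], education 0.735, ethnicities
0.805/0.078/0.077 renormalized over the three modeled groups, APOE4
0.262); and a 22% subject-level missingness rate.

Two calibrations make the generator match published *pooled* quantities:

* **Within-class correlation** (`calibrate_correlations()`). The latent
  profile model assumes local independence, but real indicators are
  correlated within class. The generator therefore draws indicators from
  class-conditional multivariate normals with one shared within-class
  correlation per pair, solved from the mixture-moment identity
  $\mathrm{cov}_{pool} = \sum_k \pi_k \rho_w \sigma_{jk}\sigma_{lk} +
  \sum_k \pi_k(\mu_{jk}-\bar\mu_j)(\mu_{lk}-\bar\mu_l)$ so that the
  pooled correlations reproduce the published zero-order table (e.g.
  HDL-C–triglycerides pooled −0.486 requires $\rho_w \approx -0.22$
  within class). The matrix is projected to the nearest positive
  semi-definite correlation if needed and the adjustment magnitude is
  recorded. Setting `within_class_corr <- diag(7)` is the
  local-independence oracle switch used in tests.
* **Concomitant intercept** (`calibrate_intercept()`). Root-finding on a
  200k-draw Monte-Carlo integral of the logistic prior over the covariate
  distribution, so the marginal high-risk probability equals 0.38.

Cognitive scores: five factor scores are drawn as class-mean-shifted
normals scaled to the published factor-score SDs (0.88, 0.87, 0.75, 0.73,
0.79), with shifts 0.068/−0.139 (speeded language) and 0.072/−0.110
(global cognition) and zero on the other three factors; 18 test scores
are then generated from the bi-factor measurement model. Two published
values force design decisions here. First, the printed low-risk global
cognition mean of 0.772 cannot coexist with factor scores centered at
zero (its prevalence-weighted combination with −0.110 is ≈0.44); the
generator uses 0.072, which centers correctly, and the discrepancy is
simply recorded. Second, the printed shifts leave a residual imbalance of
≈0.011, so the "factor scores centered overall" invariant is enforced at
a 0.02 tolerance rather than exactly.

The Framingham score has two generation paths: the default draws it as a
class-conditional normal rounded to integers (the mixture only needs its
marginal behavior), and `fps_mode = "derived"` computes it from the
generated age, total cholesterol, HDL-C, blood pressure and smoking with
`framingham_points()`, for tests of the scoring module itself. Blood
pressure, total cholesterol and smoking are drawn class-conditionally so
their pooled moments match the baseline table (≈117/75 mm Hg, ≈208
mg/dL, ≈7% smokers). Mean arterial pressure uses the standard
one-third-pulse-pressure formula; the source's own MAP formula is in an
unrendered footnote, and per-subject rounding explains the small gap
between the implied cohort mean (89.34) and the printed one (89.62), so
MAP is kept out of all calibration targets.

Missingness (`apply_missingness()`) is missing-at-random: the probability
that a subject has any missing cells is logistic in age (+) and education
(−), with the intercept solved so the marginal rate is 22%. Within a
flagged subject, APOE4 is blanked with probability 0.8, the cognitive
block with 0.45, ethnicity with 0.15 (at least one is forced), which
reproduces the approximate observed pattern (APOE4 missing ≈18%,
cognition ≈10%). The seven indicators are never blanked, matching the
complete indicator sample of the motivating analysis.

What the generator does **not** emulate: non-Gaussian within-class
distributions (real triglycerides are right-skewed), site-level
clustering, longitudinal follow-up, treatment effects, and coronary
artery calcification. Passing recovery tests therefore show that the
pipeline is correct *under its own assumptions plus the calibrated
correlation knob* — not that the original data meet those assumptions.

## Framingham point table

The women's total-cholesterol-based point system (age, total cholesterol,
HDL-C, a systolic-by-diastolic blood-pressure grid, smoking, diabetes) is
shipped as a versioned JSON data file so the scoring logic and the test
oracles share one source. Categories are left-closed; inputs outside the
scored domain raise an error rather than being clamped; when systolic and
diastolic pressures disagree, the higher-risk category governs. Diabetes
points are present in the table but default to absent, since the score
the package follows is built from six variables. The attainable score
range from enumerating the category grid is [−17, 25], which contains the
published observed range (−5 to 14).

## Problem sizes used in tests

The packaged test suite runs the recovery experiments at the study's own
scale (25 cohorts of n = 727; 10 forests of 1000 trees), the calibration
check at n = 100,000, the bootstrap-LRT null calibration at 100
replicates of B = 49 with n = 200 and three indicators, and the bi-factor
recovery at n = 5000. These sizes were chosen to keep Monte-Carlo error
well below the assertion tolerances while remaining desk-scale.

## Known limitations

* Under the calibrated defaults the unconditional 2-class fit
  overestimates the low-risk prevalence by ≈2.5 percentage points
  (≈64.7% vs the generating 62%). Roughly half of the bias comes from
  fitting class-invariant variances to classes whose true spreads differ
  (triglycerides SD 25.7 vs 60.2), and half from the within-class
  correlation. Fitting `variance = "varying"` removes the bias but
  sharpens the posteriors (entropy ≈0.87 instead of ≈0.85). Both knobs
  are exposed; the defaults follow the conventions of the software the
  motivating analysis used.
* The conditional model's Hispanic odds ratio is recovered with ≈10%
  downward attenuation at n = 727 (small cell: ≈56 Hispanic women), a
  finite-sample effect that vanishes at large n.
* Robust (sandwich) standard errors for the CFA and the mixture are not
  implemented; inference on loadings is out of scope.
* No 3-step correction for the distal tests (see above).
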