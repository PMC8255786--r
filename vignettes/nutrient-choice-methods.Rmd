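---
title: "Methods: nutrient-value estimation from binary food choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-value estimation from binary food choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrichoice)
```

## The choice model

The package analyzes repeated binary choices between liquid rewards defined
by their fat and sugar concentrations (g/100 mL) and offered in varying
magnitudes (mL). Its core object is the *nutrient–value function*: each
stimulus carries a relative value $\rho$ with

$$\log \rho = w_{fat}\,fat + w_{sugar}\,sugar\;(+\,w_{int}\,fat \cdot sugar),$$

and the subjective value of an offer is magnitude times $\rho$. Choices are
logistic in the log-value difference,

$$P(\text{left}) = \mathrm{logistic}\!\big(\tau\,[\log(m_L \rho_L) - \log(m_R \rho_R)] + b\big),$$

with temperature $\tau$ (inverse choice noise, per log-value unit) and side
bias $b$ (logit units). Working on the log-magnitude (ratio) scale is a
deliberate choice: psychometric curves are plotted against the offered
magnitude ratio, and under a log-linear model the 0.5-crossing of that curve
— the indifference point — is exactly the ratio $\rho_{target}/\rho_{ref}$,
independent of the offer distribution. Texture-driven agents replace the
nutrient terms with viscosity and sliding-friction (CSF) terms; sugar may
remain as a direct term, which is the configuration used to emulate oral
fat-sensing through texture.

Two estimators attack the same quantity from different directions:

* `psychometric_fit()` fits the logistic curve by maximum likelihood on raw
  trials of one stimulus pair (binning is used only for a descriptive
  adjusted $R^2$) and bootstraps the trials for a 95% CI of the
  indifference point.
* `fit_nutrient_model()` regresses the chosen side on
  $\Delta\log m, \Delta fat, \Delta sugar$ across all pairs; the ratio of a
  nutrient coefficient to the magnitude coefficient, exponentiated through a
  pair's concentration differences (`implied_relative_value()`), is the
  regression-implied indifference point. On 5,000-trial synthetic datasets
  the two estimators agree within 10%, which is the package's consistency
  check that both are unbiased for the generative $\rho$-ratio.

Session heterogeneity is handled either by fixed per-session dummy
intercepts or by random intercepts fitted with `lme4::glmer` (Laplace
approximation). The random-intercept route is the default recommendation
for many short sessions; the fixed-dummy route serves as a cross-check and
is exact when sessions are long.

## The synthetic-data generator

`make_factorial_stimuli()` builds the 2×2 fat-by-sugar design. Defaults are
dairy-realistic: fat 0.1 vs 3.6 g/100 mL (skimmed vs whole milk), sugar 4.7
(lactose) vs 12.575 g/100 mL, protein 3.4 g/100 mL. The high-sugar level is
chosen so that $9\,\Delta fat = 4\,\Delta sugar$ exactly, making the
high-fat/low-sugar and low-fat/high-sugar rewards isocaloric under the
Atwater factors (9/4/4 kcal per g fat/carbohydrate/protein) used throughout
the package. Offer magnitudes are drawn uniformly from a discrete grid,
default 0.2–1.2 mL in 0.2 mL steps — within the range used for controlled
liquid delivery in primate neurophysiology, and wide enough (magnitude
ratios 1/6 to 6) to bracket indifference points of 1.5–5. Side assignment
is counterbalanced pseudorandomly. Texture is generated as an affine
function of fat (viscosity slope +0.3 mPa·s and CSF slope −0.06 per g/100 mL
fat, CSF water-normalized to an intercept of 1) plus per-stimulus Gaussian
noise.

Optional choice-history terms add, to the logit, an exponentially decaying
tally (default window 5 trials, decay 0.7) of recent choices of the
fattier/sweeter option, signed by which side currently carries more of that
nutrient. Only the signs of such effects are empirically anchored; the
additive-exponential form is a package design decision, and the same
regressor definition is used by `history_regressors()` at estimation time so
the generator remains the exact inverse of the estimator.

The generator reproduces the statistical structure the analyses assume —
stable log-linear values, independent trials given the history terms,
texture collinear with fat up to stimulus-level noise. It deliberately does
**not** emulate within-session satiation, motivational drift, or stimulus
learning at session start. Passing tests on synthetic data therefore
establish correctness of the estimators under the model's assumptions, not
that real behavioral data satisfy those assumptions.

## Individual differences and transfer

Cross-context prediction evaluates a fitted model's log likelihood on
another context's trials against an intercept-only null fitted on the
target data (McFadden pseudo-$R^2$; a transferred-null variant is available
by flag). The preference dissimilarity index is

$$PDI(i,j) = \tfrac12\Big[\frac{LL(i|i) - LL(i|j)}{n_i} + \frac{LL(j|j) - LL(j|i)}{n_j}\Big],$$

normalized per trial (nats/trial) so datasets of different sizes are
comparable — the normalization is a package decision where convention is
unsettled. It is zero for identical models, symmetric by construction and
non-negative in expectation. `pdi_contribution()` quantifies how much of a
pair's dissimilarity is explained by fat or sugar by adding those
regressors to a nutrient-free base model.

## Texture mediation

`mediation_fit()` implements a regression path model: stimulus-level OLS of
texture on fat gives the *a* paths; the total-effect logistic (magnitude,
fat, sugar) gives *c*; adding texture differences gives the direct effects
*c′* and texture paths *b*. All choice-level regressors are z-scored once on
the full data before fitting, because raw logistic coefficients are not
comparable across models that differ in predictors (the rescaling problem);
the indirect effect is measured as the standardized coefficient drop
$c - c'$ rather than by any shorthand identity. Significance is a 95%
percentile CI from a session-level (cluster) bootstrap, since trials within
a session share a stimulus pair; a-path CIs come from the stimulus-level OLS
because resampling sessions does not perturb the fixed stimulus set.

Identifiability requires texture to vary off the fat axis: with only two
fat levels, or with duplicated texture channels, the design is singular and
the function refuses with the offending columns named rather than silently
dropping one. Calibration note: percentile cluster-bootstrap CIs for the
direct fat path are mildly anticonservative in this collinear design
(roughly 6–8% rejection of a true null at nominal 5%, stable across 250 vs
1,000 bootstrap draws and 12 vs 30 clusters); at least ~20 session clusters
are recommended, and the package's own acceptance checks use 20 sessions of
150 trials.

## Strategy comparison and geometry

The energy model collapses each offer to magnitude × energy density (kcal)
and is compared to the nutrient model by AIC ($2k - 2LL$). In sessions
offering the complementary isocaloric pair, the dichotomous fat and sugar
level regressors are exactly anti-collinear within a session, so separate
per-session coefficients are not identifiable; `isocaloric_coefficient_test()`
therefore estimates the identified (sugar − fat) contrast per session, with
z-scored regressors, and applies the one-sample Wilcoxon signed-rank test
(exact for n ≤ 25 sessions, normal approximation with continuity correction
above). Energy maximization predicts a zero contrast.

Nutrition-geometry quantities live in the mixture triangle: percent of
total energy from fat, sugar and protein. Because protein is constant by
design, the working plane is (fat%, sugar%) with protein implicit; the full
three-channel composition is retained in outputs. Choice balances are
energy-intake-weighted convex combinations of the offered stimuli's
compositions, computed redundantly from summed intakes and from energy
weights and required to agree to 1e-9. Reference points are projected
orthogonally onto the offer segment with the projection parameter clamped
to [0, 1]; confidence ellipses for mean balances use the
$\chi^2_2$ 0.95 quantile of the mean's covariance (slight undercoverage at
small n — about 94.7% at 200 sessions — is the known cost of the
$\chi^2$ rather than Hotelling quantile and is documented rather than
patched). Signed deviations are expressed in percentage-energy units of the
nutrient that varies most along the segment, positive toward the
high-nutrient end.

## Nutrient-sensitive reinforcement learning

The Rescorla–Wagner learner updates only the chosen option's value with
$v \leftarrow v + \alpha\,(r - v)$, unrewarded outcomes count 0, and action
selection is softmax with inverse temperature $\beta$. Nutrient
sensitivity enters through the outcome value of a rewarded high-nutrient
delivery, $r_{high} = r_{low}/(1 - \eta)$ — the unique one-parameter form
consistent with a 25% value increment at $\eta = 0.2$ and exact reduction
to the standard learner at $\eta = 0$. Defaults follow the reference
simulation: $\alpha = 0.2$, $\beta = 5$, 100 trials with probability
reversal at the midpoint (0.6 → 0.4 for the high-nutrient arm, the
low-nutrient arm complementary by default but configurable). All choice and
per-arm latent reward uniforms are drawn up front from the seed, so two
parameterizations run under one seed face identical latent outcome
sequences: this makes rep-wise comparisons paired and makes the $\eta = 0$
reduction testable trial for trial. Nutrient intake N counts high-nutrient
deliveries (not nutrient mass), a documented convention.

## Economic spaces

A 2×2 composition matrix maps bundles of two rewards into fat–sugar
nutrient space; utilities (linear or Cobb–Douglas) are defined on nutrient
space only. Because utility is a function of the nutrient profile alone and
the transforms are exact inverses, preference rankings are invariant under
any invertible reward-space re-parameterization — the module's central
property, verified by a 1,000-instance random sweep in the tests. Profiles
whose inverse image has a negative component are flagged unreachable;
singular composition matrices (nutritionally indistinguishable rewards) are
an error.

## Numerical choices and degenerate inputs

* Logistic fits run through `stats::glm.fit`; separation (non-convergence
  or |coef| > 15) triggers a small ridge-penalized IRLS refit
  ($\lambda = 0.01$) and the fit is flagged, never silently truncated.
* Bootstrap and CV procedures take explicit seeds and are exactly
  reproducible; per-session seeds in `make_dataset()` derive
  deterministically from one master seed.
* Psychometric fits refuse sessions with fewer than two distinct magnitude
  ratios or all-identical choices ("no inflection identifiable");
  bootstrap replicates that degenerate are dropped from the CI.
* Reference maximizers break exact ties uniformly at random under the seed.
* Zero-energy stimuli, zero intake, identical segment endpoints and
  singular covariance all raise errors or explicit degeneracy flags.
* The validation adjusted $R^2$ is computed on 10 equal-count bins of the
  value difference. On data with no signal this statistic is inherently
  noisy (both sums of squares are the same small order), so "no predictive
  power" should be judged by collapse relative to intact data rather than
  by a tight band around zero.

## Problem sizes used in the test suite

Unit tests run on scaled-down data (tens of sessions, 100–900 trials per
session); the acceptance-style tests use the full replication counts: 100
bootstrap-coverage replications of 500-trial sessions, 100+100 mediation
replications at 20 sessions × 150 trials with 250 bootstrap draws, 1,000
reversal-learning repetitions, 1,000 ellipse-coverage simulations and 1,000
random transform instances. These sizes were chosen as the smallest at
which the Monte-Carlo error of each check is comfortably below its decision
threshold.

## Known limitations

Only binary choices are modeled (multi-option sessions are analyzed
pairwise by choice frequency); there is no satiety or state dependence in
either the generator or the estimators; mediation is regression-based path
analysis, not latent-variable SEM; and empirical indifference maps from
real choice data are supported only through the relative-value hooks, not
estimated nonparametrically.
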