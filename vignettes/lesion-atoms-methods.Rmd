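---
title: "Lesion atoms and sex-stratified outcome modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion atoms and sex-stratified outcome modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionatoms)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## From voxels to tract lesion loads

A patient's lesion is a binary mask on the same voxel grid as a tract
atlas. The lesion load of tract $t$ is the atlas-weighted overlap
$\ell_t = \sum_v w_t(v)\,m(v)$ — for binary maps, simply the number of
lesioned voxels inside the tract. This is the standard tract-wise
convention; probabilistic maps are handled by the same weighted sum, since
nothing downstream requires binary maps. Grids must already be co-registered:
the package performs no resampling and rejects mismatched shapes.

Zero loads are common (most tracts are spared in most patients), so the
load matrix is stabilized entrywise as $\log_2(c + \ell)$ with pseudocount
$c = 1$ by default. The transform is strictly monotone, preserving
per-tract patient rankings, and maps the frequent zeros to exactly zero.
Whether loads should instead be volumes in ml or probability-weighted sums,
and how zeros were traditionally handled before the log, are not settled
conventions; both the weighting and the pseudocount are therefore exposed
in the configuration rather than hard-coded.

Continuous variables are z-scored with the sample ($n-1$) standard
deviation; the per-column centre and scale are retained, so the transform
is exactly invertible (`standardize_columns()` / `unstandardize_columns()`).

## Non-negative lesion atoms

The loads form $V \in \mathbb{R}_{\ge 0}^{m \times n}$ (tracts × patients;
$m = 28$, $n$ patients). Non-negative matrix factorization approximates
$V \approx WH$ with $W \ge 0$ ($m \times k$) and $H \ge 0$ ($k \times n$),
minimizing the Frobenius reconstruction error. Each column of $W$ is a
*lesion atom* — a recurring constellation of jointly damaged tracts — and
each patient expresses atoms in continuous non-negative degrees ($H$).
Because components combine strictly additively, atoms read as parts of a
whole; sign-indefinite alternatives such as PCA would allow physically
meaningless negative damage.

Numerical choices:

* **Solver.** Hierarchical alternating least squares: each atom's row of
  $H$ and column of $W$ is updated by its exact non-negative
  coordinate-descent minimizer. The objective is non-increasing by
  construction (a property the tests assert), and tail convergence is fast
  enough that planted factorizations are recovered to relative error
  $\sim 10^{-5}$ within the default budget.
* **Initialization.** The first run uses non-negative double SVD (NNDSVD,
  deterministic), with the sign-split zeros filled by the matrix mean so no
  atom starts dead; remaining restarts (default 5 total) are random, and
  the best final objective is kept.
* **Stopping.** Relative objective change below `tol = 1e-6` or
  `max_iter = 2000`.
* **Degenerate input.** An all-zero $V$ returns the exact zero
  factorization; all-zero atoms are warned about and ordered last.

The factor count is fixed at $k = 10$ by default, matching the ten atom
slopes of the outcome model; model-order selection is deliberately out of
scope, but $k$ is a configuration knob. Every fit is checked in the tests
against the rank-$k$ SVD tail bound
$\lVert V - WH \rVert_F \ge \sqrt{\sum_{i>k} \sigma_i^2}$, which holds for
any non-negative factorization.

NNMF is scale- and order-ambiguous, so `normalize_and_order_atoms()`
rescales each $W$ column to unit Euclidean norm (absorbing the inverse into
$H$, leaving $WH$ unchanged) and orders atoms by descending expression
variance. The unit-norm convention is this package's own choice of
presentation, not an inference about any particular prior analysis; atom
*indices* are therefore never comparable across runs — atoms should be
matched by lateralization and dominant tracts.

Each atom is summarized by its lateralization index over its loadings,
$LI = (L - R)/(L + R)$, where $L$ and $R$ sum the weights of left- and
right-hemisphere tracts (bilateral tracts excluded; $LI \in [-1, 1]$,
positive = left-dominant), and named by its `top_n = 3` highest-weighted
tracts, ties broken by tract index. Clinical relevance is ranked by
$\mathrm{score}_a = \sum_{\text{outcomes}} |r_{a,\text{outcome}}|$, the
summed absolute Pearson correlation between atom expressions and raw
outcome scores, computed on pairwise-complete cases without covariate
adjustment (the ranking is a descriptive, bottom-up stage; adjustment
happens in the Bayesian model). Note a genuine limitation: when atom
expressions are strongly correlated with one another, marginal correlations
need not order atoms by their true conditional effect sizes — the ranking
is a screening device, not an estimator.

## The sex-stratified Bayesian outcome model

For one z-scored cognitive outcome $y$:

$$y_i \sim \mathcal{N}\!\left(\alpha + \sum_{a=1}^{k} \beta_{a[\mathrm{sex}_i]} x_{ia}
 + \beta_{\mathrm{vol}} v_i + \beta_{\mathrm{age}} g_i + \beta_{\mathrm{age}^2} g^2_i
 + \beta_{\mathrm{edu}} e_i + \beta_{\mathrm{IQ}} q_i
 + \beta_m M_i + \beta_f F_i,\; \sigma\right)$$

with priors $\mathcal{N}(0,1)$ on $\alpha$, the sex-indexed atom slopes,
lesion volume, IQCODE, and the sex indicators; $\mathcal{N}(0,10)$ on age
and age²; $\mathcal{N}(0,5)$ on education; and half-Normal(1) on $\sigma$.
The likelihood family and noise prior are this package's completion of the
model (weakly informative on a z-scored outcome); covariate slopes other
than the atoms are not sex-indexed, following the model's notation.

Design-matrix conventions, in the order a reader will want to check them:

* atom expressions are z-scored over the whole sample and then *gated* by
  the sex indicators, so each atom carries one female and one male slope on
  a common scale (this is what makes posterior means comparable across
  atoms and sexes);
* age² is computed from standardized age and then itself re-standardized,
  keeping its prior scale meaningful;
* the intercept block $\alpha + \beta_m M + \beta_f F$ is deliberately
  over-parameterized ($M + F = 1$). All three carry proper priors, so the
  posterior is proper, but only their sum is data-identified: the three
  terms are never interpreted individually, and the independent-sampler
  cross-check in the tests compares slope posteriors only;
* complete-case analysis, with the number of dropped rows messaged; the
  fit refuses to run with fewer than twice as many cases as parameters.

**Sampling.** The model is conditionally conjugate: given $\sigma$, the
full coefficient vector has an exact multivariate-normal conditional,
drawn jointly via one Cholesky factorization per sweep; $\sigma$ is then
drawn by a univariate slice sampler under the half-Normal prior. This
blocked Gibbs sampler mixes essentially instantly for this model class and
samples the same posterior a Hamiltonian sampler would. Four chains with
over-dispersed $\sigma$ starts are run (defaults: 5000 post-warm-up draws
after 1000 warm-up; the test suite and acceptance script use a scaled-down
4 × 1000-draw mode with 250 warm-up, which the diagnostics show is ample
for this conjugate sampler). Split-$\hat R$ is reported per parameter and
any $\hat R > 1.01$ flags the fit as non-converged — never silently.
One numerical guard: $\sigma$ is floored at $10^{-4}$, far below any
realistic residual scale for a z-scored outcome, so that exactly noise-free
(degenerate) outcomes cannot drive the coefficient precision matrix
singular.

**Summaries.** The highest-density interval of a draw vector is the
narrowest contiguous window containing $\lceil p \cdot n \rceil$ sorted
draws (first window on ties) — checked in the tests against an exhaustive
window scan. A coefficient is *relevant* exactly when its 80% HDI excludes
zero. Posterior-predictive $R^2$ simulates one replicated outcome vector
per retained draw (including likelihood noise), takes the per-patient mean
of the replicates as the prediction, and reports
$1 - SS_{res}/SS_{tot}$; the variance-ratio Bayesian $R^2$,
$\mathbb{E}[\mathrm{var}(\mu)/(\mathrm{var}(\mu) + \sigma^2)]$, is attached
as a secondary statistic since the two formulations differ slightly in
finite samples.

## The synthetic cohort: what it emulates, and what it does not

The generator produces every input the pipeline consumes, with ground truth
retained:

* **Atlas** (default 32 × 32 × 16 grid): 13 left/right homolog tract pairs
  (each right tract the exact mirror of its left partner across the
  mid-sagittal plane; on an odd first axis the mid-plane belongs to neither
  hemisphere) plus 2 self-mirrored bilateral tracts — 28 tracts of 150
  voxels each. Tracts are pairwise **disjoint**, unlike real tractography
  atlases; this makes mask quantification exactly invertible, which the
  recovery tests exploit. Overlap would only blur the load→mask
  correspondence, not the downstream statistics.
* **Basis** $W_{\mathrm{true}}$: each atom is anchored on its own dominant
  tract pair plus minor pairs, so the planted factorization is separable
  (hence identifiable and recoverable by NNMF). A pair with base weight $b$
  and planted lateralization $\lambda$ receives left weight $b(1+\lambda)$
  and right weight $b(1-\lambda)$, making the recomputed LI equal the
  planted one to machine precision. The default profile plants mostly
  lateralized atoms with one bilateral, echoing the typical pattern of
  paired left/right lesion constellations.
* **Expressions** $H_{\mathrm{true}}$: each patient receives small
  exponential background expressions on all atoms plus a large exponential
  boost on one uniformly chosen dominant atom — non-negative and
  right-skewed, so most patients express few atoms strongly. No published
  empirical distribution of patient expressions exists; this sparse
  exponential choice is a modelling decision, exposed in the generator's
  arguments.
* **Masks**: per patient, exactly `round(W_true %*% H)` voxels are sampled
  without replacement inside each tract (half-up rounding, which is what
  bounds the quantification oracle's tolerance at zero).
* **Covariates**: sex ~ Bernoulli(0.42 female); age, education and IQCODE
  are truncated normals with sex-specific anchors whose pooled moments
  reproduce the emulated cohort table (overall age 67.58, SD 11.59).
  Total lesion volume is the planted tract burden plus an independent
  exponential "out-of-atlas damage" component — correlated with the atom
  expressions, as in real data, but not a linear combination of them
  (a pure tract-burden volume would make the atom slopes non-identified).
* **Outcomes**: the generator evaluates the *model's own* standardized
  linear predictor — through the same code path as `build_design()` — at
  configured coefficients and adds Gaussian noise, then stores outcomes on
  raw test-score scales (e.g. naming mean 9.92, SD 3.59) so that the
  pipeline's z-scoring recovers the generating scale. Because the fitted
  model sees the z-scored outcome, the estimand is $\beta / s_y$ with
  $s_y$ the sample SD of the latent outcome; the generator records these
  rescaled coefficients alongside the nominal ones, and recovery tests
  target them. With `noise_sd = NULL` the noise SD is set to the empirical
  SD of the linear predictor, giving a generating-model
  $R^2 = s^2/(s^2 + \sigma^2) = 0.5$ — the scale of the strongest fit
  reported for real naming data — so recovery tests run at a realistic
  signal-to-noise ratio. Default atom effects mix signs and magnitudes of
  roughly $-0.35$ to $+0.15$ standardized units, the range of published
  posterior means for such models.

What passing these tests shows: the pipeline recovers planted structure
and calibrated uncertainty under the model's own assumptions at realistic
size and noise. What it cannot show: robustness to overlapping tract maps,
registration error, non-Gaussian outcome noise, floor/ceiling effects in
test scores, or informative missingness — none of which the generator
emulates.

## Problem sizes and reproducibility

The test suite exercises the full 28-tract, $k = 10$, 1400-patient
configuration for factor recovery, explained variance and slope recovery
(20 repeated cohorts at 4 × 1000 draws), and smaller fixtures elsewhere;
these sizes were chosen so the whole suite completes in a few minutes while
still operating at the emulated cohort's scale. One global seed fans out
deterministically to named per-stage substreams (`stage_seed()`), so any
stage can be rerun in isolation and a fixed seed makes the full pipeline
byte-identical, manifest included.

## Known limitations

* Atom indices are arbitrary; compare atoms across runs by lateralization
  and dominant tracts, never by position.
* The relevance ranking is marginal, not conditional (see above).
* No model-order selection for $k$, no consensus clustering across NNMF
  restarts, no voxel-space back-projection of atoms.
* Inputs must share one voxel grid; no registration or resampling.
* Complete-case analysis only; no imputation.
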