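---
title: "Adventitious error: model, conventions, and simulation design"
author: "advwish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adventitious error: model, conventions, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(advwish)
```

## The generative model

The package treats every study's population covariance matrix as a random
perturbation of a theoretical matrix $\Omega$:

$$\Sigma_s \sim IW(m\Omega,\, m), \qquad S \sim W(\Sigma_s/n,\, n),
\qquad n = N-1 .$$

The inverse-Wishart dispersion $1/m$ is the single tuning knob of the
framework, and it is tied to the familiar RMSEA fit index by
$\mathrm{RMSEA}^2 = 1/m$. An RMSEA of 0.08 — conventionally the edge of
satisfactory fit — therefore corresponds to dispersion $0.0064$ and
$m = 156.25$ degrees of freedom; an RMSEA of 0.05 to dispersion $0.0025$.
These two dispersions are the package defaults wherever a benchmark is
needed, and they are *illustrative benchmarks*, not recommendations: the
dispersion is not estimable from a single data set.

Two modelling conventions deserve emphasis:

* The scale matrix is $m\Omega$ exactly, so the IW mean is
  $m\Omega/(m-p-1)$, slightly larger than $\Omega$. No bias correction is
  applied; the small mean shift is part of the model. The alternative
  dispersion $1/(m-p+1)$ gives nearly identical simulation results and is
  not separately implemented.
* Dispersion 0 is represented as an exact pass-through of $\Omega$ (no
  infinite-df arithmetic), so every downstream quantity reduces smoothly to
  its classical value.

Fractional degrees of freedom are handled exactly: draws go through the
Bartlett decomposition of the Wishart distribution (`stats::rWishart`,
which generalizes the chi-square factors through the gamma distribution)
and are then inverted. `tests/` verify the IW mean at $p=2$, $m=100$
against the closed form $m/(m-p-1)$.

## Uncertainty inflation

For parameter estimates, the standard error under adventitious error is
the traditional one times

$$q = \sqrt{\frac{1/m + 1/n}{1/n}} = \sqrt{1 + (N-1)/m}.$$

`tauf()` implements this *theoretical augmented uncertainty factor*. It is
1 exactly at dispersion 0 and **grows** with $N$: the $1/m$ term does not
shrink with the sample, so larger studies are relatively more affected.
On the Fisher-z scale for correlations, the augmented SE is

$$\sqrt{\frac{N-1}{N-3}\cdot\frac{1}{m} + \frac{1}{N-3}},$$

whose ratio to $\sqrt{1/(N-3)}$ equals $q$ identically (an algebraic
identity the tests check on a grid), and whose $N\to\infty$ limit is
$\sqrt{1/m}$ — the floor that produces the attainability threshold
$(z_{.80}+z_{.975})\sqrt{1/m}$, the significance floor
$z_{.975}\sqrt{1/m}$, and the narrowest achievable confidence intervals.

Conventions chosen here, where the choice was genuinely open:

* **One-tailed testing.** Power is assessed one-tailed at $\alpha/2$
  (rejections in the wrong direction are ignored); a
  `two_sided_regions` flag adds the other tail.
* **Real-valued N.** Sample sizes are real numbers internally; ceilings
  apply only to reported integers. The scale-up identity
  $N_2 = \{N_1-(N_1-3)/m\}/\{1-(N_1-3)/m\}$ is applied to the *unrounded*
  $N_1$; the tests verify that power at the unrounded $N_2$ equals the
  target to $10^{-9}$.
* **Exact normal quantiles.** $z_{.80} = 0.8416$ by default; a
  compatibility flag substitutes the conventional 0.84, which moves the
  attainability threshold's third decimal only.
* **Threshold scales.** The significance threshold is reported on both the
  Fisher-z scale (the headline: $1.96\times 0.08 = 0.157$ at the benchmark)
  and the correlation scale (tanh, 0.156); the two differ in the third
  decimal and reporting both avoids guessing which the reader wants.

On the Cohen's d scale ($d = 2r/(1-r^2)$, $SE(d) = 2/\sqrt{(N-1)(1-r^2)}$),
the SE surplus is interpreted as single-study heterogeneity:
$\tau^2 = (SE\cdot q)^2 - SE^2$. All intermediates are kept unrounded; the
print method shows the 3-dp rounded chain alongside because hand
calculations that round intermediates land on slightly different third
decimals (0.0337 unrounded vs 0.034 rounded at $r=.49$, $N=200$). No
meta-analytic pooling is implemented — only the single-study attribution.

## The factor-model fitter

`fit_ml()` minimizes the normal-theory discrepancy
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - \log|S| - p$
for a one-factor model (optionally with a manifest predictor of the latent
variable, the MIMIC layout) using BFGS with analytic gradients
($\partial F/\partial\Sigma = \Sigma^{-1}(\Sigma - S)\Sigma^{-1}$, chained
to loadings, log residual variances, the predictor variance and the
X–factor covariance). Numerical choices:

* one deterministic start (all loadings 0.5, residual variances 0.5) plus
  one random restart on non-convergence; convergence to relative tolerance
  $10^{-12}$ on $F$;
* variances optimized on the log scale, so positivity is structural;
* sign indeterminacy resolved by flipping the loading vector (jointly with
  the X–factor covariance) so the loading sum is positive — without this,
  sign flips masquerade as within-individual score variation in the
  measurement study;
* internal identification is always unit factor variance; marker-loading
  results are produced by rescaling the solution, which implies the
  identical covariance matrix and discrepancy (tested), so the two
  conventions never disagree about fit;
* non-convergent fits are flagged, excluded from SD computations, and
  counted in every report.

Thurstone regression score weights are $w = \hat\Lambda'\hat\Sigma^{-1}$
with the model-implied $\hat\Sigma$; the conventional $\mathrm{var}(\theta)$
premultiplier is a common scale factor across indicators and is omitted
because all scores are standardized downstream.

## The uncertainty-factor simulation

`run_sauf()` follows a four-step design: distort $\Omega$ `reps` times,
generate one $N$-row multivariate-normal dataset per operational matrix
(per-variable means drawn from $N(0, 0.5^2)$ — inert for covariance-based
estimates but kept for fidelity to the design), estimate the effect per
dataset, and take the SD across replicates; the same generation from the
undistorted $\Omega$ gives the denominator. Three effects are covered: an
OLS slope for two variables, the ML structural coefficient of a MIMIC
model with four indicators, and the OLS slope of the four-indicator summed
score. In `table1_report()` the latter two are computed from the *same*
generated datasets — they are two analyses of one design, not two
simulations. The denominator is the SD of the undistorted-arm estimates by
default; median-per-replicate-SE variants are available for the regression
cases.

The default population values: unit variances throughout,
$\mathrm{cov}(X,Y) = 0.25$ in the two-variable case, $\mathrm{cov}(X,Y_j) =
0.35$ and loadings 0.70 (indicator covariances 0.49) in the five-variable
case, dispersion 0.0064, 2000 replicates, $N \in \{200, 1000\}$.

For the factor-model case the reported SD magnitudes depend on the
identification convention, and the reference values for this design could
not be reproduced exactly under either convention (they are also mutually
inconsistent with an additive adventitious-plus-sampling variance across
the two sample sizes, suggesting a different standardization in their
original computation). The uncertainty *ratios*, however, agree under both
conventions, and both are always reported.

At 2000 replicates the ratio of two SDs carries a Monte Carlo SD of about
2.2% of its value (≈0.06 when the factor is ≈2.7): third decimals of any
single run, including the reference values themselves, are noise, which is
why the test suite compares at a tolerance of 0.10.

## The measurement-uncertainty simulation

The second study isolates what adventitious error alone does to composite
scores. Within a sample, a preliminary $N\times p$ matrix $Z_k$ is drawn
once and *exactly whitened* (column means 0, covariance $I$ to machine
precision); each of $S$ operational matrices is then imposed by a linear
map, so the empirical covariance of dataset $s$ equals $\Sigma_s$ exactly
and the $S$ datasets are exact linear transforms of one another — sampling
error and measurement error are excluded by construction. Factor scores
(regression weights from a fresh ML fit per dataset) and summed scores are
standardized within dataset; each individual's SD across the $S$ datasets,
averaged over individuals and then over $K$ samples, is the headline
within-individual uncertainty.

**Transform convention.** Two square roots of $\Sigma_s$ are implemented.
The default is the rectangular eigen factor (rows $\sqrt{e_j}v_j'$,
decreasing eigenvalues, signs fixed by a positive-first-element rule) —
the decomposition the standard multivariate-normal generator applies
internally, so scores react to an operational-matrix change exactly as
they would under dataset-by-dataset generation. The symmetric square root
$V\sqrt{E}V'$ is available as a sensitivity flag; it is continuous in
$\Sigma_s$ and, perhaps counterintuitively, produces *larger*
within-individual variation for the compound-symmetry $\Omega$ used here
(grand means ≈0.105/0.040 vs ≈0.074/0.034 under the defaults below).
The difference is a genuine convention sensitivity of the design, not a
numerical artifact — an independent computation of the summed-score
direction variance across draws reproduces the symmetric-root value.

Defaults mirror the reference design: $K=10$ samples, $S=1000$ operational
draws, $N=1000$ individuals, four indicators with loadings 0.70
($\Omega$ off-diagonals 0.49), dispersion 0.0064; a loadings-0.50 variant
(off-diagonals 0.25) roughly multiplies both uncertainties by 2.5.
Standardization uses the $N-1$ denominator (at $N=1000$ the $N$ vs $N-1$
choice is far below every reported decimal). Exact whitening removes the
per-sample covariance fluctuation of $Z_k$, so between-sample spread here
is much smaller than a design that leaves $Z_k$ raw; the grand means are
unaffected at the reported precision.

For context, the within-individual SDs translate to 95% ranges of width
$2\times 1.96\times SD$ (≈0.33 for factor scores, ≈0.14 for summed scores
at the defaults), to be compared with the standardized S.E.M.
$\sqrt{1-\text{reliability}}$ — 0.316, width 1.24, even at a reliability
of .90. Adventitious error moves composite scores far less than ordinary
measurement error.

## Seeds, reproducibility, problem sizes

Every study driver takes a single master seed; per-cell and per-sample
streams are derived from it by a pure integer map (`derive_seed()`), all
below $2^{31}$. Identical configurations reproduce results bit for bit
(tested), and run records serialize to JSON without the timestamp so
reruns are byte-identical.

The test suite runs the full reference designs — 2000 replicates per
uncertainty-factor cell and the complete $10\times 1000\times 1000$
measurement study (about ten thousand small ML fits) — in roughly a minute
total; unit tests use scaled-down designs (a few hundred replicates) whose
agreement with the full sizes is itself a tested property. The Monte Carlo
power oracle uses $10^4$ replicates per grid point and compares the
simulated rejection rate of the augmented-SE Fisher-z test with the closed
form within three Monte Carlo standard errors.

## What the simulations do and do not show

The generator *is* the model: multivariate-normal data, exact
inverse-Wishart distortion, equal loadings, compound-symmetry structures.
Agreement of the simulation-based factors with $q$ therefore validates the
implementation and the internal consistency of the framework — it cannot
validate the framework against real data, where the dispersion is not
estimable and distortions need not be inverse-Wishart. Non-normal data,
unequal loadings, structured residuals, and random sampling of indicators
(a distinct mechanism with potentially larger effects on scores) are all
outside the generator. The multilevel estimation of a dispersion parameter
from a collection of studies is likewise out of scope.
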