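---
title: "Methods: from ring widths to drought-sensitivity QTLs"
author: "dendroqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ring widths to drought-sensitivity QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroqtl)
```

## The problem

Clonally replicated forest-tree trials make it possible to ask a genetic
question about a dendroclimatological quantity: *which loci control how
strongly a genotype's annual growth responds to climate?* The pipeline in
this package chains four stages:

1. **Ring processing** — per-tree ring widths become a standardized,
   serially-uncorrelated annual growth index ("relative BAI"), averaged
   robustly across the clonal replicates.
2. **Climate indices** — daily weather becomes monthly temperature means,
   precipitation sums and a family of thresholded *dry-period* indices.
3. **Sensitivity traits** — for each clone, the Pearson correlation between
   its growth index and each lagged monthly climate variable. The per-clone
   correlation *is* the phenotype.
4. **QTL mapping** — a sparse empirical-Bayes regression of the chosen
   sensitivity trait on all markers of a two-map pseudo-testcross design,
   with PVE decomposition, cross-validated prediction accuracy, and a
   Haley–Knott interval-mapping scan as an independent check.

A seeded synthetic-data generator emulates all three inputs so that every
stage can be tested against planted ground truth.

## Ring processing

Widths $w_t$ (mm, pith outward) accumulate to radii $r_t = \sum_{i\le t}w_i$;
the basal area increment is $\mathrm{BAI}_t = \pi(r_t^2 - r_{t-1}^2)$. The
age trend is removed with a modified Hugershoff curve

$$g(t) = A\,t^b e^{-ct} + d, \qquad A>0,\; c\ge 0,$$

fitted per tree by nonlinear least squares (`minpack.lm`), initialized from a
log-linear regression of BAI on $(\log t, t)$. We use *ratio* detrending
(index $= \mathrm{BAI}_t/g(t)$), the ring-width-index convention; difference
detrending is available behind a switch because the literature is not always
explicit about which is meant. If the fit fails or the curve is not strictly
positive, the horizontal mean curve is substituted and flagged — a fallback,
not an error, because short juvenile series occasionally defeat a 4-parameter
model.

The index is then prewhitened with an AR(1) model estimated by conditional
least squares, $\hat\phi = \sum x_t x_{t-1} / \sum x_{t-1}^2$ on the centered
series, and the innovations $e_t = x_t - \hat\phi x_{t-1}$ are the *relative
BAI*. The first observation is kept as its centered value so the chronology
retains one value per ring year (configurable); with only ~11 rings, losing a
year matters for the correlation traits. Per clone and year, replicate trees
are combined with Tukey's biweight robust mean (tuning constant $c = 9$,
scale = median absolute deviation about the initial median — standard
chronology practice; the estimator, not its constants, is prescribed by the
method we follow). The stage order — detrend each tree, prewhiten each tree,
then average replicates — is pinned by a test, because averaging before
prewhitening gives a different (and wrong, replicate-noise-correlated)
result.

## Dry-period climate indices

A *dry spell* is a maximal run of days with precipitation at or below a
cutoff (0 mm by default — the strict "non-raining" reading; 0.5 mm is offered
for trace-rain gauge conventions). For threshold $k \in 1..7$ days, the
monthly index is the number of days in that calendar month that belong to
spells of *total* length $\ge k$. This is the only accumulation semantics
under which $k=1$ reproduces the total count of dry days, and it makes the
index monotone non-increasing in $k$ cell-wise — both are tested against a
brute-force day-enumeration oracle. Spells crossing month boundaries
qualify on their full length but contribute each day to the month it falls
in, so a long drought registers in both months without double counting.

Large $k$ produces months with no qualifying spell; a threshold is
*admissible* when fewer than half of all (year, month) cells are zero. All
monthly matrices (temperature, precipitation, dry-period at each threshold)
are linearly detrended per month label across years (March against Marches),
which removes a secular trend without touching seasonality; whether the
original analysis detrended the dry-period index too is ambiguous, so this is
a switch with detrending of all three as the default.

## Sensitivity traits

For ring year $Y$ the trait window pairs growth with climate from June of the
prior year (`p06`) through September of the formation year (`c09`) — 16
lagged months. The trait is the Pearson correlation (Spearman behind a flag);
missing cells and constant inputs give a missing trait rather than an error.
Significance counts at $\alpha = 0.05$ (no multiplicity correction — the
counts are descriptive) summarize the population response; the QTL phenotype
is the vector of raw per-clone $r$ values for one chosen (variable,
threshold, month) cell, by default the 4-day dry-period index in March of the
formation year. We map raw $r$ rather than Fisher-z because the downstream
effect sizes are reported on the correlation scale; Fisher-z is a
one-argument change for a user who prefers it.

## Empirical Bayesian lasso with the NEG prior

The mapping model is $y = \mu + X\beta + e$ with heterozygous/homozygous
genotypes coded 0/1, markers of both parental maps joined into one design.
Markers with more than 1% missing calls are excluded; remaining missing
calls are mean-imputed; monomorphic and (exactly) duplicated columns are
dropped or collapse naturally.

Each effect has the three-level prior
$\beta_i \sim N(0, \sigma_i^2)$, $\sigma_i^2 \sim \mathrm{Exp}(\lambda)$,
$\lambda \sim \Gamma(a, b)$. Integrating $\lambda$ gives the marginal prior
on the effect variance $p(\sigma_i^2) \propto (b + \sigma_i^2)^{-(a+1)}$, so
the type-II log-likelihood contribution of basis $i$ is

$$\ell(A) = \tfrac12\!\left[\frac{q_i^2 A}{1+A s_i} - \log(1+A s_i)\right]
  - (a{+}1)\log(1 + A/b),$$

where $s_i, q_i$ are the usual sparsity/quality factors with basis $i$
excluded. The stationarity condition is a quadratic in $A$: a basis enters
only if $b(q_i^2 - s_i)/2 > a+1$, otherwise its profiled prior variance — and
hence its effect — is exactly zero. The fit greedily adds, re-estimates or
deletes one basis at a time, always taking the largest marginal-likelihood
gain, with rank-one updates of the posterior and of all $p$ sparsity/quality
factors (the compiled core in `src/` mirrors a pure-R reference
implementation that the test suite checks it against to machine precision).

Four numerical decisions matter and are deliberate:

* **Noise estimation is a single refinement, not a fixed point.** The greedy
  sweep runs to convergence at fixed $\sigma^2$; $\sigma^2$ is then
  re-estimated from the posterior and the sweep repeated once. Iterating to a
  joint fixed point is unstable when $p \gg n$: each decrease in
  $\hat\sigma^2$ inflates every quality factor, admits more bases, and
  shrinks $\hat\sigma^2$ further, drifting toward a saturated model.
* **The phenotype is standardized internally** (effects are mapped back).
  The sensitivity trait is a correlation with variance far below 1; without
  standardization any fixed $(a, b)$ grid would sit at an arbitrary point of
  the shrinkage scale.
* **Admission is charged a minimum evidence gain** (0.25 nats by default): a
  new basis must improve the penalized marginal log-likelihood by more than a
  token amount. Without this, clusters of near-threshold spurious bases
  enter together, jointly deflate $\hat\sigma^2$ and inflate one another's
  t statistics.
* **Reported effects are re-estimated by joint OLS on the significant set.**
  Posterior means of strong effects are shrunken by construction; the
  two-stage refit de-biases them and keeps per-QTL PVE on the same scale as
  the joint PVE, which is itself defined through that regression. Selection
  and p-values still come from the empirical-Bayes posterior.

Retained effects get a posterior $t = \hat\beta_i/\mathrm{se}(\hat\beta_i)$
with $df = n - |\text{retained}| - 1$; markers with non-zero effects and
$p < 0.01$ are the significant QTLs. With dense maps one locus is often
represented by two or three retained markers in tight linkage;
`qtl_regions()` collapses calls into regions (markers within 10 cM on a
group) ranked by the variance they jointly explain.

### The hyperparameter grid

$(a, b)$ are selected by repeated five-fold cross-validation (mean squared
out-of-fold error, 10 fold assignments averaged, ties to the
stronger-shrinkage candidate). The two parameters do different jobs: the
*inclusion* condition depends only on the ratio $(a{+}1)/b$ (a basis can
enter only if $b(q^2-s)/2 > a+1$), while the penalty applied to an effect
once included grows with $a$ alone. Low-curvature (small-$a$) points act as
heavy-tailed priors: whatever enters is barely shrunk, so a spurious extreme
marker that clears the inclusion condition also clears any downstream
significance filter — and since reported effects are refit anyway, such
points add no estimation benefit. The default grid is therefore a shrinkage
*frontier* of strongly-curved members only, from an effectively closed model
($b = 0.001$, letting cross-validation select the empty model outright on a
signal-free phenotype), through near-closed ($a \in \{5,10,20\}$,
$b = 0.01$), to liberal inclusion with strong curvature
($a \in \{10,20\}, b = 0.1$ and $a \in \{80,100\}, b = 1$). Members were
placed so that each one's implied significance boundary lies above the
genome-wide noise ceiling of a ~10^3-marker scan at this sample size.
Repeating the fold assignment 10 times reduces the selection noise that
would otherwise decide between models a few percent of phenotype variance
apart.

### PVE, prediction accuracy, validation scan

Per QTL, $\mathrm{PVE}_i = \hat\beta_i^2\,\mathrm{var}(x_i)/\mathrm{var}(y)$
(percent). For all significant QTLs jointly, PVE is the variance of the
fitted values of an OLS regression of $y$ on those markers relative to
$\mathrm{var}(y)$ — algebraically the regression $R^2$, and tested to
$10^{-10}$ against it. Prediction accuracy is the Pearson correlation between
observed values and out-of-fold OLS predictions over a seeded five-fold
split. The interval-mapping validation regresses $y$ on the expected genotype
given flanking markers (inverse Haldane map function) on a 1 cM grid,
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$, optionally
with cofactor markers outside a 10 cM window of the test position; this is a
validation aid, not a full cofactor-selected composite interval mapping.

## The synthetic-data generator

The generator exists to give every stage a ground truth:

* **Maps and genotypes** — two parental maps (pseudo-testcross: each map's
  markers segregate 1:1 through its heterozygous parent, the two maps
  simulated independently), by default 11 groups × 60 cM at 1.5 cM spacing
  (~450 markers per map). Along a group, genotypes follow a Markov chain with
  Haldane recombination fractions.
* **Weather** — a two-state Markov chain with month-specific transition
  probabilities, gamma rainfall on wet days, sinusoidal temperature. Defaults
  imitate a warm-temperate monsoon climate (annual mean ~15.7 °C,
  ~1600 mm/yr, dry late winter, wet summer) so that early-spring dry spells
  of 4+ days are common enough for the index to be informative.
* **Sensitivities** — the latent drought sensitivity of clone $c$ is
  $s_c = \sum_j \alpha_j x_{cj} + \eta_c$. The default architecture plants 13
  QTLs with PVE 12.4, 2.9, 2.7, 2.5, 2.1, 1.8, 1.8, 1.6, 1.5, 1.5, 1.2, 1.0,
  0.9 percent of a unit-variance latent trait (so
  $\alpha = \pm 2\sqrt{\mathrm{PVE}}$ with marker variance 1/4), clone noise
  making up the remaining ~66%.
* **Rings** — expected BAI follows a Hugershoff age curve (defaults sized for
  a fast-growing young conifer); the year effect is multiplicative,
  $\exp(\kappa\, s_c z_t + \varepsilon_t)$ with $z$ the standardized March
  dry-period index and $\varepsilon$ AR(1) tree noise. Replicates share $s_c$
  but not $\varepsilon$. Link scale $\kappa = 0.35$ and tree-noise SD 0.25
  were calibrated once so that the *measured* trait lands in the regime such
  a trial observes: per-clone correlations spanning roughly ±0.9 with the
  leading locus accounting for ~11% of the measured trait variance.

What the generator does **not** emulate: wood-anatomy effects, missing rings
and crossdating errors, genotype-by-site interaction beyond a per-site link
scale, segregation distortion, and non-stationary climate beyond a linear
trend. Passing tests therefore certify the statistical machinery, not the
biology of any particular forest trial.

Trait estimation from ~11 years is noisy (standard error of a correlation at
$n = 11$ is ≈ 0.3), so the *measured* trait carries substantially less
genetic signal than the latent sensitivity: an architecture planted at ~34%
latent PVE yields a measured-trait PVE well below that. The
parameter-recovery checks therefore run on the latent sensitivity (the
phenotype the architecture defines), while the end-to-end run reports what
survives the full measurement chain.

## Problem sizes used by the checks

The statistical acceptance checks run at the design scale of the study the
defaults mirror: 139 clones × 3 replicates, two maps × ~450 markers, 11 ring
years; selection-behavior checks use 100 replicates at $n = 139..150$,
$p = 300$ with unlinked markers; parameter recovery uses 50 seeded replicates
at full map density with hyperparameters cross-validated once and reused, as
a single analysis would. Null interval-mapping scans use signal-free
phenotypes on the same genotypes.

## What the study conditions can and cannot deliver

Two acceptance-style properties are information-limited at the design scale
(139 clones, dense ~1.5 cM maps, one 12%-PVE locus among twelve 1–3%
minors), and the package documents rather than hides this:

* *Localization.* A 12%-PVE locus scores LOD ≈ 4; markers 5 cM apart
  correlate ≈ 0.9, so the argmax of the association surface (and the LOD
  peak) wanders beyond ±5 cM in roughly a third of replicates. QTL identity
  at this scale is a linkage-group region, not a marker.
* *Calibration vs. power.* Keeping genome-wide false positives at the few-%
  level over ~10^3 markers forces an effective significance threshold around
  $z^2 \approx 14$–16; the major locus sits at $z^2 \approx 19 \pm 5$, so
  it is called significant in ~75–85% of replicates, and the z ≈ 2 minor
  loci essentially never are. Consequently the significant set carries only
  the major's share of variance and cross-validated prediction accuracy
  centers near $\sqrt{0.15} \approx 0.39$, below what the full planted
  architecture (~34% PVE) would support if every locus were recoverable.

## Known limitations

* The greedy type-II scheme is order-dependent under near-collinearity: of
  two markers in tight linkage with a causal locus, whichever explains
  marginally more variance is retained, so "the" QTL marker is identified
  only up to a few cM — matching how such results are read in practice.
* p-values for retained effects are posterior t statistics conditional on
  selection; they are calibrated for the strong-shrinkage regimes the
  cross-validation favors, not a guarantee of frequentist size at weak
  shrinkage.
* PVE of a selected top QTL carries winner's-curse inflation that partially
  offsets shrinkage attenuation; neither is corrected.
* The Hugershoff fallback (mean curve) removes no age trend; flagged trees
  should be inspected rather than silently trusted in small data sets.
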