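---
title: "Quantifying time-lag bias in landmark digitization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying time-lag bias in landmark digitization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digitME)
```

## The problem

Landmark-based geometric morphometrics quantifies biological shape from the
Cartesian coordinates of homologous points. Digitizing those points is manual
work, and it is rarely finished in one sitting: a researcher visiting museum
collections, or returning to a photographic archive, collects data in
sessions separated by hours, days, or years. Between sessions the operator's
eye can drift, so that some landmarks are placed in a consistently different
spot — a *systematic* measurement error (bias) on top of the ordinary
*random* placement scatter. If different parts of a sample are digitized in
different sessions (for example, one sex or one species per museum visit),
that bias is confounded with the biological contrast of interest.

digitME implements a complete study pipeline for this problem on 2D data:
repeated digitizations (REPs) of the same photographs are compared with a
battery of methods that (i) separate systematic from random digitization
error and test each against noise, (ii) check how robust biological signal
(sexual dimorphism, static allometry) is across sessions, (iii) score the
absolute imprecision of each landmark in the raw coordinates, and (iv)
measure what removing imprecise landmarks buys. Because the repeated
digitizations analysed in this design are of the *same images*, there is no
repositioning or camera error in play; the pipeline measures digitization
error only, which is a deliberate, documented narrowing of scope.

## Shape variables

Each configuration of $L$ landmarks is centered, scaled to unit centroid
size ($CS$, the square root of summed squared distances of landmarks to
their centroid), and rotated to a consensus by generalized Procrustes
analysis (GPA). Rotations are solved in closed form by representing 2D
configurations as complex vectors; reflections are never allowed. Iteration
updates the consensus until it changes by less than `tol` (default 1e-10,
Frobenius norm), and the solution is then put in a canonical frame (the
consensus principal axis on x, with a sign convention on the first landmark)
so that the fit does not depend on which record initializes the consensus.

Statistics operate on tangent-plane coordinates: the aligned coordinates
projected orthogonally to the consensus direction. `tangent_diagnostic()`
regresses tangent (Euclidean) on Procrustes geodesic distances through the
origin; for data of the dispersion considered here the approximation is
essentially exact (r and slope within 1e-3 of 1), which licenses ordinary
multivariate statistics on the tangent coordinates. With $L$ 2D landmarks
the shape space has $2L - 4$ informative dimensions (two lost to
translation, one to scale, one to rotation).

## The two ANOVAs

`procrustes_anova()` is the classical hierarchical decomposition (type I,
sequential): sex, then individual within sex, then the residual, which in a
complete individual-by-REP design is *total* measurement error. Degrees of
freedom are multiplied by the shape dimension $2L-4$, and Goodall-type F
ratios test each level against the hierarchically lower one.

`me_anova()` is the bias-detecting decomposition. Every individual's REP
records are first centered on that individual's own mean, which removes all
individual variation. The centered data are then split, with type II sums of
squares, into:

* **systME** — the REP main effect: the average displacement of a whole
  session, i.e. the bias;
* **systME:sex** — does the bias differ between groups?
* **randME** — the residual scatter of repeated placements.

The test statistic for each effect is the signal-to-noise ratio
$\mathrm{SNR} = SS_\text{effect}/SS_\text{randME}$, and significance comes
from a permutation scheme that respects the design: REP labels are shuffled
*within* each individual's centered records (systME and the interaction), or
records are shuffled across individuals (individual effect), with
$p = (b+1)/(m+1)$. Effect size is $R^2 = SS_\text{effect}/SS_\text{total}$
with the total taken over the uncentered data, so the individual, systematic
and random components are all reported on one scale. The default 999
permutations and the reporting threshold $\alpha = 0.005$ are conventions of
the study design this package emulates; all p-values are emitted raw.

In a balanced complete grid the type II sums of squares equal the
sequential ones and are order-invariant; tiny-instance correctness is pinned
to explicit design-matrix least-squares oracles in the test suite, not to
any reference implementation.

### EV ordination and the regularization choice

The EV plot projects the individual-mean-centered records onto the
generalized eigenvectors of the systematic-ME scatter relative to the
random-ME scatter — the directions along which bias is largest relative to
noise. There are $R-1$ axes for $R$ REPs, and the reported variance
fractions refer to the systematic-ME subspace only.

Whitening by the random-ME scatter requires inverting a sample covariance
in a 48-dimensional shape space with ~392 residual degrees of freedom. At
that ratio ($p/\nu \approx 0.12$) the eigenvalue noise of the plain
(pseudo-)inverse is substantial, and we found it tilts the leading axis away
from a known injected bias direction by a roughly constant amount (absolute
cosine plateauing near 0.93) *independently of the bias and noise
magnitudes* — the distortion is scale-free. `ev_ordination()` therefore
defaults to Ledoit–Wolf shrinkage of the random-ME covariance toward a
scaled identity, with the shrinkage intensity estimated from the residuals
themselves: when random error is close to isotropic the estimator shrinks
hard and the axis is protected; when it is genuinely anisotropic the
structure is kept. No constant is tuned by hand. `regularize = "none"`
restores the plain pseudo-inverse (tolerance `1e-10` times the largest
eigenvalue) for comparison.

### The time-lag series

`pairwise_timelag_series()` re-runs the 2-REP ME ANOVA for the first
session against each later one, after re-superimposing each pair from raw
coordinates. If digitization drifts with time, systematic ME should be
negligible for same-day pairs and grow with the lag; the series reports
$R^2$, SNR and p per effect ordered by day lag.

## Robustness of biological signal

Within each REP (one record per individual), `permutation_regression()`
fits all tangent coordinates on a single predictor — a sex dummy (F = 0,
M = 1) or centroid size for static allometry — and tests
$R^2 = SS_\text{model}/SS_\text{total}$ via permutation of the predictor.
Sex and size are tested separately, matching the study design. The allometry
predictor is CS on its natural scale; log-CS can be passed by the caller.
`bgpca_crossval()` adds a leave-one-out nearest-group-mean classification in
the full tangent space (equivalent to classifying on the between-group PC
axes), reported as per-group and average hit rates; for two nearly balanced
groups with no real difference the expectation is 50%.

`mixed_design_test()` composes a deliberately flawed sample — each sex from
a different session (single REP, or an average of several; averages are
computed on GPA-aligned coordinates and the composite is always
re-superimposed) — and re-runs the sex and allometry tests. Geometrically,
when the bias is roughly orthogonal to the sex contrast, the biased
between-sex distance is the diagonal of a rectangle whose sides are the true
sex difference and the bias, so a small biological effect is inflated even
by an orthogonal bias; a large effect (allometry, several times the bias) is
barely moved. Congruence across sessions is summarized by the absolute
Pearson correlation of PC1 scores and by correlations of the vectorized
within-REP shape distance matrices (median, 10th, 90th percentiles).

Centroid size cannot enter the coordinate-based ME ANOVA, so session bias
in size is probed by a per-sex repeated-measures ANOVA of CS over REPs
(uncorrected F on $(R-1)$, $(R-1)(n-1)$ df), read against the between-sex
median CS differences.

## Per-landmark absolute imprecision

Because all REPs of an individual digitize the same photograph, raw
coordinates are directly comparable across sessions. For each individual and
landmark, `per_landmark_variances()` sums the sample variances (denominator
$R-1$) of X and of Y across REPs (mm²). Per landmark, the median, 90th
percentile, mean and SD over individuals are computed; medians and 90th
percentiles are each standardized by their own median over landmarks, so a
standardized median of 0.5 reads "half as imprecise as the typical
landmark". Their sum is the combined imprecision index used for
color-coding; the 90th percentile uses linear interpolation (type 7), with
the quantile type exposed because boundary flags can depend on it.

Landmarks exceeding **both** standardized thresholds — strictly above 1.5,
or strictly above 1.0 — are dropped to form the "precise" and "most
precise" configurations; boundary cases are retained, the selection is
nested and monotone in the thresholds, and every reduced configuration is
re-superimposed from raw coordinates before any downstream analysis.
`deviation_cloud()` exports the per-record deviations from each
individual's REP-mean landmark positions, anchored on an arbitrary
reference individual (the choice moves the anchors, not the scatter).

## The synthetic digitization generator

No landmark data are distributed with this package, so the generator is a
first-class module standing in for the unpublished photographs. It emulates
the study conditions: 58 adults (32 F, 26 M), 26 landmarks on a
cranium-like template, 8 REPs at day offsets 1, 1, 2, 4, 11, 41, 121 and
7300. Each individual gets one true shape (template + sex displacement +
allometric deviation proportional to centered log CS + isotropic individual
deviation), one lognormal CS per sex, and one photographic pose (rotation,
translation) reused by all its REPs — deviations in the raw coordinates are
then purely digitization error, as in the real design. Each record adds the
session's bias vector and heteroskedastic per-landmark noise on the raw mm
scale, before any superimposition.

Default magnitudes were fixed once, by Monte-Carlo calibration with
`expected_variance_components()`, to land in the variance regime the study
reports, and are not revisited per analysis:

* `sigma_individual = 0.0085` shape units per coordinate;
* per-landmark noise SDs spanning `sqrt(0.10)` to `sqrt(0.45)` mm (about a
  five-fold range of per-landmark variances, 0.2–0.9 mm²);
* a sex displacement of 0.019 shape units in total (0.010 direct plus an
  allometric component via the ~3.5 mm CS difference between the sexes),
  giving sex $R^2 \approx 2\%$, non-significant at $n = 58$;
* an allometric slope of 0.78 shape units per log-CS, giving within-REP
  allometry $R^2 \approx 11\%$, always significant;
* session biases of 0 / 0.1 / 1.1–1.45 mm (whole-configuration norm) for
  the recent REPs and 2.6 mm for the 20-year-old session, plus small
  per-session CS offsets (±0.5 mm, +1 mm for the oldest), yielding
  individual $R^2 \approx 83\%$, systematic ME $\approx 2\%$
  (SNR $\approx 0.16$), random ME $\approx 13\%$, and a time-lag profile
  that is flat for recent sessions and triples for the oldest.

Effect directions are fixed unit vectors in shape space, constructed
orthogonal to the similarity transformations (translation, scale, rotation)
of the template so that they survive superimposition, and orthogonal to one
another where confounding must be avoided (bias vs sex effect).

What the generator does **not** emulate: repositioning or camera error,
multiple operators, anisotropic or landmark-correlated individual
variation, and outlier digitizations with gross landmark swaps. Individual
variation is isotropic around the template, which makes within-REP PC1 more
stable across sessions than in real crania (where a dominant PC mixes with
session noise); PC1 congruence on synthetic data is therefore optimistic,
while distance-matrix congruence matches the reported regime. Passing tests
on this generator demonstrates that the estimators recover known structure,
not that any particular organism behaves this way.

## Numerical choices and scale of the test problems

GPA converges at `1e-10` on the consensus; ties in classification go to the
first group and are flagged; UPGMA/NN ties follow `hclust`'s deterministic
agglomeration; PCA and EV axes fix signs by forcing the largest-magnitude
loading positive; permutation p-values use $(b+1)/(m+1)$ and every
randomized routine takes an explicit seed (the study driver derives fixed
sub-seeds from one master seed, making reports byte-identical across
reruns). Degenerate inputs — zero-CS configurations, a single REP, constant
predictors, all-zero variances, empty landmark selections — raise
informative errors rather than propagating NaNs.

The simulation studies in the tests and the acceptance script use 200
replicate datasets with 199 permutations for type-I error control, 50
Monte-Carlo replicates for recovery means, and 999 permutations for
single-dataset analyses; these sizes give binomial/Monte-Carlo error well
inside the margins being asserted while keeping a full run in minutes on
one core.

## Known limitations

* Strictly 2D; `LM3=` TPS blocks are rejected by design.
* The ME ANOVA follows the published description of the method (individual
  mean-centering, REP-mean contrasts, type II SS, SNR as an SS ratio);
  numerical parity with any particular software implementation is not
  promised — correctness is defined by the explicit least-squares oracles.
* Unbalanced individual-by-REP grids are accepted but flagged experimental.
* The parametric Goodall-type F treats coordinates as exchangeable and
  equally variable; it is reported alongside, not instead of, the
  permutation tests. A Pillai-trace MANOVA variant is deliberately omitted.
* Semilandmarks, symmetry decompositions, 3D digitizer workflows and
  mixed-model (REML) variance estimation are out of scope.
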