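---
title: "Methods: presence-only habitat suitability modelling with hsmax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only habitat suitability modelling with hsmax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsmax)
```

## The problem

`hsmax` models where a species could live when all we have is a set of
presence records — typically a few dozen GPS-located observations of a rare
plant inside a protected area — together with co-registered environmental
raster layers (climate, soil, topography, land cover, human pressure). The
package implements the complete per-species workflow used in fine-scale
habitat suitability studies: occurrence preparation, environmental-variable
selection, a presence-background maximum-entropy model, tuning and
evaluation, threshold classification, and range-change accounting between
current and future climate scenario stacks.

## The model

The core is a Gibbs distribution over the study-area cells. Each raw
variable $x$ is rescaled to $[0,1]$ by its background minimum and maximum,
then expanded into feature classes: linear $x$, quadratic $x^2$, products
$x_i x_j$, forward and reverse hinges
$\max(0,(x-k)/(1-k))$ and $\max(0,(k-x)/k)$ at evenly spaced interior
knots, and step indicators $x > k$. With feature vector $f(x)$ and weights
$\lambda$, the raw model is

$$\mathrm{raw}(x) = \frac{e^{\lambda' f(x)}}{Z(\lambda)},
\qquad Z(\lambda) = \sum_{\text{background}} e^{\lambda' f(x)},$$

and $\lambda$ minimizes the L1-regularized objective

$$J(\lambda) = -\frac{1}{m}\sum_{\text{presence}} \lambda' f(x_i)
  + \ln Z(\lambda) + \sum_j \beta_j |\lambda_j|,$$

with $\beta_j = \mathrm{RM} \cdot s_j \cdot c(\text{class}, m)$, where
$s_j$ is the presence-sample standard deviation of feature $j$ and the
class constants are $0.05(1 + 10/\sqrt{m})$ for linear, quadratic and
product features, $0.5$ for hinges and $1.0$ for thresholds. The published
interpolation tables of the reference implementation are not reproduced in
print anywhere we could build from, so these constants are a deliberately
simple monotone-in-$m$ substitute; they are configurable, and the shapes
that matter (hinge > linear penalties, penalties growing as $m$ shrinks)
are preserved. $s_j$ is floored at $0.05$ so that degenerate presence sets
(all records in one cell) keep a strictly positive penalty and the optimum
stays finite.

The optimizer is cyclic coordinate descent with an analytic soft-threshold
step on a local quadratic approximation; each proposed step is accepted
only if the exact objective decreases (with up to 20 step halvings), so
the iteration can never diverge. Convergence is declared when the largest
coefficient change in a full sweep is below $10^{-5}$, with a cap of 500
sweeps — the settings reported for the study this package re-implements.
On small instances the fit lands within $10^{-8}$ of an exhaustive
grid-search oracle (see `test-maxent.R`).

Reported suitability uses the cloglog transform
$1 - \exp(-e^{H}\,\mathrm{raw}(x))$, where
$H = -\sum \mathrm{raw}\,\ln \mathrm{raw}$ is the entropy of the fitted
distribution over the background. The transform is monotone, so cell
rankings agree between raw and cloglog maps; the scaling constants and
$Z$, $H$ are frozen at training time and reused verbatim when projecting
to future scenarios.

**Background.** All non-masked study-area cells serve as the background
(about 600 at the default synthetic scale). At protected-area extents this
is both cheaper and more reproducible than random background sampling, and
it makes the raw normalization $\sum \mathrm{raw} = 1$ exact.

## Variable selection

The five-step workflow mirrors common practice with large candidate sets
(up to 46 layers):

1. **Screening and ranking.** Three replicate fits at FC = LQHPT, RM = 1 —
   the first on the full presence set, the others on bootstrap resamples —
   yield mean permutation importance (AUC drop when one variable's values
   are permuted across presence and background rows, normalized to 100)
   and mean percent contribution (objective-improvement credit accumulated
   along the optimization path). Replicate refits matter: with strongly
   collinear predictors an L1 fit commits near-arbitrarily to one member
   of a correlated group, and averaging over resamples lets the variable
   that genuinely carries signal come out ahead.
2. **Contribution cut.** Variables with mean contribution below 1% are
   dropped.
3. **Pearson filter.** Pairs with $|r| \ge 0.8$ are processed in
   descending $|r|$; in each pair still intact, the lower-ranked variable
   is dropped.
4. **VIF elimination.** While any variance inflation factor
   $1/(1-R^2_j)$ exceeds 5, the worst variable is removed and VIFs are
   recomputed.
5. **Top-5.** The five highest-ranked survivors (by permutation
   importance) become the final predictors.

**Which values feed the collinearity filters?** By default the Pearson and
VIF computations use the background cells, not the occurrence matrix
(`cor_data = "presence"` restores the alternative). Collinearity is a
property of the environmental layers over the landscape. Measured on
synthetic landscapes with known structure, presence-point correlations at
$n = 60$ are range-restricted — pairs built at $r = 0.92$ can fall below
the 0.8 cut, letting a redundant shadow variable through so that the VIF
step then removes the true driver — and conversely acquire spurious
correlation between genuinely independent drivers, because presences
concentrate where one is high and the other low. Both pathologies
disappear when the filters see the full landscape.

## Tuning and evaluation

The regularization multiplier sweeps 0.5–4.0 in steps of 0.5 and the
feature classes sweep {L, LQ, H, LQH, LQHP, LQHPT}: 48 combinations. Each
is fitted on all presences and scored by the sample-size-corrected AIC,
computed from raw predictions standardized to sum to one over the study
cells, with $k$ the number of nonzero weights:
$\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$ (undefined rows,
$n \le k+1$, are excluded from ranking). The combination with
$\Delta\mathrm{AICc} = 0$ wins; ties break toward smaller $k$, then larger
RM.

Replicate evaluation follows the bootstrap scheme: per replicate the
training set is a with-replacement resample of $\lceil 0.75 n \rceil$
presences, the test set the never-drawn points, and we record training and
test AUC (rank-based, ties half-credited, all background cells as the
negative class), their difference (an overfitting signal when above 0.1),
and the 10% training omission rate (fraction of test presences strictly
below the interpolated 10th percentile of training scores). Each tuning
row also carries these metrics averaged over a configurable number of
replicates — 3 by default during the grid sweep, versus 10 for the
selected combination — because 48 × 10 refits would dominate runtime
while the grid only needs the metrics for reporting, not for the
AICc-based choice.

## Thresholding, classification, range change

The binarization threshold is the maximum test sensitivity plus
specificity (MTSPS): per replicate, candidate thresholds sweep the union
of observed test and background scores, sensitivity counts test presences
at or above the candidate, specificity counts background cells below it,
and the lowest maximizer is taken; the final threshold is the mean over
replicates, reported to 4 decimals. Suitability $p$ is then cut into four
classes — unsuitable $p < t$, then three equal-width classes low,
moderate, high on $[t, 1]$ with boundaries $t + (1-t)/3$ and
$t + 2(1-t)/3$. Intervals are lower-closed, upper-open, with the top
class closed at 1, so every cell lands in exactly one class.

Range change cross-tabulates current and future binary maps:
loss ($1\to0$), stable ($1\to1$), gain ($0\to1$);
$\%\mathrm{Loss} = 100\,L/(L+S)$, $\%\mathrm{Gain} = 100\,G/(L+S)$,
$\mathrm{SRC} = \%\mathrm{Gain} - \%\mathrm{Loss}$ (an identity asserted
before rounding on every call), and the current range size
$\mathrm{CRS} = L + S$. Cell counts convert to km² at a configurable cell
area whose default, $25/36 \approx 0.6944$ km², is back-derived from the
study tables this pipeline replicates (315.28 km² / 454 cells), which is
self-consistent across every table we checked, unlike the nominal
"$\simeq$ 0.86 km² at the equator" description. Percentages and km² are
rounded half-away-from-zero to 2 decimals, thresholds and class
boundaries to 4 — matching the printed precision conventions.

## The synthetic landscape generator

Because the original occurrence database and downloaded rasters are not
redistributable, every stage is exercised on synthetic data built by the
package itself:

* **Layers** are Gaussian random fields — white noise convolved with an
  isotropic Gaussian kernel (default lengths: 4 cells for the 19
  climate-like layers, 3 for the 11 soil layers, 5/2/2 for elevation,
  slope, aspect, 1.5 for the 12 land-cover layers, 2 for human pressure) —
  standardized over the usable cells of a 25 × 25 grid at 30 arc-seconds,
  with 6 cells clipped from each corner (601 usable cells, mirroring the
  ~595-cell study area). A target correlation matrix, when given, is
  imposed by empirically orthogonalizing the fields and mixing with the
  symmetric square root of the target, so realized correlations track the
  targets closely.
* **Truth** is the inverse logit of a linear (optionally quadratic)
  predictor over named layers. The recovery experiments use two drivers
  with coefficients $+3$ and $-3$ and intercept $-6$: a rare, sharply
  defined niche (roughly 8% of cells highly suitable) whose Bayes-optimal
  AUC is about 0.92 — the "good to excellent" regime the real models this
  workflow targets operate in. Weaker signals were examined and rejected
  at design time because their optimal AUC (below 0.81) sits under the
  evaluation bars any competent fit is expected to clear.
* **Occurrences** are cells drawn without replacement with probability
  proportional to suitability, each point then placed uniformly within its
  cell. Goodness-of-fit of draw frequencies is tested by exact binomial
  intervals and chi-square.
* **Future stacks** shift only `BIO*` layers (constant shift plus a smooth
  Gaussian noise field); all other layers are carried over bit-identically,
  and that invariance is asserted layer by layer.

What the generator does *not* emulate: observation bias (roads, trails),
positional error, non-stationary covariance between layers, and the heavy
spatial clustering of real botanical records. Passing tests therefore
certify the machinery and its arithmetic, not field performance on real
occurrence databases.

## Numerical choices and edge cases

* Haversine distances with $R = 6371$ km; spatial thinning removes, per
  randomized run, one of the points with the most neighbours closer than
  `thin_par_km` (ties uniform at random), and the best of `reps = 100`
  runs is kept. Distances in degrees use half-open cells
  $[x, x+\text{cs}) \times [y, y+\text{cs})$, so points on the extreme
  top/right extent are outside.
* Exact-coordinate deduplication only; no snap tolerance.
* Zero-variance variables are dropped from the feature design with a
  warning; features whose local curvature vanishes use a floor of
  $10^{-8}$ in the Newton denominator.
* Along an L1 regularization path the *count* of active features is not
  monotone in RM (a 3 → 4 step between RM 0.5 and 1 occurs on legitimate
  data); the L1 *norm* of the optimum is, and that is what the shrinkage
  test asserts.
* Bootstrap replicates with an empty out-of-bag test set are redrawn.
* Percent increase/decrease of a class empty at present is reported as a
  flagged `NA`, not a number.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
25 × 25 landscapes (601 usable cells), 30–60 presences per species, 8–14
environmental layers for the recovery and demo experiments, 20 replicate
landscapes for the recovery study, and the full 48-combination grid in the
end-to-end demo. These sizes were chosen so a complete run is a
desk-scale computation while still exercising every operation at the
study's own grid resolution and sample sizes.

## Known limitations

* The per-class regularization constants approximate, not reproduce, the
  reference implementation's interpolation tables; fitted weights will
  differ from reference software even on identical data, though tuning
  rankings are driven by relative, not absolute, penalties.
* Variable recovery under near-duplicate collinearity has a hard
  information limit: with shadow variables mixed at $r = 0.92$ and 60
  presences, even exhaustive likelihood comparison identifies the true
  driver pair in only about 60% of landscapes, and no selection heuristic
  can do materially better. The workflow's value there is honest
  bookkeeping — every drop decision is logged with the statistic that
  caused it — not clairvoyance.
* No reprojection or geodesy beyond haversine; rasters must arrive
  co-registered. No categorical feature support.
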