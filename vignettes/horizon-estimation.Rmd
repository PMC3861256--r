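---
title: "Estimating the horizon in outdoor scenes: models, ground truth, and evaluation"
author: "skyline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the horizon in outdoor scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skyline)
```

## The problem

The *astronomical horizon* of a photograph is the image row where the plane
perpendicular to gravity at the camera's eye height projects. It is a
compact, one-dimensional summary of camera viewpoint: everything physically
above the camera appears above it, everything below appears below,
regardless of terrain slant or occluders. Human observers extract an
estimate of this row within the first glance at a scene; `skyline`
implements a family of machine estimators of the same quantity from single
visual cues, plus one holistic estimator, and evaluates all of them against
*ground-truth densities* built from sets of human (here: simulated)
estimates rather than against a single "correct" row.

The reason for a density rather than a point target is substantive: on a
clean coastal scene the horizon is visually unambiguous and deviations
should be penalized sharply, while on a closed forest scene even careful
observers disagree, and an estimator should not be punished for landing
anywhere inside that band of disagreement. The density encodes exactly
this image-specific tolerance.

Coordinates throughout are normalized vertical positions in $[0,1]$ with 0
at the top edge and 1 at the bottom edge of the full upright image; the
center of pixel row $r$ (0-based) of an $H$-row image sits at
$(r + 0.5)/H$. The 0-at-top choice follows raster convention.

## Ground-truth densities

For one image with $n$ retained estimates $y_1,\dots,y_n$ the ground truth
is the Gaussian kernel density

$$p(y) = \frac{1}{n\,h\,\sqrt{2\pi}} \sum_{i=1}^n
  \exp\!\left(-\frac{(y - y_i)^2}{2h^2}\right),\qquad
  h = n^{-1/(d+4)}\,\hat\sigma,\; d = 1,$$

with $\hat\sigma$ the sample standard deviation ($n-1$ denominator,
matching the covariance estimator of the usual scientific-Python KDE) and
$n^{-1/5}$ Scott's factor. An evaluation $p(y^\ast)$ at an estimate
$y^\ast$ is called a *confidence*; it is a density value and routinely
exceeds 1 for tight estimate sets. Two numerical choices:

* **Bandwidth floor 0.005.** Real raters always disagree a little, but the
  synthetic generator can emit zero-spread estimate sets; the floor keeps
  the density defined. At the floor, a unanimous set at $y_0$ has
  $p(y_0) = 1/(0.005\sqrt{2\pi}) \approx 79.8$.
* **Outlier filtering** is a single pass: estimates more than three sample
  standard deviations from the per-image mean are dropped; with zero
  spread nothing is dropped. Note a finite-sample fact that matters for
  calibration: with $n = 12$ the sample z-score is bounded by
  $(n-1)/\sqrt{n} \approx 3.18$, so ideal Normal raters essentially never
  trip the filter — its removals on real data come from non-Normal errors
  (lapses, misclicks), which is precisely what it is for. The filter is
  therefore far more conservative than the naive population-3$\sigma$
  expectation of 0.3% removals.

## Single-cue estimators

Each per-row estimator consumes exactly one channel of the CIE L\*a\*b\*
decomposition (standard sRGB $\to$ XYZ (D65) $\to$ L\*a\*b\* transform) and
returns a non-negative confidence per image row; the readout is
winner-takes-all, $(\arg\max_r + 0.5)/H$, with exact ties broken toward
the row nearest the image center, then toward the smaller index (the tie
rule is this package's choice; ties essentially only arise on degenerate
inputs such as constant images).

* **div / ndiv** — tests each row boundary for how well it splits the
  channel into a light region above and dark region below (the daytime
  sky/ground prior). Global term: difference of the mean values above and
  below the boundary. Local term: column-mean absolute vertical derivative
  at the boundary after Gaussian smoothing. Both terms are min–max
  normalized over boundaries before the linear mix
  $(1-w)\,\hat g + w\,\hat l$, which makes the mixing weight $w$
  scale-free. `ndiv` flips the sign of the global term (dark above). The
  difference-of-means formalization and the min–max normalization are
  design choices of this package; boundary 0 (nothing above) scores 0.
* **lin** — sums $|S(r+1,c) - S(r,c)|$ over columns of the smoothed
  channel; the vertical gradient is a forward difference between adjacent
  rows, reported at the boundary between them, with the final row padded
  by 0.
* **gab** — convolves with a horizontally oriented Gabor quadrature pair
  and sums the response magnitude per row. The even kernel is recentred to
  zero mean so constant images give zero response; the envelope support is
  truncated at 2.5 envelope SDs and additionally capped at the image
  half-size so extreme wavelength/selectivity settings stay computable.
* **van** — Canny edge detection (Gaussian smoothing, Sobel gradients,
  non-maximum suppression, double-threshold hysteresis), then a Hough
  transform in which each edge pixel votes with its gradient magnitude, so
  line strength reflects both edge response and length. Lines within 5°
  of the image vertical are discarded — they cross rows almost uniformly
  and only add noise. The strongest `nLines` (default 20) accumulator
  peaks are selected under non-maximum suppression in $(\rho,\theta)$
  (radius 2 bins each way), because a single physical line otherwise
  reappears as a stack of near-duplicate cells that drowns the true
  crossing. Selected lines are drawn binarily (one vote per crossed
  pixel), elongated across the whole image, with intensity proportional to
  relative strength; the profile is the per-row sum of accumulator pixels
  raised to `exponentRho` (default 2), which emphasizes rows where many
  strong lines intersect — vanishing-point candidates.
* **dum1 / dum2** — random guessing from a uniform interval (intersected
  with $[0,1]$) or a clamped Normal; by signature they never see pixels.
  They bound achievable chance performance.

All spatial filtering uses explicit reflection-padded convolution. This
keeps boundary handling under exact control (blur preserves the image mean
to well under 0.5%) and lets brute-force double-loop oracles in the test
suite reproduce the arithmetic to $10^{-9}$.

## The holistic pathway

The spatial-envelope descriptor resizes each channel to 64×64, applies a
bank of oriented band-pass filters (one-sided log-Gabor transfer functions
in the frequency domain, DC bin zeroed; default 4 scales × 8
orientations), and averages response magnitudes over a 4×4 grid,
concatenating across the three channels (length $3 \cdot 4 \cdot 8 \cdot
16 + 1 = 1537$ with the appended intercept).

The regressor is a cluster-weighted mixture: each of $K$ components owns a
linear regressor from the descriptor to the horizon plus a diagonal
Gaussian gate in a PCA-reduced descriptor space (default 64 dimensions,
basis fitted on training data only). EM responsibilities combine mixing
prior, gate density and target likelihood; the M-step solves
ridge-stabilized ($\lambda = 10^{-6}$) weighted least squares, in dual
(kernel) form when descriptor dimensions exceed the sample count, which
they typically do here. The gating scheme is a documented assumption of
this package — with constant priors instead of feature-dependent gates the
mixture cannot route images to components at prediction time, so
cluster-weighted gating is the natural completion. Numerical floors: gate
and noise SDs at $10^{-4}$; with the tiny ridge these floors can in
principle break exact EM monotonicity, so the test suite asserts
non-decrease of the log-likelihood to within $10^{-8}$. Restarts are
seeded k-means initializations; the best final log-likelihood wins.
Predictions are responsibility-weighted component outputs clamped to
$[0,1]$ with a `clamped` attribute.

Because evaluating one [gst] parameter setting requires training, the
tuner wraps every evaluation in an inner 3-fold cross-validation. The
tunable parameters are $K$ and the gating dimensionality; the descriptor's
scales/orientations/grid are held fixed within a tune run (changing them
invalidates every cached descriptor) and exposed as function arguments
instead.

## Conditions and coordinate algebra

Six stimulus conditions: `norm` (identity), `inverted` (vertical mirror),
`blurred` (Gaussian, SD = 1% of image height by default, scaling with
image size), and the `lower`/`middle`/`upper` subwindows keeping the
lower, middle or upper two-thirds of the rows (removing $\lfloor H/3
\rfloor$ from the top, $\lfloor H/6 \rfloor$ from top and bottom, or
$\lfloor H/3 \rfloor$ from the bottom — floor rounding, remainder rows
staying with the kept block). Subwindows then drop columns alternately
from the left and right border (starting side by a seeded coin flip;
"random" in the original procedure) until the aspect ratio matches the
original within one column.

Every conditioned image carries an affine `CoordinateMap`
($y_{\text{full}} = \text{offset} + \text{scale}\cdot y_{\text{window}}$,
mirror first when flipped) so estimates made in a window are comparable in
full-image coordinates. Estimates mapping outside $[0,1]$ are clamped and
flagged rather than discarded — the original procedure does not say which
was done; clamping keeps every image scored.

One wording note: a Gaussian convolution is a low-pass filter, so the
blurred condition removes *high* spatial frequencies (fine detail) while
leaving the holistic impression intact; descriptions of it as removing
low-frequency information are treated as an erratum.

## Synthetic scenes and simulated raters

The generator renders landscape-format outdoor-like scenes whose
astronomical horizon is known exactly by construction, with the first
ground row at $\lfloor t\,H \rfloor$ for true horizon $t$. Per-class
recipes follow the difficulty ordering seen in human raters:

* `coast`: clean two-tone sky/ground split with a mild sky gradient
  (easiest; the division cue is maximally informative);
* `open_country`: split plus low-amplitude ground luminance undulation;
* `forest` / `enclosed_nature`: split heavily occluded by dark vertical
  strips crossing the horizon;
* `non_urban_street` / `city`: split plus a perspective bundle of lines
  drawn exactly through a vanishing point on the horizon row (city: more,
  stronger lines);
* `other`: the base split with moderate occluders and a weak bundle.

Corpus horizons are drawn uniformly from the middle third $[1/3, 2/3]$,
mirroring the stimulus-selection rule of the human experiments (it avoids
border-click bias and keeps subwindow conditions from cropping the horizon
away). The default class mix is proportional to the stimulus-set counts
32/29/18/46/16/47/12.

Simulated raters draw from a Normal centred on the true horizon, truncated
to $[0,1]$ by rejection, with a per-draw contamination probability
(default 0.02) of a Uniform$[0,1]$ guess — a rare attentional lapse. The
default per-class spreads (coast 0.01; non-urban street 0.02; city 0.025;
other 0.03; open country/forest/enclosed nature 0.04 normalized units)
are free parameters of the generator chosen once to reproduce the
*ordering* "coast far tighter than closed natural scenes, streets in
between"; the human per-class magnitudes are not available to
machine-read, so no claim is made beyond the ordering. Twelve raters per
image is the default, matching the reference experiment's design.

What the generator does *not* emulate: photographic texture statistics,
cast shadows, sky gradients from atmospheric scattering, camera roll,
photographer's framing bias, and rater biases that depend on condition
order or fatigue. Passing tests on this corpus therefore demonstrate that
the estimators, scoring and tuning machinery are correct and that the
relative orderings the cues imply hold where the cues are present by
construction — not that any estimator attains a particular accuracy on
photographs.

## Tuning and evaluation

Images are split into $k$ folds (default 10) by a seeded hill-climb over
pairwise swaps that minimizes, per fold, the L1 deviation of class
proportions from the global proportions plus the absolute deviation of
the fold's mean *peak* ground-truth density (computed on a 401-point
grid) from the global mean, the density term standardized by the global
SD of peaks so both terms are unitless with equal weight. Swaps that do
not strictly decrease the objective are rejected, so it is monotone. The
peak-density summary is this package's reading of "mean ground truth
density" as a per-image difficulty proxy; the per-image mean density over
a grid would be dominated by the near-zero tails.

For each fold, parameters are tuned on the other folds (normal condition)
by seeded uniform/log-uniform random search followed by Nelder–Mead
refinement from the best draws (integers relaxed during refinement and
rounded at evaluation; the recorded best never falls below the best random
draw). The training objective is the evaluation measure itself: the mean
ground-truth density value at the estimated position. Dummy objectives are
averaged over 10 seeded runs. Cross-validation then scores every image
exactly once with the parameter set tuned without its fold, applying the
requested condition transform before estimation and mapping the estimate
back to full coordinates.

Behavior comparison: a source's "behavior" is its 13-cell vector of mean
confidences — 6 condition means followed by 7 scene-type means — and two
sources are compared by Pearson correlation across cells. The 13 marginal
cells (rather than the 42 crossed cells, available behind `crossed =
TRUE`) match how per-condition and per-scene-type means are reported and
compared. The human reference in the synthetic pipeline is a clearly
labeled synthetic stand-in: one quick-viewing estimate per image and
condition with class spread inflated per condition (inversion and blur
hardest). Inter-rater reliability uses the Shrout–Fleiss two-way
random-effects intraclass correlations,

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},\qquad
\mathrm{ICC}(2,k) = \frac{MS_R - MS_E}{MS_R + \tfrac{1}{n}(MS_C - MS_E)},$$

computed on complete rows only (any do-not-know response drops the whole
image). Routine group-comparison statistics (ANOVA with post-hoc
criteria) are deliberately out of scope; base R provides them directly on
the exported confidence tables.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full chain at reduced
scale chosen to exercise every code path with comfortable margins: corpora
of 100–300 images at 64×48 to 96×72 pixels, 5–10 folds, random-search
budgets of 4–60 draws with 0–2 refinement starts. These sizes are the
package's own defaults for its self-checks; all functions scale to larger
corpora linearly in images × pixels. Every stochastic step (rendering,
raters, fold assignment, search, dummies, EM restarts) takes an explicit
seed, and derived child seeds are hashed from labeled streams, so equal
seeds give byte-identical outputs and no call disturbs the caller's RNG
state.

## Example

```{r example, eval = FALSE}
corpus <- makeCorpus(60, seed = 1)
densities <- lapply(corpus, function(x)
  fitDensity(removeOutliers(x$estimates)))
names(densities) <- names(corpus)
folds <- stratifiedFolds(corpus, densities, k = 5, seed = 2)
tuned <- tuneAlgorithm("lin", "L", corpus, densities, folds,
                       budget = list(nRandom = 25, nRefineStarts = 1,
                                     refineMaxIter = 40), seed = 3)
cv <- crossValidate("lin", "L", corpus, densities, folds, tuned)
mean(cv$confidence)
```

## Known limitations

* The vanishing-point cue localizes one-pixel-wide synthetic lines via
  the Canny ridges on either side, so recovered intersections can shift
  by a couple of rows; on thicker real edges this effect is smaller.
* The mixture's EM maximizes a ridge-penalized surrogate with variance
  floors; monotonicity is asserted only to numerical tolerance.
* PNG is the only raster format read or written (lossless and
  sufficient for the synthetic pipeline).
* The behavior-correlation reference is simulated; correlations against
  it validate the machinery, not human similarity of any algorithm.
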