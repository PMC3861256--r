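# skyline

Horizon estimation in outdoor scenes: single-cue machine estimators, a
holistic regressor, and human-referenced evaluation.

## What this is for

The **astronomical horizon** of a photograph — the image row where the
gravity-perpendicular plane at eye height projects — is a compact summary
of camera viewpoint. Human observers extract it within the first glance;
computer-vision systems use it as a prior for object scale and scene
geometry. `skyline` is for researchers in visual psychophysics and scene
perception who want to ask *which low-level cues suffice* to estimate it:
the package implements a family of per-row cue estimators, an end-to-end
evaluation against per-image "ground-truth densities" built from sets of
human estimates, and the behavior-comparison statistics needed to relate
machine and human patterns across stimulus manipulations and scene types.

Estimators (each returns a per-row confidence; the readout is
winner-takes-all, `(argmax + 0.5)/H`):

| name | cue |
|------|-----|
| `div` / `ndiv` | how well a row splits the channel into a light region above and a dark region below (or the reverse): a weighted mix of a global difference-of-means term and a local smoothed vertical-gradient term |
| `lin` | column-summed absolute vertical gradient |
| `gab` | per-row energy of a horizontally oriented Gabor quadrature pair |
| `van` | vanishing points: Canny edges, magnitude-weighted Hough lines (near-vertical lines excluded, accumulator peaks deduplicated), lines re-drawn full-length into a vote image; per-row sum of votes raised to an exponent |
| `gst` | spatial-envelope (GIST-style) descriptor over all three L\*a\*b\* channels feeding an EM-trained cluster-weighted mixture of linear regressors; returns a position directly |
| `dum1` / `dum2` | random guessing (uniform interval / clamped normal) — the chance floor |

Scoring: for each image, a Gaussian kernel density over normalized
vertical position is fitted to the (outlier-filtered) human estimates
with Scott's-factor bandwidth `h = n^(-1/5) * sd`,

```
p(y) = 1/(n h sqrt(2 pi)) * sum_i exp(-(y - y_i)^2 / (2 h^2))
```

and an estimate's **confidence** is `p(y*)` — a density value, so tight
estimate sets give values well above 1. Hyperparameters are tuned per
fold (stratified k-fold by scene class and peak density) by random
search plus Nelder–Mead, maximizing mean confidence on the training
folds; evaluation is on the left-out folds, optionally under the six
stimulus conditions (`norm`, `inverted`, `blurred`, `lower`, `middle`,
`upper`), with estimates mapped back to full-image coordinates.

Because no image corpus or human estimate set is distributed, the
package ships a synthetic generator: outdoor-like scenes with exactly
known horizons (sky/ground splits, occluders, perspective bundles; seven
scene-class recipes) and simulated raters with class-dependent spread.
See the vignette (`vignettes/horizon-estimation.Rmd`) for the models,
the recipes, and what the synthetic conditions do and do not show.

## Worked example

```r
library(skyline)

corpus <- makeCorpus(60, seed = 1, width = 64, height = 48)
densities <- lapply(corpus, function(x)
  fitDensity(removeOutliers(x$estimates)))
names(densities) <- names(corpus)

folds <- stratifiedFolds(corpus, densities, k = 5, seed = 2)
tuned <- tuneAlgorithm("lin", "L", corpus, densities, folds,
                       budget = list(nRandom = 25, nRefineStarts = 1,
                                     refineMaxIter = 40), seed = 3)
cv <- crossValidate("lin", "L", corpus, densities, folds, tuned)
mean(cv$confidence)
#> [1] 8.296248

dumT <- tuneAlgorithm("dum1", "L", corpus, densities, folds,
                      budget = list(nRandom = 25, nRefineStarts = 1,
                                    refineMaxIter = 40), seed = 3)
mean(crossValidate("dum1", "L", corpus, densities, folds, dumT,
                   seed = 4)$confidence)
#> [1] 3.075009
```

Reading the numbers: the vertical-gradient cue's estimates land where the
simulated raters concentrate (mean density ≈ 8.3 — for reference, a
rater set with spread 0.03 peaks near 9), while informed guessing only
reaches the density's background level (≈ 3.1). The gap is the
information the cue extracts from the image.

A thin CLI wraps the same functions
(`inst/exec/skyline synth|estimate|run`), e.g.
`Rscript inst/exec/skyline run --n 60 --algos lin,dum1 --out run1`.

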