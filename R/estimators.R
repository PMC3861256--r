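## Single-cue per-row horizon estimators and their readout.
##
## Every estimator consumes exactly one image channel (a numeric matrix)
## and returns a ConfidenceProfile: one non-negative confidence per image
## row that the horizon lies there. Confidence indices are 0-based row
## boundaries; the winner-takes-all readout reports the center of the
## winning row, (argmax + 0.5) / H, in normalized coordinates.

#' Estimator parameter constructors
#'
#' Validated parameter bundles for the single-cue estimators and the
#' random-guessing baselines.
#'
#' * `divParams`: the light/dark division cue. `smoothingSigma` (pixels)
#'   smooths before the local gradient term; `localWeight` in [0, 1] mixes
#'   the global concentration term (weight `1 - localWeight`) with the
#'   local vertical-gradient term.
#' * `gaborParams`: horizontal Gabor energy. `wavelength` (pixels),
#'   `bandwidth` (octaves), `selectivity` (spatial aspect ratio; smaller is
#'   more orientation-selective).
#' * `vanParams`: vanishing-point voting. Canny smoothing sigma and low /
#'   high magnitude thresholds; Hough rho (pixels) and theta (radians)
#'   resolutions; `nLines` retained Hough peaks; `exponentRho >= 1`
#'   emphasizing accumulator maxima; `verticalExclusionDeg` excluding
#'   near-image-vertical lines, which cross rows almost uniformly and only
#'   add noise.
#' * `dummyParams`: `kind = "uniform"` draws from
#'   `[center - halfWidth, center + halfWidth]` intersected with [0, 1];
#'   `kind = "normal"` draws from `Normal(mean, sd)` clamped to [0, 1].
#'
#' @param smoothingSigma,localWeight,wavelength,bandwidth,selectivity
#'   see above.
#' @param cannySigma,cannyLow,cannyHigh,houghRho,houghTheta,nLines see
#'   above.
#' @param exponentRho,verticalExclusionDeg,kind,center,halfWidth,mean,sd
#'   see above.
#' @return a named list of validated parameters.
#' @name estimatorParams
NULL

#' @rdname estimatorParams
#' @export
divParams <- function(smoothingSigma = 1, localWeight = 0.5) {
  assertScalarIn(smoothingSigma, "smoothingSigma", 0, Inf)
  assertScalarIn(localWeight, "localWeight", 0, 1)
  list(smoothingSigma = smoothingSigma, localWeight = localWeight)
}

#' @rdname estimatorParams
#' @export
gaborParams <- function(wavelength = 8, bandwidth = 1, selectivity = 0.3) {
  assertScalarIn(wavelength, "wavelength", 1e-9, Inf)
  assertScalarIn(bandwidth, "bandwidth", 1e-9, Inf)
  assertScalarIn(selectivity, "selectivity", 1e-9, Inf)
  list(wavelength = wavelength, bandwidth = bandwidth,
       selectivity = selectivity)
}

#' @rdname estimatorParams
#' @export
vanParams <- function(cannySigma = 1.4, cannyLow = 2, cannyHigh = 6,
                      houghRho = 1, houghTheta = pi / 180, nLines = 20,
                      exponentRho = 2, verticalExclusionDeg = 5) {
  assertScalarIn(cannySigma, "cannySigma", 0, Inf)
  if (cannyLow >= cannyHigh) {
    stop("'cannyLow' must be smaller than 'cannyHigh'", call. = FALSE)
  }
  assertScalarIn(exponentRho, "exponentRho", 1, Inf)
  assertScalarIn(nLines, "nLines", 1, Inf)
  list(cannySigma = cannySigma, cannyLow = cannyLow, cannyHigh = cannyHigh,
       houghRho = houghRho, houghTheta = houghTheta,
       nLines = round(nLines), exponentRho = exponentRho,
       verticalExclusionDeg = verticalExclusionDeg)
}

#' @rdname estimatorParams
#' @export
dummyParams <- function(kind = c("uniform", "normal"), center = 0.5,
                        halfWidth = 0.25, mean = 0.5, sd = 0.1) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    lo <- max(0, center - halfWidth); hi <- min(1, center + halfWidth)
    if (lo > hi) stop("uniform interval does not intersect [0, 1]",
                      call. = FALSE)
    list(kind = kind, center = center, halfWidth = halfWidth)
  } else {
    assertScalarIn(sd, "sd", 0, Inf)
    list(kind = kind, mean = mean, sd = sd)
  }
}

.assertChannel <- function(channel) {
  if (!is.matrix(channel) || !is.numeric(channel)) {
    stop("estimators consume exactly one channel: pass a numeric matrix, ",
         "e.g. labChannel(toLab(image), \"L\")", call. = FALSE)
  }
  if (nrow(channel) < 2L) stop("channel must have >= 2 rows", call. = FALSE)
  invisible(channel)
}

minmaxNorm <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Division cue: light region above, dark region below
#'
#' Scores each row boundary r by how well it splits the channel into a
#' light region above and a dark region below. The global term is the
#' difference of means above/below the boundary; the local term is the
#' column-mean absolute vertical derivative at the boundary after Gaussian
#' smoothing. Both are min-max normalized over boundaries and mixed
#' linearly: `(1 - localWeight) * global + localWeight * local`. Boundary 0
#' (nothing above) is assigned 0. `polarity = "dark_above"` exchanges light
#' and dark — the sign of the global term flips.
#'
#' @param channel numeric matrix, one channel.
#' @param params a [divParams()] list.
#' @param polarity `"light_above"` (the sky-is-brighter cue) or
#'   `"dark_above"`.
#' @param channelTag optional label stored in the profile.
#' @return a [ConfidenceProfile-class] of length `nrow(channel)`.
#' @examples
#' img <- makeScene(sceneSpec("coast", 0.5, seed = 1))
#' p <- profileDiv(labChannel(toLab(img), "L"), divParams(localWeight = 0))
#' winnerTakesAll(p)
#' @export
profileDiv <- function(channel, params = divParams(),
                       polarity = c("light_above", "dark_above"),
                       channelTag = "") {
  .assertChannel(channel)
  polarity <- match.arg(polarity)
  h <- nrow(channel); w <- ncol(channel)
  rs <- rowSums(channel)
  cum <- cumsum(rs)
  tot <- cum[h]
  r <- seq_len(h - 1L)                       # 0-based boundaries 1..H-1
  g <- cum[r] / (r * w) - (tot - cum[r]) / ((h - r) * w)
  if (polarity == "dark_above") g <- -g
  s <- smoothGaussian(channel, params$smoothingSigma)
  l <- rowMeans(abs(s[r + 1L, , drop = FALSE] - s[r, , drop = FALSE]))
  vals <- c(0, (1 - params$localWeight) * minmaxNorm(g) +
                 params$localWeight * minmaxNorm(l))
  methods::new("ConfidenceProfile", values = vals, channel = channelTag)
}

#' Vertical-gradient cue
#'
#' Sums the absolute vertical derivative of the (optionally smoothed)
#' channel over columns: `profile[r] = sum_c |S(r+1, c) - S(r, c)|`, with
#' the final row padded with 0. Around the horizon the difference between
#' neighboring rows is expected to be greatest.
#'
#' @param channel numeric matrix, one channel.
#' @param smoothingSigma Gaussian smoothing SD in pixels (0 = none).
#' @param channelTag optional label stored in the profile.
#' @return a [ConfidenceProfile-class].
#' @export
profileLin <- function(channel, smoothingSigma = 1, channelTag = "") {
  .assertChannel(channel)
  s <- smoothGaussian(channel, smoothingSigma)
  h <- nrow(s)
  d <- abs(s[-1L, , drop = FALSE] - s[-h, , drop = FALSE])
  methods::new("ConfidenceProfile", values = c(rowSums(d), 0),
               channel = channelTag)
}

#' Horizontal Gabor energy cue
#'
#' Convolves the channel with a horizontally oriented Gabor quadrature pair
#' (reflection boundary) and sums the response magnitude per row — a
#' biologically motivated detector of horizontal structure.
#'
#' @param channel numeric matrix, one channel.
#' @param params a [gaborParams()] list.
#' @param channelTag optional label stored in the profile.
#' @return a [ConfidenceProfile-class].
#' @export
profileGab <- function(channel, params = gaborParams(), channelTag = "") {
  .assertChannel(channel)
  if (params$wavelength > nrow(channel)) {
    stop("Gabor wavelength exceeds the image height", call. = FALSE)
  }
  ## the envelope support is capped at the image half-size so extreme
  ## wavelength/selectivity settings stay computable; the kernel remains
  ## zero-mean after truncation
  k <- gaborKernel(params$wavelength, params$bandwidth,
                   params$selectivity, orientationDeg = 90,
                   maxRadius = floor(min(dim(channel)) / 2))
  re <- conv2Reflect(channel, k$even)
  im <- conv2Reflect(channel, k$odd)
  mag <- sqrt(re^2 + im^2)
  methods::new("ConfidenceProfile", values = rowSums(mag),
               channel = channelTag)
}

#' Vanishing-point cue via Canny + Hough line voting
#'
#' Detects edges with the Canny filter, finds lines and their strengths
#' with a magnitude-weighted Hough transform, discards lines within
#' `verticalExclusionDeg` of the image vertical, selects the strongest
#' `nLines` accumulator peaks under non-maximum suppression (so one
#' physical line is retained once, not as a stack of near-duplicate
#' cells), and draws the selected lines — elongated across the whole image — additively into an
#' empty accumulator image with intensity proportional to relative line
#' strength. Rows where many strong lines meet accumulate bright spots
#' (vanishing-point candidates); maxima are emphasized by raising
#' accumulator pixels to `exponentRho` before summing per row.
#'
#' @param channel numeric matrix, one channel (at least 16 x 16).
#' @param params a [vanParams()] list.
#' @param channelTag optional label stored in the profile.
#' @return a [ConfidenceProfile-class]; all-zero when no edges survive.
#' @export
profileVan <- function(channel, params = vanParams(), channelTag = "") {
  .assertChannel(channel)
  h <- nrow(channel); w <- ncol(channel)
  if (h < 16L || w < 16L) {
    stop("vanishing-point estimation needs at least a 16 x 16 image",
         call. = FALSE)
  }
  ce <- cannyEdges(channel, params$cannySigma, params$cannyLow,
                   params$cannyHigh)
  hl <- houghLines(ce$edges, ce$magnitude, params$houghRho,
                   params$houghTheta)
  acc <- hl$accumulator
  ## a vertical image line has its normal along x, i.e. theta near 0
  excl <- params$verticalExclusionDeg * pi / 180
  acc[, abs(hl$theta) < excl] <- 0
  votes <- voteImage(acc, hl$rho, hl$theta, params$nLines, h, w)
  methods::new("ConfidenceProfile",
               values = rowSums(votes^params$exponentRho),
               channel = channelTag)
}

## Greedy Hough peak selection with non-maximum suppression: picking a
## cell zeroes its (rho, theta) neighborhood so one physical line is not
## retained many times as near-duplicate cells.
houghPeaks <- function(acc, nLines, rhoRadius = 2L, thetaRadius = 2L) {
  picked <- integer(0)
  nr <- nrow(acc); nt <- ncol(acc)
  for (i in seq_len(nLines)) {
    cell <- which.max(acc)
    if (acc[cell] <= 0) break
    picked <- c(picked, cell)
    ri <- ((cell - 1L) %% nr) + 1L
    ti <- ((cell - 1L) %/% nr) + 1L
    rr <- max(1L, ri - rhoRadius):min(nr, ri + rhoRadius)
    tt <- max(1L, ti - thetaRadius):min(nt, ti + thetaRadius)
    acc[rr, tt] <- 0
  }
  picked
}

## Draw the top-n Hough lines into an h x w accumulator image, each
## spanning the full image, intensity proportional to relative strength.
voteImage <- function(acc, rho, theta, nLines, h, w) {
  votes <- matrix(0, h, w)
  ord <- houghPeaks(acc, nLines)
  if (!length(ord)) return(votes)
  top <- acc[ord[1]]
  for (cell in ord) {
    ri <- ((cell - 1L) %% nrow(acc)) + 1L
    ti <- ((cell - 1L) %/% nrow(acc)) + 1L
    px <- rasterizeHoughLine(rho[ri], theta[ti], h, w)
    votes[px] <- votes[px] + acc[cell] / top
  }
  votes
}

## Pixels (column-major indices) of the full-length line
## rho = x cos(theta) + y sin(theta) inside an h x w raster.
rasterizeHoughLine <- function(rho, theta, h, w) {
  ct <- cos(theta); st <- sin(theta)
  if (abs(st) >= abs(ct)) {
    xs <- seq_len(w)
    ys <- round((rho - xs * ct) / st)
    ok <- ys >= 1 & ys <= h
    unique((xs[ok] - 1L) * h + ys[ok])
  } else {
    ys <- seq_len(h)
    xs <- round((rho - ys * st) / ct)
    ok <- xs >= 1 & xs <= w
    unique((xs[ok] - 1L) * h + ys[ok])
  }
}

#' Winner-takes-all readout of a confidence profile
#'
#' Returns the normalized position of the center of the winning row,
#' `(argmax + 0.5) / H`. Exact ties are broken toward the row nearest the
#' image center, then toward the smaller row index.
#'
#' @param profile a [ConfidenceProfile-class] or numeric vector.
#' @return normalized position in (0, 1).
#' @examples
#' winnerTakesAll(c(0, 0, 5, 0))   # (2 + 0.5) / 4
#' @export
winnerTakesAll <- function(profile) {
  v <- if (methods::is(profile, "ConfidenceProfile"))
    profileValues(profile) else profile
  if (!length(v)) stop("empty profile", call. = FALSE)
  if (anyNA(v) || any(!is.finite(v))) {
    stop("profile contains non-finite values", call. = FALSE)
  }
  h <- length(v)
  cand <- which(v == max(v))
  center <- (h - 1) / 2                     # 0-based center row
  d <- abs((cand - 1) - center)
  cand <- cand[d == min(d)]
  row0 <- cand[1] - 1L                      # smaller index on remaining tie
  (row0 + 0.5) / h
}

#' Random-guessing baselines
#'
#' The dummy estimators ignore the image entirely (by signature: there is
#' no image argument) and draw estimates from a uniform interval or a
#' clamped normal distribution; they bound achievable chance performance.
#'
#' @param params a [dummyParams()] list.
#' @param seed integer seed.
#' @param n number of draws.
#' @return numeric estimate(s) in [0, 1].
#' @export
dummyEstimate <- function(params, seed = 1L, n = 1L) {
  withSeed(seed, {
    if (params$kind == "uniform") {
      lo <- max(0, params$center - params$halfWidth)
      hi <- min(1, params$center + params$halfWidth)
      if (lo > hi) stop("empty uniform interval", call. = FALSE)
      if (lo == hi) rep(lo, n) else stats::runif(n, lo, hi)
    } else {
      pmin(pmax(stats::rnorm(n, params$mean, params$sd), 0), 1)
    }
  })
}

.algorithmNames <- c("div", "ndiv", "lin", "gab", "van", "gst",
                     "dum1", "dum2")

#' Names of the implemented estimation algorithms
#'
#' `div` / `ndiv` (light-above / dark-above division), `lin` (vertical
#' gradient), `gab` (Gabor energy), `van` (vanishing point), `gst`
#' (spatial-envelope regressor mixture), `dum1` / `dum2` (uniform / normal
#' random guessing).
#'
#' @return character vector of algorithm names.
#' @export
algorithmNames <- function() .algorithmNames

#' Compute a confidence profile for a named per-row algorithm
#'
#' Dispatcher over the per-row estimators; `gst` and the dummies return no
#' profile and are rejected here.
#'
#' @param algorithm one of "div", "ndiv", "lin", "gab", "van" ("-div" is
#'   accepted as an alias of "ndiv").
#' @param channel numeric matrix, one channel.
#' @param params parameter list from the matching constructor; `NULL` takes
#'   defaults.
#' @param channelTag optional label stored in the profile.
#' @return a [ConfidenceProfile-class].
#' @export
confidenceProfile <- function(algorithm, channel, params = NULL,
                              channelTag = "") {
  if (identical(algorithm, "-div")) algorithm <- "ndiv"
  switch(algorithm,
    div = profileDiv(channel, if (is.null(params)) divParams() else params,
                     "light_above", channelTag),
    ndiv = profileDiv(channel, if (is.null(params)) divParams() else params,
                      "dark_above", channelTag),
    lin = profileLin(channel,
                     if (is.null(params)) 1 else params$smoothingSigma,
                     channelTag),
    gab = profileGab(channel, if (is.null(params)) gaborParams() else params,
                     channelTag),
    van = profileVan(channel, if (is.null(params)) vanParams() else params,
                     channelTag),
    stop(sprintf("'%s' does not produce a per-row confidence profile",
                 algorithm), call. = FALSE))
}
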