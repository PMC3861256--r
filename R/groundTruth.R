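## Ground-truth densities: turning a set of human (or simulated) horizon
## estimates for one image into a kernel density over normalized vertical
## position, and scoring any estimate by the density value at its position
## (a "confidence" — a density value, routinely above 1 for tight sets).

#' Scott's-factor kernel bandwidth
#'
#' `n^(-1/(d+4)) * sd`; the package only exercises d = 1 (horizon positions
#' are scalar) but the general formula is implemented.
#'
#' @param n number of estimates.
#' @param sd sample standard deviation of the estimates.
#' @param d dimensionality of the estimates (default 1).
#' @return bandwidth in the units of the estimates.
#' @export
scottBandwidth <- function(n, sd, d = 1) {
  assertScalarIn(n, "n", 1, Inf)
  n^(-1 / (d + 4)) * sd
}

#' Remove outlier estimates (3-SD rule)
#'
#' Single pass: compute mean and sample SD of all usable estimates for the
#' image and drop those more than three SDs from the mean. With zero SD
#' nothing is dropped. Under Normal rater noise about 0.3% of estimates are
#' expected to be removed. Sets with fewer than 2 usable estimates are
#' returned unchanged with a warning.
#'
#' @param estimateSet an [EstimateSet-class].
#' @return the filtered [EstimateSet-class] (`outlierFiltered` slot set);
#'   attribute `nRemoved` counts dropped estimates.
#' @examples
#' es <- methods::new("EstimateSet", imageId = "x",
#'                    positions = c(rep(0.5, 11), 0.9),
#'                    doNotKnow = rep(FALSE, 12))
#' estimates(removeOutliers(es))
#' @export
removeOutliers <- function(estimateSet) {
  stopifnot(methods::is(estimateSet, "EstimateSet"))
  y <- estimates(estimateSet)
  if (length(y) < 2L) {
    warning("fewer than 2 usable estimates; returned unchanged")
    out <- estimateSet
    out@outlierFiltered <- TRUE
    attr(out, "nRemoved") <- 0L
    return(out)
  }
  m <- mean(y); s <- stats::sd(y)
  keepVal <- if (s == 0) rep(TRUE, length(y)) else abs(y - m) <= 3 * s
  ## map back onto the raw response vector (do-not-knows stay flagged)
  usable <- !estimateSet@doNotKnow
  drop <- usable
  drop[usable] <- !keepVal
  out <- methods::new("EstimateSet", imageId = estimateSet@imageId,
                      positions = estimateSet@positions[!drop],
                      doNotKnow = estimateSet@doNotKnow[!drop],
                      outlierFiltered = TRUE)
  attr(out, "nRemoved") <- sum(drop)
  out
}

#' Fit a ground-truth density to an estimate set
#'
#' Replaces each retained estimate by a Gaussian kernel centred on it with
#' common bandwidth `Scott's factor x sample SD` ([scottBandwidth()] with
#' d = 1; the sample SD uses the n-1 denominator), floored at 0.005
#' normalized units so zero-spread simulated sets still define a density.
#' The density is
#' `p(y) = 1 / (n h sqrt(2 pi)) * sum_i exp(-(y - y_i)^2 / (2 h^2))`
#' and integrates to 1 over the real line.
#'
#' @param estimateSet an [EstimateSet-class] (usually after
#'   [removeOutliers()]).
#' @param bandwidthFloor lower bound on the bandwidth, normalized units.
#' @return a [GroundTruthDensity-class].
#' @examples
#' es <- simulateEstimates(0.5, 0.03, n = 12, seed = 2, imageId = "x")
#' d <- fitDensity(removeOutliers(es))
#' confidence(d, 0.5)
#' @export
fitDensity <- function(estimateSet, bandwidthFloor = 0.005) {
  stopifnot(methods::is(estimateSet, "EstimateSet"))
  y <- estimates(estimateSet)
  if (!length(y)) {
    stop("cannot fit a density to an empty estimate set", call. = FALSE)
  }
  s <- if (length(y) >= 2L) stats::sd(y) else 0
  h <- max(scottBandwidth(length(y), s, d = 1), bandwidthFloor)
  methods::new("GroundTruthDensity", imageId = estimateSet@imageId,
               samplePoints = y, bandwidth = h)
}

#' @describeIn confidence exact kernel-sum evaluation (no grid
#'   interpolation).
#' @export
setMethod("confidence", signature("GroundTruthDensity", "numeric"),
  function(density, position) {
    if (anyNA(position) || any(!is.finite(position))) {
      stop("'position' must be finite", call. = FALSE)
    }
    y <- density@samplePoints
    h <- density@bandwidth
    n <- length(y)
    vapply(position, function(p) {
      sum(exp(-(p - y)^2 / (2 * h^2))) / (n * h * sqrt(2 * pi))
    }, numeric(1))
  })
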