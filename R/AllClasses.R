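## Central S4 containers.
##
## Coordinate convention used throughout: normalized vertical position in
## [0, 1] with 0 at the top edge and 1 at the bottom edge of the full upright
## image; the center of pixel row r (0-based) of an H-row image sits at
## (r + 0.5) / H.

.sceneClasses <- c("coast", "open_country", "forest", "enclosed_nature",
                   "non_urban_street", "city", "other")

.conditionNames <- c("norm", "inverted", "blurred", "lower", "middle", "upper")

#' Scene class and condition vocabularies
#'
#' The seven outdoor scene types and the six stimulus manipulations the
#' package knows about. Scene types run roughly from natural to man-made;
#' conditions are the baseline image, its vertical mirror, a Gaussian-blurred
#' version, and the lower / middle / upper two-thirds subwindows.
#'
#' @return a character vector of valid names.
#' @examples
#' sceneClasses()
#' conditionNames()
#' @export
sceneClasses <- function() .sceneClasses

#' @rdname sceneClasses
#' @export
conditionNames <- function() .conditionNames

#' HorizonImage: an image with a known horizon
#'
#' Holds an 8-bit sRGB pixel array together with its scene class and the
#' true (astronomical) horizon as a normalized vertical position.
#'
#' @slot id character image identifier.
#' @slot pixels numeric H x W x 3 array with values in [0, 255].
#' @slot sceneClass one of [sceneClasses()].
#' @slot trueHorizon normalized vertical position in [0, 1] (0 = top row).
#' @export
setClass("HorizonImage",
  representation(id = "character", pixels = "array",
                 sceneClass = "character", trueHorizon = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
      return("'pixels' must be an H x W x 3 array")
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      return("pixel values must lie in [0, 255]")
    if (!object@sceneClass %in% .sceneClasses)
      return(sprintf("unknown sceneClass '%s'", object@sceneClass))
    if (length(object@trueHorizon) != 1L || is.na(object@trueHorizon) ||
        object@trueHorizon < 0 || object@trueHorizon > 1)
      return("'trueHorizon' must be a single value in [0, 1]")
    TRUE
  })

#' EstimateSet: raw human (or simulated) horizon estimates for one image
#'
#' Positions are normalized to the height of the full upright image.
#' Do-not-know responses are kept with their flag so reaction-time style
#' analyses remain possible, but [estimates()] excludes them: they carry no
#' position information and never enter a ground-truth density.
#'
#' @slot imageId character id of the rated image.
#' @slot positions numeric vector of raw normalized positions in [0, 1].
#' @slot doNotKnow logical vector, one flag per raw response.
#' @slot outlierFiltered logical, TRUE once [removeOutliers()] has run.
#' @export
setClass("EstimateSet",
  representation(imageId = "character", positions = "numeric",
                 doNotKnow = "logical", outlierFiltered = "logical"),
  prototype(outlierFiltered = FALSE),
  validity = function(object) {
    if (length(object@positions) != length(object@doNotKnow))
      return("'positions' and 'doNotKnow' must have equal length")
    ok <- object@positions[!object@doNotKnow]
    if (length(ok) && (anyNA(ok) || min(ok) < 0 || max(ok) > 1))
      return("usable positions must lie in [0, 1]")
    TRUE
  })

#' LabImage: CIE 1976 L*a*b* channel decomposition
#'
#' @slot L numeric matrix, lightness L* in [0, 100].
#' @slot a numeric matrix, green-red opponent axis a*.
#' @slot b numeric matrix, blue-yellow opponent axis b*.
#' @export
setClass("LabImage",
  representation(L = "matrix", a = "matrix", b = "matrix"),
  validity = function(object) {
    d <- dim(object@L)
    if (!identical(d, dim(object@a)) || !identical(d, dim(object@b)))
      return("L, a and b channels must share identical dimensions")
    TRUE
  })

#' CoordinateMap: affine map from window to full-image coordinates
#'
#' Maps a normalized vertical position inside a conditioned image window back
#' to the normalized coordinate system of the full upright image:
#' `y_full = offset + scale * y_window`, mirrored first when `flip` is set.
#'
#' @slot scale unitless scale factor (window height / full height).
#' @slot offset normalized offset of the window top inside the full image.
#' @slot flip logical, TRUE for the vertically mirrored condition.
#' @export
setClass("CoordinateMap",
  representation(scale = "numeric", offset = "numeric", flip = "logical"),
  prototype(scale = 1, offset = 0, flip = FALSE),
  validity = function(object) {
    if (object@scale <= 0) return("'scale' must be positive")
    TRUE
  })

#' ConditionedImage: pixels after one stimulus manipulation
#'
#' @slot pixels numeric H x W x 3 array in [0, 255].
#' @slot condition one of [conditionNames()].
#' @slot map [CoordinateMap-class] back to full-image coordinates.
#' @slot sourceId id of the originating [HorizonImage-class].
#' @export
setClass("ConditionedImage",
  representation(pixels = "array", condition = "character",
                 map = "CoordinateMap", sourceId = "character"),
  validity = function(object) {
    if (!object@condition %in% .conditionNames)
      return(sprintf("unknown condition '%s'", object@condition))
    if (length(dim(object@pixels)) != 3L)
      return("'pixels' must be an H x W x 3 array")
    TRUE
  })

#' ConfidenceProfile: one horizon confidence per image row
#'
#' The per-row output of the single-cue estimators; the winner-takes-all
#' readout turns it into a point estimate.
#'
#' @slot values numeric vector, one non-negative finite value per image row.
#' @slot channel which channel produced it ("L", "a" or "b"; "" when
#'   unspecified).
#' @export
setClass("ConfidenceProfile",
  representation(values = "numeric", channel = "character"),
  prototype(channel = ""),
  validity = function(object) {
    v <- object@values
    if (!length(v)) return("'values' must be non-empty")
    if (anyNA(v) || any(!is.finite(v))) return("'values' must be finite")
    if (min(v) < 0) return("'values' must be non-negative")
    TRUE
  })

#' GroundTruthDensity: per-image kernel density over horizon position
#'
#' A Gaussian kernel density over normalized vertical position fitted to the
#' retained estimates for one image, with Scott's-factor bandwidth.  Point
#' evaluations ("confidences") are density values and may exceed 1.
#'
#' @slot imageId character id of the underlying image.
#' @slot samplePoints the retained estimates (kernel centers).
#' @slot bandwidth normalized units; Scott's factor times the sample SD,
#'   floored at 0.005.
#' @export
setClass("GroundTruthDensity",
  representation(imageId = "character", samplePoints = "numeric",
                 bandwidth = "numeric"),
  validity = function(object) {
    if (!length(object@samplePoints)) return("no sample points")
    if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
      return("'bandwidth' must be a single positive value")
    TRUE
  })

#' RegressorMixture: EM-trained mixture of linear regressors
#'
#' The holistic estimator: K linear regressors over spatial-envelope
#' descriptors with cluster-weighted gating by per-component diagonal
#' Gaussians in a PCA-reduced descriptor space.
#'
#' @slot K integer component count.
#' @slot coef d x K matrix of regression weights (descriptor dims incl.
#'   the trailing intercept).
#' @slot noiseSd length-K positive per-component target noise SDs.
#' @slot prior length-K mixing priors (positive, sum to 1).
#' @slot gateMean p x K gating means in PCA space.
#' @slot gateSd p x K gating SDs in PCA space.
#' @slot pca list with elements `center` (length d-1) and `rotation`
#'   ((d-1) x p) mapping descriptors (minus intercept) to gating space.
#' @slot logLik final training log-likelihood of the selected restart.
#' @slot trace numeric vector of per-iteration log-likelihoods.
#' @export
setClass("RegressorMixture",
  representation(K = "integer", coef = "matrix", noiseSd = "numeric",
                 prior = "numeric", gateMean = "matrix", gateSd = "matrix",
                 pca = "list", logLik = "numeric", trace = "numeric"),
  validity = function(object) {
    if (object@K < 1L) return("'K' must be >= 1")
    if (ncol(object@coef) != object@K) return("'coef' must have K columns")
    if (any(object@prior <= 0) || abs(sum(object@prior) - 1) > 1e-6)
      return("mixing priors must be positive and sum to 1")
    if (any(object@noiseSd <= 0)) return("noise SDs must be positive")
    TRUE
  })

setMethod("show", "HorizonImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("HorizonImage '%s' (%d x %d, class %s, horizon %.3f)\n",
              object@id, d[1], d[2], object@sceneClass, object@trueHorizon))
})

setMethod("show", "EstimateSet", function(object) {
  cat(sprintf("EstimateSet for '%s': %d responses (%d do-not-know)%s\n",
              object@imageId, length(object@positions),
              sum(object@doNotKnow),
              if (object@outlierFiltered) ", outlier-filtered" else ""))
})

setMethod("show", "ConfidenceProfile", function(object) {
  cat(sprintf("ConfidenceProfile (%d rows, channel '%s', peak at row %d)\n",
              length(object@values), object@channel,
              which.max(object@values) - 1L))
})

setMethod("show", "GroundTruthDensity", function(object) {
  cat(sprintf("GroundTruthDensity '%s': n = %d, bandwidth = %.4f\n",
              object@imageId, length(object@samplePoints), object@bandwidth))
})

setMethod("show", "RegressorMixture", function(object) {
  cat(sprintf(
    "RegressorMixture: K = %d, %d descriptor dims, logLik = %.3f\n",
    object@K, nrow(object@coef), object@logLik))
})

setMethod("show", "CoordinateMap", function(object) {
  cat(sprintf("CoordinateMap: y_full = %.4f + %.4f * y_window%s\n",
              object@offset, object@scale,
              if (object@flip) " (after vertical mirror)" else ""))
})
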