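## Generics and accessors. Slots are never touched directly by user code.

#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("sceneClass", function(x) standardGeneric("sceneClass"))
#' @rdname accessors
#' @export
setGeneric("trueHorizon", function(x) standardGeneric("trueHorizon"))
#' @rdname accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
#' @rdname accessors
#' @export
setGeneric("doNotKnow", function(x) standardGeneric("doNotKnow"))
#' @rdname accessors
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))
#' @rdname accessors
#' @export
setGeneric("samplePoints", function(x) standardGeneric("samplePoints"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("channelTag", function(x) standardGeneric("channelTag"))
#' @rdname accessors
#' @export
setGeneric("coordinateMap", function(x) standardGeneric("coordinateMap"))
#' @rdname accessors
#' @export
setGeneric("conditionName", function(x) standardGeneric("conditionName"))

#' Evaluate a ground-truth density at a position
#'
#' @param density a [GroundTruthDensity-class].
#' @param position finite normalized position(s).
#' @return non-negative density value(s); these are densities, not
#'   probabilities, and routinely exceed 1 for tight estimate sets.
#' @export
setGeneric("confidence",
           function(density, position) standardGeneric("confidence"))

#' Predict a horizon position from a fitted regressor mixture
#'
#' @param object a [RegressorMixture-class].
#' @param descriptor a descriptor vector (or matrix of rows) as produced by
#'   [gistDescriptor()], dimension matching training.
#' @return normalized position(s) clamped to [0, 1]; attribute `clamped`
#'   flags predictions that fell outside before clamping.
#' @export
setGeneric("predictHorizon",
           function(object, descriptor) standardGeneric("predictHorizon"))

#' Accessors for skyline containers
#'
#' Read-only accessors for the S4 containers: image identity, pixel arrays,
#' scene class and true horizon of a [HorizonImage-class]; usable positions
#' of an [EstimateSet-class] (do-not-know responses excluded); kernel
#' centers and bandwidth of a [GroundTruthDensity-class]; per-row values and
#' channel tag of a [ConfidenceProfile-class]; coordinate map and condition
#' of a [ConditionedImage-class].
#'
#' @param x the object.
#' @return the slot value (for `estimates`, raw positions with do-not-know
#'   responses removed).
#' @name accessors
NULL

#' @rdname accessors
setMethod("imageId", "HorizonImage", function(x) x@id)
#' @rdname accessors
setMethod("imageId", "EstimateSet", function(x) x@imageId)
#' @rdname accessors
setMethod("imageId", "GroundTruthDensity", function(x) x@imageId)
#' @rdname accessors
setMethod("pixels", "HorizonImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "ConditionedImage", function(x) x@pixels)
#' @rdname accessors
setMethod("sceneClass", "HorizonImage", function(x) x@sceneClass)
#' @rdname accessors
setMethod("trueHorizon", "HorizonImage", function(x) x@trueHorizon)
#' @rdname accessors
setMethod("estimates", "EstimateSet", function(x) {
  x@positions[!x@doNotKnow]
})
#' @rdname accessors
setMethod("doNotKnow", "EstimateSet", function(x) x@doNotKnow)
#' @rdname accessors
setMethod("bandwidth", "GroundTruthDensity", function(x) x@bandwidth)
#' @rdname accessors
setMethod("samplePoints", "GroundTruthDensity", function(x) x@samplePoints)
#' @rdname accessors
setMethod("profileValues", "ConfidenceProfile", function(x) x@values)
#' @rdname accessors
setMethod("channelTag", "ConfidenceProfile", function(x) x@channel)
#' @rdname accessors
setMethod("coordinateMap", "ConditionedImage", function(x) x@map)
#' @rdname accessors
setMethod("conditionName", "ConditionedImage", function(x) x@condition)
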