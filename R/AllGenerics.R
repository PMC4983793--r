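#' Accessors for FLIPimage objects
#'
#' Small accessor generics used across the package: pixel data and bit depth
#' of a [FluorImage], the label matrix and per-region table of a
#' [BeadRegions] object, the image/truth halves of a [SimulatedScene], and
#' the signal slots of a [FlipResult].
#'
#' @param object An object of the documented class.
#' @return The slot value (see the class documentation for types).
#' @name accessors
#' @rdname accessors
#' @examples
#' img <- FluorImage(matrix(7, 4, 4), bitDepth = 8L)
#' pixels(img)[1, 1]
#' bitDepth(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))

#' @rdname accessors
#' @export
setGeneric("sceneImage", function(object) standardGeneric("sceneImage"))

#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("rawSignal", function(object) standardGeneric("rawSignal"))

#' @rdname accessors
#' @export
setGeneric("controlSignal", function(object) standardGeneric("controlSignal"))

#' @rdname accessors
#' @export
setGeneric("correctedSignal", function(object) standardGeneric("correctedSignal"))

#' @rdname accessors
#' @export
setGeneric("nBeads", function(object) standardGeneric("nBeads"))

#' @rdname accessors
#' @export
setGeneric("replicateValues", function(object) standardGeneric("replicateValues"))

#' @rdname accessors
#' @export
setGeneric("variability", function(object) standardGeneric("variability"))

#' @rdname accessors
#' @export
setGeneric("curveSlope", function(object) standardGeneric("curveSlope"))

#' @rdname accessors
#' @export
setGeneric("curveIntercept", function(object) standardGeneric("curveIntercept"))

#' @rdname accessors
#' @export
setGeneric("curveRSquared", function(object) standardGeneric("curveRSquared"))

#' @rdname accessors
#' @export
setGeneric("massRange", function(object) standardGeneric("massRange"))
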