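#' @rdname ScheimpflugFrame-class
#' @param x A `ScheimpflugFrame` or `RegionMasks` object.
#' @export
setGeneric("framePixels", function(x) standardGeneric("framePixels"))

#' @rdname ScheimpflugFrame-class
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname ScheimpflugFrame-class
#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))

#' @rdname ScheimpflugFrame-class
#' @export
setGeneric("meridianIndex", function(x) standardGeneric("meridianIndex"))

#' @rdname RegionMasks-class
#' @param x A `RegionMasks` object.
#' @export
setGeneric("corneaMask", function(x) standardGeneric("corneaMask"))

#' @rdname RegionMasks-class
#' @export
setGeneric("irisMask", function(x) standardGeneric("irisMask"))

#' @rdname RegionMasks-class
#' @export
setGeneric("lateralMask", function(x) standardGeneric("lateralMask"))

#' @rdname RegionMasks-class
#' @export
setGeneric("maskProvenance", function(x) standardGeneric("maskProvenance"))

#' @rdname CohortNormalization-class
#' @param x A `CohortNormalization` object.
#' @export
setGeneric("cohortMedians", function(x) standardGeneric("cohortMedians"))

#' @rdname CohortNormalization-class
#' @export
setGeneric("cohortIqrs", function(x) standardGeneric("cohortIqrs"))

#' @rdname CohortNormalization-class
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))
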