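#' @rdname ScheimpflugFrame-class
setMethod("framePixels", "ScheimpflugFrame", function(x) x@pixels)

#' @rdname ScheimpflugFrame-class
setMethod("frameDim", "ScheimpflugFrame", function(x) dim(x@pixels))

#' @rdname ScheimpflugFrame-class
setMethod("eyeId", "ScheimpflugFrame", function(x) x@eyeId)

#' @rdname ScheimpflugFrame-class
setMethod("meridianIndex", "ScheimpflugFrame", function(x) x@meridianIndex)

#' @rdname RegionMasks-class
setMethod("corneaMask", "RegionMasks", function(x) x@cornea)

#' @rdname RegionMasks-class
setMethod("irisMask", "RegionMasks", function(x) x@iris)

#' @rdname RegionMasks-class
setMethod("lateralMask", "RegionMasks", function(x) x@lateral)

#' @rdname RegionMasks-class
setMethod("maskProvenance", "RegionMasks", function(x) x@provenance)

#' @rdname CohortNormalization-class
setMethod("cohortMedians", "CohortNormalization", function(x) x@medians)

#' @rdname CohortNormalization-class
setMethod("cohortIqrs", "CohortNormalization", function(x) x@iqrs)

#' @rdname CohortNormalization-class
setMethod("cohortSize", "CohortNormalization", function(x) x@nEyes)

setMethod("show", "ScheimpflugFrame", function(object) {
  d <- dim(object@pixels)
  cat("ScheimpflugFrame", sprintf("(%d x %d px)", d[1], d[2]),
      "eye:", object@eyeId,
      "meridian:", object@meridianIndex, "\n")
  cat("  intensity range:",
      sprintf("[%.1f, %.1f] a.u.", min(object@pixels), max(object@pixels)),
      "\n")
})

setMethod("show", "RegionMasks", function(object) {
  d <- dim(object@cornea)
  cat("RegionMasks", sprintf("(%d x %d px,", d[1], d[2]),
      object@provenance, "provenance)\n")
  cat(sprintf("  cornea: %d px | iris: %d px | lateral: %d px\n",
      sum(object@cornea), sum(object@iris), sum(object@lateral)))
})

setMethod("show", "CohortNormalization", function(object) {
  cat("CohortNormalization over", object@nEyes, "eyes\n")
  cat(sprintf("  median (L*, a*, b*): %.3f, %.3f, %.3f\n",
      object@medians["L"], object@medians["a"], object@medians["b"]))
  cat(sprintf("  IQR    (L*, a*, b*): %.3f, %.3f, %.3f\n",
      object@iqrs["L"], object@iqrs["a"], object@iqrs["b"]))
})
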