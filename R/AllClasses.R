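#' @import methods
NULL

#' ScheimpflugFrame: one grayscale anterior-segment image
#'
#' Container for a single Scheimpflug-style optical section. Pixel values are
#' 8-bit grayscale intensities in arbitrary units (a.u.) on the 0--255 scale,
#' stored as a numeric matrix in row-major image convention (rows = image
#' rows, origin at the top-left). A Pentacam-style acquisition yields up to 25
#' such frames per eye, one per meridian.
#'
#' @slot pixels Numeric matrix of intensities in [0, 255].
#' @slot eyeId Character scalar identifying the eye.
#' @slot meridianIndex Integer in [1, 25], the meridian of this frame.
#'
#' @seealso [ScheimpflugFrame()] for the user-facing constructor,
#'   [segmentFrame()], [analyzeFrame()].
#' @name ScheimpflugFrame-class
#' @rdname ScheimpflugFrame-class
#' @exportClass ScheimpflugFrame
setClass("ScheimpflugFrame",
  representation(
    pixels = "matrix",
    eyeId = "character",
    meridianIndex = "integer"
  )
)

setValidity("ScheimpflugFrame", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 64 || ncol(p) < 64) {
    return("frame must be at least 64 x 64 pixels")
  }
  if (anyNA(p) || min(p) < 0 || max(p) > 255) {
    return("intensities must lie in [0, 255] with no NAs")
  }
  if (length(object@eyeId) != 1L) return("eyeId must be a single string")
  m <- object@meridianIndex
  if (length(m) != 1L || is.na(m) || m < 1L || m > 25L) {
    return("meridianIndex must be a single integer in [1, 25]")
  }
  TRUE
})

#' Construct a ScheimpflugFrame
#'
#' @param pixels Numeric matrix of 8-bit intensities (0--255); rows are image
#'   rows, columns are image columns.
#' @param eyeId Character identifier for the eye (default `"eye"`).
#' @param meridianIndex Meridian number in [1, 25] (default 1).
#' @return A [ScheimpflugFrame-class] object.
#' @examples
#' f <- ScheimpflugFrame(matrix(50, 64, 64), eyeId = "OD-01")
#' frameDim(f)
#' @export
ScheimpflugFrame <- function(pixels, eyeId = "eye", meridianIndex = 1L) {
  new("ScheimpflugFrame",
    pixels = as.matrix(pixels), eyeId = as.character(eyeId),
    meridianIndex = as.integer(meridianIndex))
}

#' RegionMasks: cornea / iris / lateral region labels for one frame
#'
#' Binary masks delineating the three regions of interest in a Scheimpflug
#' frame: the cornea (the densitometry region), the iris band beneath the
#' posterior corneal boundary in the central third of the width, and the
#' lateral corneoscleral flanks at the same depth in the outer thirds. The
#' three masks are pairwise disjoint and share the frame's dimensions.
#' Provenance records whether the masks came from the automatic segmenter
#' (`"automatic"`) or were supplied externally (`"external"`).
#'
#' @slot cornea,iris,lateral Logical matrices, pairwise disjoint.
#' @slot provenance `"automatic"` or `"external"`.
#'
#' @seealso [RegionMasks()], [segmentFrame()], [validateMasks()].
#' @name RegionMasks-class
#' @rdname RegionMasks-class
#' @exportClass RegionMasks
setClass("RegionMasks",
  representation(
    cornea = "matrix",
    iris = "matrix",
    lateral = "matrix",
    provenance = "character"
  )
)

setValidity("RegionMasks", function(object) {
  ms <- list(object@cornea, object@iris, object@lateral)
  if (!all(vapply(ms, is.logical, logical(1)))) {
    return("masks must be logical matrices")
  }
  d <- dim(ms[[1]])
  if (!all(vapply(ms, function(m) identical(dim(m), d), logical(1)))) {
    return("masks must share dimensions")
  }
  if (any(object@cornea & object@iris) || any(object@cornea & object@lateral) ||
      any(object@iris & object@lateral)) {
    return("region masks must be pairwise disjoint")
  }
  if (!object@provenance %in% c("automatic", "external")) {
    return("provenance must be 'automatic' or 'external'")
  }
  TRUE
})

#' Construct a RegionMasks object
#'
#' @param cornea,iris,lateral Logical matrices of identical dimensions,
#'   pairwise disjoint.
#' @param provenance `"automatic"` or `"external"`.
#' @return A [RegionMasks-class] object.
#' @export
RegionMasks <- function(cornea, iris, lateral, provenance = "external") {
  new("RegionMasks",
    cornea = matrix(as.logical(cornea), nrow(cornea)),
    iris = matrix(as.logical(iris), nrow(iris)),
    lateral = matrix(as.logical(lateral), nrow(lateral)),
    provenance = provenance)
}

#' CohortNormalization: robust per-component normalization constants
#'
#' Cohort-level medians and interquartile ranges of the CIELAB components
#' (L*, a*, b*), fitted once per cohort and used to place all eyes on a
#' common dimensionless scale before combining the components into the
#' IrisColor index. Normalized values are cohort-relative: editing the cohort
#' requires refitting.
#'
#' @slot medians,iqrs Named numeric vectors with elements `L`, `a`, `b`.
#' @slot nEyes Integer cohort size (at least 4).
#'
#' @seealso [fitCohortNormalization()], [scoreIrisCohort()].
#' @name CohortNormalization-class
#' @rdname CohortNormalization-class
#' @exportClass CohortNormalization
setClass("CohortNormalization",
  representation(
    medians = "numeric",
    iqrs = "numeric",
    nEyes = "integer"
  )
)

setValidity("CohortNormalization", function(object) {
  nm <- c("L", "a", "b")
  if (!identical(names(object@medians), nm) ||
      !identical(names(object@iqrs), nm)) {
    return("medians and iqrs must be named L, a, b")
  }
  if (any(object@iqrs <= 0)) return("all IQRs must be positive")
  if (object@nEyes < 4L) return("cohort must contain at least 4 eyes")
  TRUE
})
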