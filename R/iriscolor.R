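## Objective iris-pigmentation metric from RGB slit-lamp photographs.
##
## Each image is converted to CIELAB (sRGB transfer function, D65 reference
## white), summarized over the iris region of interest, and the cohort of
## per-eye summaries is robustly normalized component-wise by median and
## IQR. Because L* runs opposite to pigmentation while a* and b* run with
## it, the normalized L* enters the composite with a minus sign:
##
##   IrisColor = -Ln + an + bn
##
## Negative values indicate light irises, positive values dark irises. The
## index is cohort-relative by construction.

#' Convert an 8-bit RGB image to CIELAB
#'
#' Applies the standard sRGB linearization and the sRGB -> XYZ -> CIELAB
#' closed form under the D65 reference white (via [grDevices::convertColor]).
#' Slit-lamp cameras are assumed to encode sRGB; no device calibration is
#' attempted.
#'
#' @param image Numeric array `h x w x 3` with values in 0--255 (or 0--1,
#'   detected automatically).
#' @return Numeric array `h x w x 3` with CIELAB planes `L` (0--100), `a`,
#'   `b`.
#' @section Errors: `NotColorImage` on input without three channels.
#' @examples
#' px <- array(c(255, 255, 255), c(1, 1, 3))
#' rgbToCielab(px)[1, 1, ] # L = 100, a = 0, b = 0
#' @export
rgbToCielab <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    .err("NotColorImage", "expected an h x w x 3 RGB array")
  image <- image[, , 1:3, drop = FALSE]
  mx <- max(image)
  if (mx > 1) image <- image / 255
  d <- dim(image)
  lab <- grDevices::convertColor(matrix(image, ncol = 3),
                                 from = "sRGB", to = "Lab")
  array(lab, c(d[1], d[2], 3), dimnames = list(NULL, NULL, c("L", "a", "b")))
}

#' Summarize CIELAB components over an iris ROI
#'
#' Reduces a Lab image to one triple per eye over the iris region of
#' interest (pupil, specular highlights and non-iris areas are excluded by
#' the mask). The per-pixel reduction is the arithmetic mean by default; the
#' median is available as a robust alternative.
#'
#' @param lab CIELAB array from [rgbToCielab()].
#' @param roi Logical matrix matching the image plane.
#' @param eyeId Identifier recorded in the output.
#' @param stat `"mean"` (default) or `"median"`.
#' @return One-row `data.frame` with columns `eyeId`, `L`, `a`, `b`.
#' @section Errors: `DegenerateRegion` on an empty ROI.
#' @export
summarizeIrisRoi <- function(lab, roi, eyeId = "eye",
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  roi <- matrix(as.logical(roi), nrow(roi))
  if (!identical(dim(roi), dim(lab)[1:2]))
    .err("MaskMismatch", "ROI dimensions do not match the image")
  if (!any(roi)) .err("DegenerateRegion", "ROI selects no pixels")
  f <- if (stat == "mean") mean else stats::median
  data.frame(
    eyeId = eyeId,
    L = f(lab[, , "L"][roi]),
    a = f(lab[, , "a"][roi]),
    b = f(lab[, , "b"][roi]),
    stringsAsFactors = FALSE
  )
}

#' Fit cohort-level robust normalization constants
#'
#' Computes the median and interquartile range (Q3 - Q1, linear-interpolation
#' quantiles, `type = 7`) of each CIELAB component across the cohort's
#' per-eye summaries. Normalizing by median/IQR rather than mean/SD keeps
#' the index robust to outlying eyes and puts the three components, whose
#' native numerical ranges differ substantially, on a comparable scale.
#'
#' @param summaries `data.frame` of stacked [summarizeIrisRoi()] rows (at
#'   least 4 eyes).
#' @return A [CohortNormalization-class].
#' @section Errors: `CohortTooSmall` (< 4 eyes); `ZeroIQR` (a component with
#'   zero spread, i.e. a degenerate cohort).
#' @export
fitCohortNormalization <- function(summaries) {
  n <- nrow(summaries)
  if (is.null(n) || n < 4) .err("CohortTooSmall", "need at least 4 eyes")
  med <- vapply(summaries[c("L", "a", "b")], stats::median, 0)
  iqr <- vapply(summaries[c("L", "a", "b")],
                function(x) diff(stats::quantile(x, c(0.25, 0.75),
                                                 names = FALSE, type = 7)), 0)
  names(med) <- names(iqr) <- c("L", "a", "b")
  if (any(iqr == 0))
    .err("ZeroIQR", sprintf("zero IQR in component(s): %s",
                            paste(c("L", "a", "b")[iqr == 0], collapse = ", ")))
  new("CohortNormalization", medians = med, iqrs = iqr, nEyes = as.integer(n))
}

#' Robustly normalize one component value
#'
#' @param x Component value.
#' @param median Cohort median of the component.
#' @param iqr Cohort IQR of the component (positive).
#' @return `(x - median) / iqr`, dimensionless.
#' @section Errors: `ZeroIQR` when `iqr <= 0`.
#' @export
normalizeComponent <- function(x, median, iqr) {
  if (any(iqr <= 0)) .err("ZeroIQR", "IQR must be positive")
  (x - median) / iqr
}

#' Composite IrisColor index from normalized components
#'
#' Combines the cohort-normalized CIELAB components into a single scalar.
#' The normalized lightness enters with a minus sign so that all three
#' components increase with pigmentation: `-Ln + an + bn`.
#'
#' @param Ln,an,bn Normalized L*, a*, b* (finite).
#' @return The IrisColor scalar, a.u.
#' @examples
#' irisColorIndex(-1, 1, 1) # 3, a dark eye
#' @export
irisColorIndex <- function(Ln, an, bn) {
  stopifnot(is.finite(Ln), is.finite(an), is.finite(bn))
  -Ln + an + bn
}

#' Classify pigmentation from the sign of IrisColor
#'
#' Strictly negative values classify as `"light"`, strictly positive as
#' `"dark"`. An exact zero is `"indeterminate"`: the sign rule defines only
#' the strict cases, and such eyes are excluded from two-group comparisons.
#'
#' @param irisColor Numeric vector of IrisColor values.
#' @return Character vector in `{"light", "dark", "indeterminate"}`.
#' @export
classifyPigmentation <- function(irisColor) {
  stopifnot(all(is.finite(irisColor)))
  ifelse(irisColor < 0, "light", ifelse(irisColor > 0, "dark", "indeterminate"))
}

#' Score a cohort of iris Lab summaries
#'
#' Convenience wrapper running the full cohort-level stage: fit the robust
#' normalization, normalize each eye's components, compute IrisColor and the
#' light/dark classification. The normalization is refit on every call --
#' IrisColor values are cohort-relative and must never be cached across
#' cohort edits.
#'
#' @param summaries `data.frame` of stacked [summarizeIrisRoi()] rows.
#' @return `data.frame` with columns `eyeId`, `L`, `a`, `b`, `Ln`, `an`,
#'   `bn`, `irisColor`, `pigmentClass`; the fitted
#'   [CohortNormalization-class] is attached as attribute `"normalization"`.
#' @export
scoreIrisCohort <- function(summaries) {
  norm <- fitCohortNormalization(summaries)
  med <- cohortMedians(norm); iqr <- cohortIqrs(norm)
  out <- summaries[c("eyeId", "L", "a", "b")]
  out$Ln <- normalizeComponent(summaries$L, med["L"], iqr["L"])
  out$an <- normalizeComponent(summaries$a, med["a"], iqr["a"])
  out$bn <- normalizeComponent(summaries$b, med["b"], iqr["b"])
  out$irisColor <- irisColorIndex(out$Ln, out$an, out$bn)
  out$pigmentClass <- classifyPigmentation(out$irisColor)
  rownames(out) <- NULL
  attr(out, "normalization") <- norm
  out
}

#' Rasterize a polygon into a binary ROI mask
#'
#' Helper for producing an iris ROI mask from polygon vertices (e.g. traced
#' in any annotation tool) instead of a mask file. Uses even-odd point-in-
#' polygon tests at pixel centres.
#'
#' @param vertices Two-column matrix of (row, col) polygon vertices.
#' @param height,width Mask dimensions in pixels.
#' @return Logical `height x width` matrix.
#' @export
polygonMask <- function(vertices, height, width) {
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  vr <- vertices[, 1]; vc <- vertices[, 2]
  n <- nrow(vertices)
  mask <- matrix(FALSE, height, width)
  grid <- expand.grid(r = seq_len(height), c = seq_len(width))
  inside <- rep(FALSE, nrow(grid))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vr[i] > grid$r) != (vr[j] > grid$r)
    xint <- (vc[j] - vc[i]) * (grid$r - vr[i]) / (vr[j] - vr[i]) + vc[i]
    inside <- xor(inside, cross & grid$c < xint)
    j <- i
  }
  mask[cbind(grid$r, grid$c)] <- inside
  mask
}
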