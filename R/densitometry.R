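## Corneal densitometry (mean pixel intensity of the segmented cornea), the
## per-frame adaptive artefact threshold, per-region spurious-brightness
## percentages, and per-eye aggregation over the frame set.

#' Mean and standard deviation of intensities under a mask
#'
#' Corneal densitometry is defined as the mean pixel intensity (MPI) of the
#' segmented cornea; this helper computes that mean together with the sample
#' standard deviation (n - 1 denominator) used by the adaptive artefact
#' threshold. The SD is 0 for a single-pixel or constant region.
#'
#' @param frame A [ScheimpflugFrame-class].
#' @param mask Logical matrix matching the frame's dimensions.
#' @return Named numeric vector `c(mean = , sd = )`, in a.u.
#' @section Errors: `DegenerateRegion` on an empty mask.
#' @export
regionIntensityStats <- function(frame, mask) {
  stopifnot(is(frame, "ScheimpflugFrame"))
  mask <- as.logical(mask)
  if (length(mask) != length(framePixels(frame)))
    .err("MaskMismatch", "mask dimensions do not match the frame")
  v <- framePixels(frame)[mask]
  if (length(v) == 0) .err("DegenerateRegion", "mask selects no pixels")
  s <- if (length(v) > 1) stats::sd(v) else 0
  c(mean = mean(v), sd = s)
}

#' Adaptive artefact threshold: corneal MPI plus three SDs
#'
#' The threshold is established individually for each frame as the corneal
#' mean pixel intensity plus three times its standard deviation. It is not
#' clamped to 255: a threshold above the intensity ceiling legitimately
#' yields 0% artefacts.
#'
#' @param mpi Corneal mean pixel intensity, a.u. (non-negative).
#' @param sd Corneal intensity standard deviation, a.u. (non-negative).
#' @return The threshold `mpi + 3 * sd`, a.u.
#' @examples
#' artefactThreshold(50, 10) # 80
#' @export
artefactThreshold <- function(mpi, sd) {
  stopifnot(mpi >= 0, sd >= 0)
  mpi + 3 * sd
}

#' Percentage of region pixels exceeding a threshold
#'
#' The proportion of pixels within a segmented region whose intensity is
#' strictly greater than the adaptive threshold, relative to the total pixel
#' count of the region, expressed in percent. Ties at the threshold do not
#' count as artefacts.
#'
#' @param frame A [ScheimpflugFrame-class].
#' @param mask Logical region mask.
#' @param threshold Intensity threshold, a.u.
#' @return Percentage in [0, 100].
#' @section Errors: `DegenerateRegion` on an empty mask.
#' @export
artefactPercentage <- function(frame, mask, threshold) {
  stopifnot(is(frame, "ScheimpflugFrame"))
  mask <- as.logical(mask)
  v <- framePixels(frame)[mask]
  if (length(v) == 0) .err("DegenerateRegion", "mask selects no pixels")
  100 * sum(v > threshold) / length(v)
}

#' Densitometry and artefact metrics for one frame
#'
#' Composes the per-frame measurement: corneal MPI and SD, the adaptive
#' threshold (MPI + 3 SD), and the percentage of super-threshold pixels in
#' the iris region, the lateral region, and their union (`pctOverall`,
#' pixel-weighted over the combined region).
#'
#' @param frame A [ScheimpflugFrame-class].
#' @param masks A [RegionMasks-class] valid for the frame (automatic or
#'   external provenance).
#' @return One-row `data.frame` with columns `eyeId`, `meridianIndex`,
#'   `mpiCornea`, `sdCornea`, `threshold`, `pctIris`, `pctLateral`,
#'   `pctOverall`.
#' @examples
#' ph <- makePhantom(phantomSpec(artefactFractionIris = 0.05, seed = 2))
#' analyzeFrame(ph$frame, ph$masks)
#' @export
analyzeFrame <- function(frame, masks) {
  stopifnot(is(frame, "ScheimpflugFrame"), is(masks, "RegionMasks"))
  if (!identical(frameDim(frame), dim(corneaMask(masks))))
    .err("MaskMismatch", "mask dimensions do not match the frame")
  cs <- regionIntensityStats(frame, corneaMask(masks))
  thr <- artefactThreshold(cs["mean"], cs["sd"])
  data.frame(
    eyeId = eyeId(frame),
    meridianIndex = meridianIndex(frame),
    mpiCornea = unname(cs["mean"]),
    sdCornea = unname(cs["sd"]),
    threshold = unname(thr),
    pctIris = artefactPercentage(frame, irisMask(masks), thr),
    pctLateral = artefactPercentage(frame, lateralMask(masks), thr),
    pctOverall = artefactPercentage(frame, irisMask(masks) | lateralMask(masks),
                                    thr),
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-frame densitometry into a per-eye summary
#'
#' Final per-eye values are unweighted arithmetic means of the per-frame
#' measurements across the available meridians (nominally 25 per
#' acquisition; fewer frames are averaged as-is with `nFrames` recording the
#' count). The aggregated corneal MPI is the eye's corneal densitometry
#' (`cd`).
#'
#' @param frameResults `data.frame` of stacked [analyzeFrame()] rows.
#' @param eyeId Identifier recorded in the output (defaults to the single
#'   `eyeId` present in `frameResults`).
#' @return One-row `data.frame` with `eyeId`, `nFrames`, `cd`, `pctIris`,
#'   `pctLateral`, `pctOverall`.
#' @section Errors: `EmptyInput` when `frameResults` has no rows.
#' @export
aggregateEye <- function(frameResults, eyeId = NULL) {
  if (is.null(frameResults) || nrow(frameResults) == 0)
    .err("EmptyInput", "no per-frame results to aggregate")
  if (is.null(eyeId)) {
    ids <- unique(frameResults$eyeId)
    if (length(ids) != 1)
      .err("EmptyInput", "frameResults mixes eyes; supply eyeId explicitly")
    eyeId <- ids
  }
  data.frame(
    eyeId = eyeId,
    nFrames = nrow(frameResults),
    cd = mean(frameResults$mpiCornea),
    pctIris = mean(frameResults$pctIris),
    pctLateral = mean(frameResults$pctLateral),
    pctOverall = mean(frameResults$pctOverall),
    stringsAsFactors = FALSE
  )
}
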