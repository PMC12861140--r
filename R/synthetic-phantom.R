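## Seeded Scheimpflug-style phantoms with recorded ground truth.
##
## The phantom is a geometric emulator, not an optical model: a bright
## corneal arc (two near-horizontal parabolic boundaries) over a darker
## background, with an iris band and lateral corneoscleral flanks rendered
## beneath the posterior boundary. A controlled number of super-threshold
## "artefact" pixels is planted at seeded positions inside the iris and
## lateral regions, and the exact planted counts are recorded so the whole
## densitometry pipeline can be validated against known truth.

# Central-third column indices; shared by the generator and the segmenter so
# the iris/lateral split is a single convention.
.centralThird <- function(width) {
  seq.int(floor(width / 3) + 1L, ceiling(2 * width / 3))
}

# Run expr with a private RNG stream; the caller's RNG state is untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for a synthetic Scheimpflug phantom
#'
#' Collects the intensity and geometry parameters of a phantom frame.
#' Defaults render a 300 x 155 frame (quarter linear scale of the native
#' 1200 x 620 Scheimpflug resolution, keeping batch generation fast; pass the
#' full size explicitly when needed) with a corneal arc sampled from
#' N(48, 3^2) a.u., iris/lateral base intensity 30 a.u. (safely below the
#' adaptive artefact threshold 48 + 3*3 = 57 a.u.) and planted artefact
#' pixels at 120 a.u.
#'
#' Geometry arguments (`apexRow`, `thickness`, `edgeRise`, `arcCols`) default
#' to height-proportional values; `arcCols` restricts the rendered arc to a
#' column range (used to exercise degenerate-region handling).
#'
#' @param width,height Frame size in pixels (each at least 64).
#' @param corneaMean,corneaSd Corneal intensity distribution, a.u.
#' @param irisBase,lateralBase Base intensity of the iris band and lateral
#'   flanks, a.u.; must stay below `corneaMean + 3 * corneaSd`.
#' @param artefactFractionIris,artefactFractionLateral Planted fraction of
#'   super-threshold pixels per region, in [0, 1).
#' @param artefactValue Intensity of planted artefact pixels, a.u.; must
#'   exceed `corneaMean + 3 * corneaSd`.
#' @param background Background intensity, a.u.
#' @param apexRow Row of the anterior boundary at the arc apex.
#' @param thickness Corneal thickness in rows.
#' @param edgeRise Extra depth of the boundaries at the lateral image edges.
#' @param arcCols Integer range of columns over which the arc is rendered.
#' @param seed Integer seed; the phantom is a pure function of spec + seed.
#' @return A named list of class `"phantomSpec"`.
#' @examples
#' ph <- makePhantom(phantomSpec(artefactFractionIris = 0.1, seed = 3))
#' ph$truth$plantedIris
#' @export
phantomSpec <- function(width = 300L, height = 155L,
                        corneaMean = 48, corneaSd = 3,
                        irisBase = 30, lateralBase = 30,
                        artefactFractionIris = 0,
                        artefactFractionLateral = 0,
                        artefactValue = 120,
                        background = 10,
                        apexRow = NULL, thickness = NULL, edgeRise = NULL,
                        arcCols = NULL,
                        seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.null(apexRow)) apexRow <- max(4L, round(0.12 * height))
  if (is.null(thickness)) thickness <- max(6L, round(0.16 * height))
  if (is.null(edgeRise)) edgeRise <- round(0.10 * height)
  if (is.null(arcCols)) arcCols <- c(1L, width)
  spec <- list(width = width, height = height,
    corneaMean = corneaMean, corneaSd = corneaSd,
    irisBase = irisBase, lateralBase = lateralBase,
    artefactFractionIris = artefactFractionIris,
    artefactFractionLateral = artefactFractionLateral,
    artefactValue = artefactValue, background = background,
    apexRow = as.integer(apexRow), thickness = as.integer(thickness),
    edgeRise = edgeRise, arcCols = as.integer(arcCols),
    seed = as.integer(seed))
  class(spec) <- c("phantomSpec", "list")
  .validatePhantomSpec(spec)
  spec
}

.validatePhantomSpec <- function(s) {
  thr <- s$corneaMean + 3 * s$corneaSd
  if (s$width < 64L || s$height < 64L)
    .err("SpecInvalid", "phantom must be at least 64 x 64 pixels")
  if (s$artefactValue <= thr)
    .err("SpecInvalid", sprintf(
      "artefactValue (%.1f) must exceed corneaMean + 3*corneaSd (%.1f)",
      s$artefactValue, thr))
  if (s$irisBase >= thr || s$lateralBase >= thr || s$background >= thr)
    .err("SpecInvalid", "base intensities must stay below the artefact threshold")
  for (f in c(s$artefactFractionIris, s$artefactFractionLateral))
    if (f < 0 || f >= 1) .err("SpecInvalid", "artefact fractions must be in [0, 1)")
  if (s$apexRow < 2L || s$apexRow + s$thickness + s$edgeRise >= s$height / 2)
    .err("SpecInvalid",
         "corneal arc must fit in the upper half of the frame")
  invisible(TRUE)
}

# Anterior boundary row per column: parabola with apex at the frame centre.
.arcBoundary <- function(spec) {
  x <- seq_len(spec$width)
  cx <- (spec$width + 1) / 2
  spec$apexRow + spec$edgeRise * ((x - cx) / (spec$width / 2))^2
}

#' Generate a synthetic Scheimpflug phantom with ground truth
#'
#' Renders the frame described by a [phantomSpec()], together with its
#' ground-truth [RegionMasks-class] (provenance `"external"`) and a
#' bookkeeping list recording the planted artefact counts, region sizes and
#' geometry. Intensities are quantized to integers (8-bit capture) and
#' clipped to [0, 255]. Generation is bit-reproducible for a given spec.
#'
#' The iris band starts one row below the posterior corneal boundary, has
#' height equal to half the corneal thickness, and is restricted to the
#' central third of the width; the lateral flanks occupy the same depth range
#' in the outer thirds. The base intensity continues to the bottom of the
#' frame (anterior-segment tissue does not end at the band), so the band's
#' lower limit is a geometric convention, not an image edge.
#'
#' @param spec A `phantomSpec`.
#' @return A list with elements `frame` ([ScheimpflugFrame-class]), `masks`
#'   ([RegionMasks-class]) and `truth` (planted counts `plantedIris`,
#'   `plantedLateral`, region pixel totals `nIris`, `nLateral`, `nCornea`,
#'   and the geometry used).
#' @export
makePhantom <- function(spec) {
  if (!inherits(spec, "phantomSpec")) spec <- do.call(phantomSpec, spec)
  .validatePhantomSpec(spec)
  w <- spec$width; h <- spec$height
  ya <- round(.arcBoundary(spec))
  yp <- ya + spec$thickness - 1L
  cols <- seq.int(spec$arcCols[1], spec$arcCols[2])
  central <- intersect(.centralThird(w), cols)
  outer <- setdiff(cols, central)

  cornea <- iris <- lateral <- matrix(FALSE, h, w)
  img <- matrix(spec$background, h, w)
  bandH <- max(1L, as.integer(round(spec$thickness / 2)))
  for (x in cols) {
    cr <- ya[x]:yp[x]
    cornea[cr, x] <- TRUE
    below <- seq.int(yp[x] + 1L, h)
    img[below, x] <- if (x %in% central) spec$irisBase else spec$lateralBase
    band <- seq.int(yp[x] + 1L, min(h, yp[x] + bandH))
    if (x %in% central) iris[band, x] <- TRUE else lateral[band, x] <- TRUE
  }

  truth <- .withSeed(spec$seed, {
    img[cornea] <- rnorm(sum(cornea), spec$corneaMean, spec$corneaSd)
    nIris <- sum(iris); nLateral <- sum(lateral)
    plantIris <- round(spec$artefactFractionIris * nIris)
    plantLat <- round(spec$artefactFractionLateral * nLateral)
    if (plantIris > 0)
      img[which(iris)[sample.int(nIris, plantIris)]] <- spec$artefactValue
    if (plantLat > 0)
      img[which(lateral)[sample.int(nLateral, plantLat)]] <- spec$artefactValue
    list(plantedIris = plantIris, plantedLateral = plantLat,
         nIris = nIris, nLateral = nLateral, nCornea = sum(cornea),
         anteriorRow = ya, posteriorRow = yp, bandHeight = bandH,
         spec = spec)
  })
  img <- .clip255(round(img))

  list(
    frame = ScheimpflugFrame(img, eyeId = "phantom", meridianIndex = 1L),
    masks = RegionMasks(cornea, iris, lateral, provenance = "external"),
    truth = truth
  )
}
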