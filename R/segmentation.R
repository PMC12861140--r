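## Automatic delineation of the cornea, iris band and lateral corneoscleral
## flanks in a grayscale Scheimpflug-style frame.
##
## Pipeline: 5x5 median filter -> Canny edge detection (Gaussian smoothing,
## Sobel gradients, non-maximum suppression, hysteresis with thresholds
## derived from the frame's Otsu level) -> the two longest near-horizontal
## edge contours in the upper half of the frame are taken as the anterior
## and posterior corneal boundaries -> region masks are constructed from the
## boundary curves. All downstream densitometry also accepts externally
## supplied masks, so this segmenter is replaceable without touching the
## metric code.

.shiftMat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- seq.int(max(1, 1 + dr), min(h, h + dr))
  cs <- seq.int(max(1, 1 + dc), min(w, w + dc))
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Canny edge detector on a numeric matrix (0-255 scale). Returns a logical
# edge map. high/low are hysteresis thresholds on the Sobel gradient
# magnitude.
.cannyEdges <- function(img, sigma = 1.4, high, low) {
  r <- max(1L, ceiling(3 * sigma))
  g1 <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g1, g1); k <- k / sum(k)
  sm <- EBImage::filter2(img, k, boundary = "replicate")
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sy <- t(sx)
  gx <- EBImage::filter2(sm, sx, boundary = "replicate")
  gy <- EBImage::filter2(sm, sy, boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi          # gradient direction
  bin <- (round(ang / 45) %% 4 + 4) %% 4   # 0=E/W, 1=NE/SW, 2=N/S, 3=NW/SE

  n1 <- n2 <- matrix(0, nrow(img), ncol(img))
  offs <- list(`0` = c(0, 1), `1` = c(-1, 1), `2` = c(1, 0), `3` = c(1, 1))
  for (b in 0:3) {
    o <- offs[[as.character(b)]]
    sel <- bin == b
    n1[sel] <- .shiftMat(mag, -o[1], -o[2])[sel]
    n2[sel] <- .shiftMat(mag,  o[1],  o[2])[sel]
  }
  nms <- mag >= n1 & mag >= n2 & mag > 0

  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(strong)) {
    return(list(edges = matrix(FALSE, nrow(img), ncol(img)), mag = mag))
  }
  lab <- .label8(weak)
  good <- unique(lab[strong])
  list(edges = weak & matrix(lab %in% good, nrow(img), ncol(img)), mag = mag)
}

# Sub-pixel row of an edge pixel: parabolic interpolation of the gradient
# magnitude across the rows above and below. The refined position lands on
# the intensity step (halfway between the two adjacent rows).
.subpixelRow <- function(mag, rows, cols) {
  h <- nrow(mag)
  up <- mag[cbind(pmax(1L, rows - 1L), cols)]
  mid <- mag[cbind(rows, cols)]
  dn <- mag[cbind(pmin(h, rows + 1L), cols)]
  denom <- up - 2 * mid + dn
  off <- ifelse(abs(denom) > .Machine$double.eps, 0.5 * (up - dn) / denom, 0)
  rows + pmax(-0.5, pmin(0.5, off))
}

# 8-connected component labels for a logical mask. EBImage::bwlabel is
# 4-connected, so label a one-pixel dilation and read the labels back at the
# original pixels; this also merges double-response Canny ridges one pixel
# apart, which is what contour grouping wants.
.label8 <- function(mask) {
  dil <- EBImage::dilate(EBImage::Image(mask * 1),
                         EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(dil)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask] <- as.integer(lab[mask])
  out
}

# Principal-axis angle (degrees from horizontal, in [0, 90]) of a pixel set.
.contourAngle <- function(rows, cols) {
  if (length(rows) < 2) return(90)
  v <- eigen(stats::cov(cbind(rows, cols)))$vectors[, 1]
  ang <- atan2(abs(v[1]), abs(v[2])) * 180 / pi
  ang
}

# Median boundary row per column, linearly interpolated over interior gaps.
# Returns a numeric vector indexed by column (NA outside the contour span).
.boundaryCurve <- function(rows, cols, width) {
  med <- tapply(rows, cols, stats::median)
  xs <- as.integer(names(med))
  out <- rep(NA_real_, width)
  span <- seq.int(min(xs), max(xs))
  out[span] <- stats::approx(xs, as.numeric(med), xout = span)$y
  out
}

#' Segment a Scheimpflug frame into cornea, iris and lateral regions
#'
#' Detects the anterior and posterior corneal boundaries as the two longest
#' near-horizontal Canny edge contours in the upper half of the frame, fills
#' the area between them as the cornea, and constructs the iris band (half
#' the local corneal thickness, measured downward from the posterior
#' boundary, restricted to the central third of the width) and the lateral
#' flank regions (the same depth range in the outer thirds). Hysteresis
#' thresholds default to the frame's Otsu level (high) and half of it (low),
#' applied to the Sobel gradient magnitude; when fewer than two candidate
#' contours emerge (a weak posterior boundary under low cornea-iris
#' contrast), detection is retried at halved thresholds before failing.
#'
#' The detected sub-pixel boundary curves sit half a pixel outside the first
#' and last corneal rows (the gradient peaks at the intensity step between
#' rows), so half a pixel is added/subtracted before rounding to rows.
#'
#' @param frame A [ScheimpflugFrame-class].
#' @param medianKernel Odd side length of the median prefilter (default 5).
#' @param cannySigma Gaussian smoothing sigma inside the edge detector.
#' @param cannyThresholds `NULL` for Otsu-derived hysteresis thresholds, or
#'   a numeric `c(low, high)` on the gradient-magnitude scale.
#' @return A [RegionMasks-class] with provenance `"automatic"`.
#' @section Errors: `NoEdgesFound` when fewer than two candidate corneal
#'   contours are detected (blank or uninterpretable frame);
#'   `DegenerateRegion` when any required region is empty after construction.
#' @examples
#' ph <- makePhantom(phantomSpec(seed = 1))
#' m <- segmentFrame(ph$frame)
#' diceCoefficient(corneaMask(m), corneaMask(ph$masks))
#' @export
segmentFrame <- function(frame, medianKernel = 5L, cannySigma = 1.4,
                         cannyThresholds = NULL) {
  stopifnot(is(frame, "ScheimpflugFrame"))
  img <- framePixels(frame)
  h <- nrow(img); w <- ncol(img)
  if (diff(range(img)) == 0)
    .err("NoEdgesFound", "frame has no intensity variation")

  size <- max(1L, as.integer((medianKernel - 1) / 2))
  med <- EBImage::medianFilter(img / 255, size) * 255

  if (is.null(cannyThresholds)) {
    highT <- EBImage::otsu(EBImage::Image(med / 255), range = c(0, 1)) * 255
    lowT <- highT / 2
  } else {
    lowT <- cannyThresholds[1]; highT <- cannyThresholds[2]
  }
  # a weak posterior boundary (low cornea-iris contrast) can fall below the
  # Otsu-derived thresholds; retry at halved thresholds before giving up
  cand <- list()
  for (scale in c(1, 0.5, 0.25)) {
    cn <- .cannyEdges(med, sigma = cannySigma,
                      high = highT * scale, low = lowT * scale)
    lab <- .label8(cn$edges)
    idx <- which(lab > 0)
    if (length(idx) == 0) next
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L

    cand <- lapply(split(seq_along(idx), lab[idx]), function(i) {
      r <- rows[i]; cc <- cols[i]
      list(rows = r, cols = cc, n = length(i),
           meanRow = mean(r), angle = .contourAngle(r, cc))
    })
    cand <- Filter(function(co) co$angle <= 30 && co$meanRow <= h / 2, cand)
    if (length(cand) >= 2) break
  }
  if (length(cand) < 2)
    .err("NoEdgesFound",
         "fewer than two near-horizontal corneal contours found")
  cand <- cand[order(vapply(cand, `[[`, 0, "n"), decreasing = TRUE)][1:2]
  if (cand[[1]]$meanRow > cand[[2]]$meanRow) cand <- cand[c(2, 1)]

  ya <- .boundaryCurve(.subpixelRow(cn$mag, cand[[1]]$rows, cand[[1]]$cols),
                       cand[[1]]$cols, w)
  yp <- .boundaryCurve(.subpixelRow(cn$mag, cand[[2]]$rows, cand[[2]]$cols),
                       cand[[2]]$cols, w)
  span <- which(!is.na(ya) & !is.na(yp) & yp > ya)
  if (length(span) == 0)
    .err("DegenerateRegion", "corneal boundaries do not overlap in any column")

  cornea <- iris <- lateral <- matrix(FALSE, h, w)
  central <- .centralThird(w)
  top <- pmax(1L, pmin(h, as.integer(round(ya + 0.5))))
  bot <- pmax(1L, pmin(h, as.integer(round(yp - 0.5))))
  for (x in span) {
    if (bot[x] < top[x]) next
    cornea[top[x]:bot[x], x] <- TRUE
    t <- bot[x] - top[x] + 1L
    bandH <- max(1L, as.integer(round(t / 2)))
    b0 <- bot[x] + 1L
    if (b0 > h) next
    band <- seq.int(b0, min(h, bot[x] + bandH))
    if (x %in% central) iris[band, x] <- TRUE else lateral[band, x] <- TRUE
  }
  for (nm in c("cornea", "iris", "lateral")) {
    if (!any(get(nm)))
      .err("DegenerateRegion", sprintf("constructed %s region is empty", nm))
  }
  RegionMasks(cornea, iris, lateral, provenance = "automatic")
}

#' Validate externally supplied region masks against a frame
#'
#' Checks that masks loaded from a label image match the frame's dimensions,
#' are pairwise disjoint, and that every region is non-empty, then stamps
#' them with provenance `"external"`. This is the entry point for
#' substituting any external segmentation for the built-in one.
#'
#' @param frame A [ScheimpflugFrame-class].
#' @param masks A [RegionMasks-class], or a named list with logical matrices
#'   `cornea`, `iris`, `lateral` (e.g. three separately loaded mask files,
#'   which unlike a single label image may overlap).
#' @return The masks as a [RegionMasks-class] with provenance `"external"`.
#' @section Errors: `MaskMismatch` (dimensions differ), `MaskOverlap`
#'   (regions intersect), `DegenerateRegion` (an empty region).
#' @export
validateMasks <- function(frame, masks) {
  stopifnot(is(frame, "ScheimpflugFrame"))
  ms <- if (is(masks, "RegionMasks")) {
    list(cornea = corneaMask(masks), iris = irisMask(masks),
         lateral = lateralMask(masks))
  } else {
    stopifnot(all(c("cornea", "iris", "lateral") %in% names(masks)))
    lapply(masks[c("cornea", "iris", "lateral")],
           function(m) matrix(as.logical(m), nrow(m)))
  }
  d <- dim(ms$cornea)
  if (!identical(dim(ms$iris), d) || !identical(dim(ms$lateral), d) ||
      !identical(frameDim(frame), d))
    .err("MaskMismatch", "mask dimensions do not match the frame")
  if (any(ms$cornea & ms$iris) || any(ms$cornea & ms$lateral) ||
      any(ms$iris & ms$lateral))
    .err("MaskOverlap", "region masks intersect")
  for (nm in names(ms)) {
    if (!any(ms[[nm]]))
      .err("DegenerateRegion", sprintf("%s region is empty", nm))
  }
  RegionMasks(ms$cornea, ms$iris, ms$lateral, provenance = "external")
}
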