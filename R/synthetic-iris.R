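## Synthetic slit-lamp iris images along a blue -> brown pigmentation
## gradient, with recorded CIELAB ground truth.

# CIELAB anchors of the pigmentation gradient: a light blue-gray iris at
# level 0 (high L*, slightly negative a*, negative b*) and a dark brown iris
# at level 1 (low L*, positive a* and b*). All three components are affine
# in the level, so -L*, a* and b* increase monotonically with pigmentation.
.irisLabAnchors <- list(
  light = c(L = 75, a = -4, b = -10),
  dark = c(L = 32, a = 16, b = 24)
)

.irisLabAt <- function(level) {
  .irisLabAnchors$light + level * (.irisLabAnchors$dark - .irisLabAnchors$light)
}

#' Render a synthetic iris photograph at a given pigmentation level
#'
#' Draws an annular iris whose base color interpolates in CIELAB between a
#' light blue-gray anchor (level 0) and a dark brown anchor (level 1),
#' converts to 8-bit sRGB, and adds seeded per-pixel Gaussian noise. The
#' central disk (pupil) is rendered dark and excluded from the ROI, and the
#' surround is rendered as a bright sclera-like field. The recorded ground
#' truth is the noise-free CIELAB triple of the annulus.
#'
#' @param pigmentation Level in [0, 1]; 0 = lightest, 1 = darkest.
#' @param seed Integer seed; the image is a pure function of its arguments.
#' @param size Image side length in pixels (square image).
#' @param noiseSd Per-channel Gaussian noise SD on the 0--255 RGB scale
#'   (0 for a noise-free image).
#' @return List with `image` (numeric `size x size x 3` array, 0--255),
#'   `roi` (logical annulus mask) and `truth` (list with `lab`, the planted
#'   CIELAB triple, and the arguments).
#' @section Errors: `SpecInvalid` when `pigmentation` is outside [0, 1].
#' @examples
#' im <- makeIrisImage(0.8, seed = 1)
#' summarizeIrisRoi(rgbToCielab(im$image), im$roi)
#' @export
makeIrisImage <- function(pigmentation, seed = 1L, size = 96L, noiseSd = 2) {
  if (!is.finite(pigmentation) || pigmentation < 0 || pigmentation > 1)
    .err("SpecInvalid", "pigmentation level must lie in [0, 1]")
  size <- as.integer(size)
  lab <- .irisLabAt(pigmentation)
  rgb <- grDevices::convertColor(matrix(lab, 1), from = "Lab", to = "sRGB")
  rgb <- .clip255(as.numeric(rgb) * 255)

  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  dist <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  roi <- dist <= 0.45 * size & dist >= 0.15 * size
  pupil <- dist < 0.15 * size

  img <- array(230, c(size, size, 3))              # sclera-like surround
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[roi] <- rgb[ch]
    plane[pupil] <- 25
    img[, , ch] <- plane
  }
  img <- .withSeed(seed, {
    if (noiseSd > 0) {
      img + array(stats::rnorm(length(img), 0, noiseSd), dim(img))
    } else img
  })
  img <- .clip255(round(img))

  list(image = img, roi = roi,
       truth = list(lab = lab, pigmentation = pigmentation,
                    seed = seed, size = size, noiseSd = noiseSd))
}
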