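## Reading and writing frames, label masks and color images.
##
## Frames are 8-bit grayscale PNG or TIFF; region masks travel as a single
## 8-bit label PNG with codes 0 = background, 1 = cornea, 2 = iris,
## 3 = lateral; iris ROI masks are binary (0/255) PNGs.

.readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
}

#' Read a grayscale Scheimpflug frame from a PNG/TIFF file
#'
#' @param path Image file; multi-channel images are reduced to their first
#'   channel.
#' @param eyeId,meridianIndex Identity attached to the frame.
#' @return A [ScheimpflugFrame-class] with intensities on the 0--255 scale.
#' @export
readFrame <- function(path, eyeId = "eye", meridianIndex = 1L) {
  img <- .readImageFile(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  ScheimpflugFrame(round(img * 255), eyeId = eyeId,
                   meridianIndex = meridianIndex)
}

#' Read region masks from an 8-bit label image
#'
#' @param path Label PNG/TIFF with codes 0 = background, 1 = cornea,
#'   2 = iris, 3 = lateral.
#' @return A [RegionMasks-class] with provenance `"external"`.
#' @export
readMasks <- function(path) {
  img <- .readImageFile(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  lab <- round(img * 255)
  RegionMasks(cornea = lab == 1, iris = lab == 2, lateral = lab == 3,
              provenance = "external")
}

#' Write region masks as an 8-bit label PNG
#'
#' @param masks A [RegionMasks-class].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
writeMasks <- function(masks, path) {
  stopifnot(is(masks, "RegionMasks"))
  lab <- matrix(0L, nrow(corneaMask(masks)), ncol(corneaMask(masks)))
  lab[corneaMask(masks)] <- 1L
  lab[irisMask(masks)] <- 2L
  lab[lateralMask(masks)] <- 3L
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' Write a frame as an 8-bit grayscale PNG
#'
#' @param frame A [ScheimpflugFrame-class].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
writeFrame <- function(frame, path) {
  stopifnot(is(frame, "ScheimpflugFrame"))
  png::writePNG(framePixels(frame) / 255, path)
  invisible(path)
}

#' Read an RGB color image (slit-lamp photograph)
#'
#' @param path PNG/TIFF file with at least three channels.
#' @return Numeric `h x w x 3` array on the 0--255 scale.
#' @export
readRgbImage <- function(path) {
  img <- .readImageFile(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    .err("NotColorImage", "expected an RGB image file")
  img[, , 1:3, drop = FALSE] * 255
}

#' Read a binary (0/255) ROI mask
#'
#' @param path PNG/TIFF file; any nonzero pixel counts as inside.
#' @return Logical matrix.
#' @export
readRoiMask <- function(path) {
  img <- .readImageFile(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
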