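## Internal helpers shared across modules.

# Signal a classed error so callers/tests can dispatch on the failure kind.
.err <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "iridensError")))
}

.clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

.isBinaryMask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

#' Dice overlap coefficient between two binary masks
#'
#' Computes 2|A intersect B| / (|A| + |B|), the standard overlap score used to
#' compare a segmentation mask against ground truth. Returns 1 when both
#' masks are empty (perfect agreement on absence).
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return A number in [0, 1].
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, ] <- TRUE
#' diceCoefficient(m, m)
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
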