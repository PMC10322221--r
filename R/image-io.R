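## Image containers and file I/O.
##
## Internal convention: grayscale image = numeric matrix m[y, x] with
## intensities in [0, 255]; RGB image = numeric array a[y, x, channel];
## binary mask = logical matrix; A/V label mask = integer matrix with
## 0 = background, 1 = artery, 2 = vein, 3 = unknown.
## EBImage stores images transposed (x, y[, c]) and scaled to [0, 1];
## the two helpers below convert at the boundary.

#' @noRd
.as_ebimage <- function(m) {
  if (length(dim(m)) == 3L) {
    EBImage::Image(aperm(m, c(2L, 1L, 3L)) / 255, colormode = "Color")
  } else {
    EBImage::Image(t(m) / 255)
  }
}

#' @noRd
.from_ebimage <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) aperm(d, c(2L, 1L, 3L)) * 255 else t(d) * 255
}

#' @noRd
.assert_image <- function(x, what = "image") {
  if (!is.numeric(x) || !(length(dim(x)) %in% c(2L, 3L)))
    stop(what, " must be a numeric matrix (H x W) or array (H x W x 3)",
         call. = FALSE)
  if (length(dim(x)) == 3L && dim(x)[3L] != 3L)
    stop(what, " must have 3 channels", call. = FALSE)
  invisible(x)
}

#' Read an image file
#'
#' Reads an 8-bit PNG/JPEG/TIFF image into the package's matrix
#' representation (intensities 0-255, `m[y, x]`).
#'
#' @param path file path.
#' @return A numeric matrix (grayscale file) or `H x W x 3` array (colour
#'   file). Alpha channels are dropped.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L && dim(d)[3L] > 3L)   # drop alpha
    d <- d[, , 1:3, drop = FALSE]
  if (length(dim(d)) == 3L && dim(d)[3L] == 2L)  # gray + alpha
    d <- d[, , 1L]
  if (length(dim(d)) == 3L) aperm(d, c(2L, 1L, 3L)) * 255 else t(d) * 255
}

#' Read a binary mask
#'
#' Single-channel PNG with 0 = background, 255 = foreground (any value
#' above 127 counts as foreground).
#'
#' @param path file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 127
}

#' Read an artery/vein label mask
#'
#' Coded single-channel PNG with labels 0 (background), 1 (artery),
#' 2 (vein), 3 (unknown).
#'
#' @param path file path.
#' @return integer matrix with values in 0..3.
#' @export
read_av_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  lab <- as.integer(round(m))
  if (any(lab > 3L)) lab <- as.integer(round(m / 85))  # {0,85,170,255} coding
  lab[lab > 3L] <- 3L
  matrix(lab, nrow = nrow(m))
}

#' Write an image or mask as PNG
#'
#' @param x numeric image (0-255), logical mask, or integer label mask.
#' @param path output path (extension selects the format; PNG recommended).
#' @export
write_image <- function(x, path) {
  if (is.logical(x)) x <- x * 255
  x <- pmin(pmax(x, 0), 255)
  EBImage::writeImage(.as_ebimage(x), path)
  invisible(path)
}
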