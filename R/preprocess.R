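## Image conditioning chain: ROI extraction, median denoising, mean
## calibration + resampling, CLAHE enhancement, grayscale conversion.

#' Grayscale conversion weights
#'
#' The pipeline's grayscale formula is `Gray = 0.299 R + 0.587 G + 0.144 B`
#' (note the blue weight 0.144, so the weights sum to 1.030). The
#' conventional ITU-R BT.601 triple (blue weight 0.114, sum 1) is available
#' as an alternative.
#'
#' @param convention `"pipeline"` (default, blue weight 0.144) or
#'   `"bt601"` (blue weight 0.114).
#' @return numeric length-3 vector of R, G, B weights.
#' @export
gray_coeffs <- function(convention = c("pipeline", "bt601")) {
  convention <- match.arg(convention)
  switch(convention,
         pipeline = c(0.299, 0.587, 0.144),
         bt601    = c(0.299, 0.587, 0.114))
}

#' Preprocessing configuration
#'
#' @param roi_threshold_fraction fraction of the mean R-channel grey value
#'   used as the ROI preselection threshold (default 1/3).
#' @param median_kernel odd median-filter window size in pixels (>= 3).
#' @param target_size output side length in pixels for resampling; `NULL`
#'   keeps the input size.
#' @param reference_means per-channel target means for brightness/colour
#'   calibration; `NULL` skips calibration.
#' @param mean_mode `"additive"` (shift) or `"multiplicative"` (gain)
#'   calibration.
#' @param clahe_clip CLAHE clip limit (> 0).
#' @param clahe_tiles CLAHE tile grid, length-2 integer (nx, ny).
#' @param gray_coeffs grayscale weights, see [gray_coeffs()].
#' @param opening_radius structuring-disk radius in pixels for the ROI
#'   boundary opening, at a 1024-px working size (scaled proportionally).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(roi_threshold_fraction = 1 / 3,
                              median_kernel = 3L,
                              target_size = 1024L,
                              reference_means = NULL,
                              mean_mode = c("additive", "multiplicative"),
                              clahe_clip = 2,
                              clahe_tiles = c(8L, 8L),
                              gray_coeffs = retmorph::gray_coeffs(),
                              opening_radius = 5) {
  stopifnot(roi_threshold_fraction > 0, roi_threshold_fraction < 1,
            median_kernel >= 3, median_kernel %% 2 == 1,
            clahe_clip > 0, all(clahe_tiles >= 1), all(gray_coeffs > 0))
  structure(list(roi_threshold_fraction = roi_threshold_fraction,
                 median_kernel = as.integer(median_kernel),
                 target_size = target_size,
                 reference_means = reference_means,
                 mean_mode = match.arg(mean_mode),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 gray_coeffs = gray_coeffs,
                 opening_radius = opening_radius),
            class = "preprocess_config")
}

#' Convert an RGB image to grayscale
#'
#' Weighted channel sum `Gray = w_R R + w_G G + w_B B`. No clipping is
#' applied, so with the pipeline weights (sum 1.030) output values may
#' slightly exceed 255.
#'
#' @param image `H x W x 3` array, intensities 0-255.
#' @param coeffs length-3 positive weights, see [gray_coeffs()].
#' @return numeric matrix.
#' @export
to_grayscale <- function(image, coeffs = gray_coeffs()) {
  .assert_image(image)
  if (length(dim(image)) == 2L) return(image)
  stopifnot(length(coeffs) == 3L, all(coeffs > 0))
  image[, , 1L] * coeffs[1L] + image[, , 2L] * coeffs[2L] +
    image[, , 3L] * coeffs[3L]
}

#' Extract the fundus region of interest
#'
#' Thresholds the red channel at a fraction of its mean grey value,
#' keeps the largest connected component, and smooths its boundary by
#' morphological opening. The result is the effective retinal imaging
#' area (camera aperture).
#'
#' @param image RGB array or grayscale matrix (then used as the R channel).
#' @param cfg [preprocess_config()].
#' @return logical matrix, a single connected component.
#' @export
extract_roi <- function(image, cfg = preprocess_config()) {
  .assert_image(image)
  r <- if (length(dim(image)) == 3L) image[, , 1L] else image
  m <- mean(r)
  if (m <= 0) stop("empty ROI: image has no positive R-channel intensity",
                   call. = FALSE)
  cand <- r >= cfg$roi_threshold_fraction * m & r > 0
  if (!any(cand)) stop("empty ROI: no pixel passes the threshold",
                       call. = FALSE)
  cand <- .largest_component(cand)
  rad <- max(1L, round(cfg$opening_radius * min(dim(r)) / 1024))
  brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
  opened <- .from_ebimage(EBImage::opening(.as_ebimage(cand * 255), brush)) > 127
  if (!any(opened)) opened <- cand   # opening erased a small ROI; keep it
  .largest_component(opened)
}

#' @noRd
.largest_component <- function(mask) {
  lab <- .label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' @noRd
.label_components <- function(mask) {
  lab <- EBImage::bwlabel(.as_ebimage(mask * 255))
  matrix(as.integer(t(EBImage::imageData(lab))), nrow = nrow(mask))
}

## 8-connected component labels (bwlabel is 4-connected; vessel masks and
## skeletons rely on diagonal adjacency).
#' @noRd
.label_components_8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, h, w)
  if (!length(idx)) return(out)
  node <- matrix(0L, h, w)
  node[idx] <- seq_along(idx)
  ys <- (idx - 1L) %% h + 1L
  xs <- (idx - 1L) %/% h + 1L
  edges <- list()
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    yy <- ys + o[1L]; xx <- xs + o[2L]
    ok <- yy >= 1L & yy <= h & xx >= 1L & xx <= w
    j <- (xx[ok] - 1L) * h + yy[ok]
    hit <- mask[j]
    edges[[length(edges) + 1L]] <- cbind(node[idx[ok]][hit], node[j][hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  out[idx] <- as.integer(igraph::components(g)$membership)
  out
}

#' Median denoising
#'
#' Replaces every pixel by the median of its `kernel x kernel`
#' neighbourhood (per channel for RGB input); image edges are handled by
#' reflection padding.
#'
#' @param image grayscale matrix or RGB array (0-255).
#' @param kernel odd window size >= 3.
#' @return same shape as input.
#' @export
median_denoise <- function(image, kernel = 3L) {
  .assert_image(image)
  if (kernel < 3 || kernel %% 2 != 1) stop("kernel must be odd and >= 3",
                                           call. = FALSE)
  if (length(dim(image)) == 3L) {
    out <- image
    for (ch in 1:3) out[, , ch] <- median_denoise(image[, , ch], kernel)
    return(out)
  }
  r <- (kernel - 1L) %/% 2L
  padded <- .pad_reflect(image, r)
  f <- .from_ebimage(EBImage::medianFilter(.as_ebimage(padded), size = r,
                                           cacheSize = 64L))
  h <- nrow(image); w <- ncol(image)
  out <- f[(r + 1L):(r + h), (r + 1L):(r + w)]
  if (all(image == round(image))) out <- round(out)
  pmin(pmax(out, 0), 255)
}

#' @noRd
.pad_reflect <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  ridx <- c(rev(seq_len(min(r, h - 1L)) + 1L),
            rep(1L, max(0L, r - h + 1L)), 1:h,
            rev(h - seq_len(min(r, h - 1L))),
            rep(h, max(0L, r - h + 1L)))
  cidx <- c(rev(seq_len(min(r, w - 1L)) + 1L),
            rep(1L, max(0L, r - w + 1L)), 1:w,
            rev(w - seq_len(min(r, w - 1L))),
            rep(w, max(0L, r - w + 1L)))
  m[ridx, cidx, drop = FALSE]
}

#' Corner-aligned bilinear resize
#'
#' Separable linear interpolation with the source grid corners mapped to
#' the output grid corners (so a 2x2 image resized to 3x3 places the
#' 4-pixel average at the center).
#'
#' @param image grayscale matrix or RGB array.
#' @param out_h,out_w output dimensions in pixels (>= 2).
#' @return resized image.
#' @export
bilinear_resize <- function(image, out_h, out_w = out_h) {
  .assert_image(image)
  if (out_h < 2 || out_w < 2) stop("degenerate target size", call. = FALSE)
  if (length(dim(image)) == 3L) {
    out <- array(0, dim = c(out_h, out_w, 3L))
    for (ch in 1:3) out[, , ch] <- bilinear_resize(image[, , ch], out_h, out_w)
    return(out)
  }
  h <- nrow(image); w <- ncol(image)
  sy <- if (h == 1L) rep(1, out_h) else seq(1, h, length.out = out_h)
  sx <- if (w == 1L) rep(1, out_w) else seq(1, w, length.out = out_w)
  y0 <- pmin(floor(sy), h - 1L); wy <- sy - y0
  x0 <- pmin(floor(sx), w - 1L); wx <- sx - x0
  rows <- image[y0, , drop = FALSE] * (1 - wy) + image[y0 + 1L, , drop = FALSE] * wy
  wxm <- matrix(wx, out_h, out_w, byrow = TRUE)
  rows[, x0, drop = FALSE] * (1 - wxm) + rows[, x0 + 1L, drop = FALSE] * wxm
}

#' Brightness/colour calibration and resampling
#'
#' Adjusts each channel's mean to a reference mean (additive shift by
#' default, multiplicative gain as alternative), clips to `[0, 255]`, and
#' resamples to a uniform size by corner-aligned bilinear interpolation.
#'
#' @param image RGB array or grayscale matrix.
#' @param reference_means per-channel target means in (0, 255); scalar for
#'   grayscale. `NULL` skips calibration.
#' @param target_size length-1 or length-2 (h, w) output size; `NULL`
#'   keeps the input size.
#' @param mode `"additive"` or `"multiplicative"`.
#' @return calibrated, resampled image.
#' @export
normalize_image <- function(image, reference_means = NULL, target_size = NULL,
                            mode = c("additive", "multiplicative")) {
  .assert_image(image)
  mode <- match.arg(mode)
  nch <- if (length(dim(image)) == 3L) 3L else 1L
  if (!is.null(reference_means)) {
    stopifnot(all(reference_means > 0), all(reference_means < 255))
    reference_means <- rep_len(reference_means, nch)
    adjust <- function(ch, ref) {
      m <- mean(ch)
      out <- if (mode == "additive") ch + (ref - m)
             else if (m > 0) ch * (ref / m) else ch
      pmin(pmax(out, 0), 255)
    }
    if (nch == 3L) {
      for (ch in 1:3) image[, , ch] <- adjust(image[, , ch], reference_means[ch])
    } else image <- adjust(image, reference_means)
  }
  if (!is.null(target_size)) {
    ts <- rep_len(as.integer(target_size), 2L)
    image <- bilinear_resize(image, ts[1L], ts[2L])
  }
  image
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE on a grayscale image: local histogram equalization on a tile
#' grid with a clip limit to bound contrast amplification.
#'
#' @param image grayscale matrix (0-255).
#' @param clip clip limit (> 0); higher values allow stronger enhancement.
#' @param tiles length-2 integer tile grid (nx, ny).
#' @return enhanced grayscale matrix in `[0, 255]`.
#' @export
clahe_enhance <- function(image, clip = 2, tiles = c(8L, 8L)) {
  .assert_image(image)
  stopifnot(clip > 0, all(tiles >= 1))
  tiles <- rep_len(as.integer(tiles), 2L)
  x <- pmin(pmax(image, 0), 255)
  if (max(x) - min(x) < 1e-9) return(x)  # flat histogram: nothing to equalize
  out <- .from_ebimage(EBImage::clahe(.as_ebimage(x),
                                      nx = tiles[1L], ny = tiles[2L],
                                      limit = clip))
  pmin(pmax(out, 0), 255)
}

#' Run the full preprocessing chain
#'
#' ROI extraction, median denoising, mean calibration + resampling, then
#' CLAHE enhancement of the grayscale conversion — in that order. The ROI
#' mask is carried through the resampling (nearest neighbour).
#'
#' @param image RGB array (0-255).
#' @param cfg [preprocess_config()].
#' @return list with elements `image` (conditioned RGB), `gray` (enhanced
#'   grayscale), `gray_raw` (unenhanced grayscale) and `roi` (logical mask).
#' @export
preprocess <- function(image, cfg = preprocess_config()) {
  .assert_image(image)
  roi <- extract_roi(image, cfg)
  image <- median_denoise(image, cfg$median_kernel)
  image <- normalize_image(image, cfg$reference_means, cfg$target_size,
                           cfg$mean_mode)
  if (!is.null(cfg$target_size)) {
    ts <- rep_len(as.integer(cfg$target_size), 2L)
    roi <- .resize_nearest(roi, ts[1L], ts[2L])
  }
  gray <- to_grayscale(image, cfg$gray_coeffs)
  enhanced <- clahe_enhance(pmin(gray, 255), cfg$clahe_clip, cfg$clahe_tiles)
  list(image = image, gray = enhanced, gray_raw = gray, roi = roi)
}

#' @noRd
.resize_nearest <- function(mask, out_h, out_w) {
  h <- nrow(mask); w <- ncol(mask)
  sy <- round(seq(1, h, length.out = out_h))
  sx <- round(seq(1, w, length.out = out_w))
  mask[sy, sx, drop = FALSE]
}
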