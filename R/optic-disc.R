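## Optic disc localization, polar boundary tracing, minimum enclosing
## circle, and papillary-diameter (PD) calibration. The disc diameter is
## assumed to be 1.5 mm and provides the pixel-to-mm conversion.

#' Locate the optic disc
#'
#' Brightness heuristic: the disc is the brightest large structure in an
#' optic-disc-centred fundus photograph. The image is Gaussian-smoothed,
#' thresholded at a top intensity percentile within the ROI, and the
#' centroid of the largest bright component is returned. A user-supplied
#' seed is passed through verbatim.
#'
#' @param image RGB array or grayscale matrix (0-255).
#' @param roi optional logical ROI mask.
#' @param seed optional length-2 `c(x, y)` user seed, returned unchanged.
#' @param percentile intensity percentile defining "bright" (default 0.99).
#' @param sigma Gaussian smoothing sd in pixels.
#' @param min_area minimum bright-component area in pixels.
#' @return list with `center` (`c(x, y)`) and `source`
#'   (`"heuristic"` or `"user"`).
#' @export
locate_disc <- function(image, roi = NULL, seed = NULL, percentile = 0.99,
                        sigma = 5, min_area = 50) {
  if (!is.null(seed)) {
    stopifnot(length(seed) == 2L)
    return(list(center = as.numeric(seed), source = "user"))
  }
  gray <- if (length(dim(image)) == 3L)
    (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3 else image
  sm <- .from_ebimage(EBImage::gblur(.as_ebimage(pmin(pmax(gray, 0), 255)),
                                     sigma = sigma))
  vals <- if (is.null(roi)) sm else sm[roi]
  if (length(vals) == 0L) stop("ROI is empty", call. = FALSE)
  q <- quantile(vals, percentile, names = FALSE)
  med <- median(vals)
  if (q - med < 5)
    stop("disc seed not found: no distinct bright structure", call. = FALSE)
  bright <- sm >= (q + med) / 2   # midway cut is stable on flat-topped discs
  if (!is.null(roi)) bright <- bright & roi
  if (!any(bright))
    stop("disc seed not found: no bright region above percentile",
         call. = FALSE)
  comp <- .largest_component(bright)
  if (sum(comp) < min_area)
    stop("disc seed not found: bright region too small", call. = FALSE)
  idx <- which(comp)
  ys <- (idx - 1L) %% nrow(comp) + 1L
  xs <- (idx - 1L) %/% nrow(comp) + 1L
  list(center = c(mean(xs), mean(ys)), source = "heuristic")
}

#' @noRd
.bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 1), w); y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0
  m[i00] * (1 - fx) * (1 - fy) + m[i00 + h] * fx * (1 - fy) +
    m[i00 + 1] * (1 - fx) * fy + m[i00 + h + 1] * fx * fy
}

#' Trace the optic disc boundary in polar coordinates
#'
#' Transforms the grayscale image to polar coordinates about the seed,
#' applies a 1-D derivative-of-Gaussian edge operator along each radial
#' column, takes the strongest bright-to-dark transition as the boundary
#' radius for each angle, and median-smooths the radii across angles.
#'
#' @param gray grayscale matrix (0-255).
#' @param seed disc seed from [locate_disc()] or a length-2 `c(x, y)`.
#' @param n_angles number of uniform angular samples over `[0, 2*pi)`.
#' @param r_max maximum search radius in pixels (default
#'   `0.4 * min(H, W)`); the seed must lie at least `r_max` inside the
#'   frame for full coverage (profiles are clamped at the border).
#' @param sigma edge-operator Gaussian sd in pixels.
#' @param smooth_window circular median window (odd) across angles.
#' @return list of class `disc_boundary`: `center`, `theta`, `radii`,
#'   `points` (n x 2 boundary coordinates).
#' @export
trace_boundary_polar <- function(gray, seed, n_angles = 360L, r_max = NULL,
                                 sigma = 2, smooth_window = 9L) {
  center <- if (is.list(seed)) seed$center else as.numeric(seed)
  if (is.null(r_max)) r_max <- 0.4 * min(dim(gray))
  stopifnot(r_max > 4)
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  rr <- seq(1, r_max, by = 0.5)
  # polar image: rows = radius, cols = angle
  xs <- outer(rr, cos(theta), function(r, c) center[1L] + r * c)
  ys <- outer(rr, sin(theta), function(r, s) center[2L] + r * s)
  polar <- matrix(.bilinear_sample(gray, as.vector(xs), as.vector(ys)),
                  nrow = length(rr))
  # derivative-of-Gaussian kernel along the radius (step 0.5 px)
  ks <- sigma / 0.5
  t0 <- seq(-ceiling(3 * ks), ceiling(3 * ks))
  kern <- -t0 * exp(-t0^2 / (2 * ks^2))
  kern <- kern / sum(pmax(kern, 0))   # unit response to a unit step
  ## edge strength: positive at a bright-to-dark radial transition
  resp <- apply(polar, 2L, function(col)
    as.numeric(stats::filter(col, rev(kern), sides = 2)))
  resp[is.na(resp)] <- 0
  if (max(resp) < 1e-6)
    stop("boundary not found: flat radial profiles", call. = FALSE)
  ridx <- apply(resp, 2L, which.max)
  radii <- rr[ridx]
  radii <- .circular_median(radii, smooth_window)
  pts <- cbind(x = center[1L] + radii * cos(theta),
               y = center[2L] + radii * sin(theta))
  structure(list(center = center, theta = theta, radii = radii,
                 points = pts),
            class = "disc_boundary")
}

#' @noRd
.circular_median <- function(x, window) {
  if (window < 2L) return(x)
  n <- length(x)
  r <- window %/% 2L
  ext <- c(tail(x, r), x, head(x, r))
  vapply(seq_len(n), function(i) median(ext[i:(i + 2L * r)]), numeric(1L))
}

#' Minimum enclosing circle
#'
#' Smallest circle containing all input points (Welzl-style incremental
#' construction with a deterministic scrambled insertion order).
#'
#' @param points n x 2 matrix of (x, y) coordinates, n >= 2.
#' @return list with `center` (`c(x, y)`), `radius` and `diameter`.
#' @export
min_enclosing_circle <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(n) || n < 2L) stop("need at least 2 points", call. = FALSE)
  # deterministic pseudo-random insertion order (expected linear time)
  ord <- order(sin(seq_len(n) * 12.9898 + 78.233) * 43758.5453 %% 1)
  p <- points[ord, , drop = FALSE]
  inside <- function(c_, q) {
    sqrt(sum((q - c_$center)^2)) <= c_$radius + 1e-9
  }
  circ2 <- function(a, b) list(center = (a + b) / 2,
                               radius = sqrt(sum((a - b)^2)) / 2)
  circ3 <- function(a, b, c) {
    d <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
                c[1L] * (a[2L] - b[2L]))
    if (abs(d) < 1e-12) {   # collinear: widest pair
      cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      return(cands[[which.max(vapply(cands, `[[`, 0, "radius"))]])
    }
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
    ux <- (a2 * (b[2L] - c[2L]) + b2 * (c[2L] - a[2L]) +
             c2 * (a[2L] - b[2L])) / d
    uy <- (a2 * (c[1L] - b[1L]) + b2 * (a[1L] - c[1L]) +
             c2 * (b[1L] - a[1L])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  circ <- circ2(p[1L, ], p[2L, ])
  if (n > 2L) for (i in 3:n) {
    if (inside(circ, p[i, ])) next
    circ <- circ2(p[1L, ], p[i, ])
    for (j in seq_len(i - 1L)[-1L]) {
      if (inside(circ, p[j, ])) next
      circ <- circ2(p[i, ], p[j, ])
      for (k in seq_len(j - 1L)) {
        if (inside(circ, p[k, ])) next
        circ <- circ3(p[i, ], p[j, ], p[k, ])
      }
    }
  }
  list(center = circ$center, radius = circ$radius,
       diameter = 2 * circ$radius)
}

#' Papillary-diameter calibration
#'
#' Converts the fitted disc circle to an `optic_disc` object carrying the
#' pixel-to-mm calibration derived from the 1.5 mm reference papillary
#' diameter: `mm_per_px = 1.5 / diameter_px`.
#'
#' @param center length-2 `c(x, y)` disc center in pixels.
#' @param diameter_px disc diameter (PD) in pixels, > 0.
#' @return list of class `optic_disc`: `center_xy`, `diameter_px`,
#'   `mm_per_px`.
#' @export
calibrate_disc <- function(center, diameter_px) {
  if (diameter_px <= 0) stop("diameter must be positive", call. = FALSE)
  structure(list(center_xy = as.numeric(center),
                 diameter_px = diameter_px,
                 mm_per_px = 1.5 / diameter_px),
            class = "optic_disc")
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf("optic disc: center (%.1f, %.1f), PD %.1f px, %.5f mm/px\n",
              x$center_xy[1L], x$center_xy[2L], x$diameter_px, x$mm_per_px))
  invisible(x)
}

#' Segment the optic disc and calibrate
#'
#' Full disc pipeline: locate (or accept a seed), trace the boundary in
#' polar coordinates, fit the minimum enclosing circle to the boundary
#' points, and derive the PD calibration. The fitted circle's center is
#' the final disc center.
#'
#' @inheritParams locate_disc
#' @inheritParams trace_boundary_polar
#' @param gray optional grayscale matrix for the boundary trace; computed
#'   from `image` when `NULL`.
#' @return `optic_disc` object with an additional `boundary` element.
#' @export
segment_disc <- function(image, roi = NULL, seed = NULL, gray = NULL,
                         n_angles = 360L, r_max = NULL, sigma = 2,
                         smooth_window = 9L) {
  ds <- locate_disc(image, roi = roi, seed = seed)
  if (is.null(gray))
    gray <- if (length(dim(image)) == 3L)
      to_grayscale(image, gray_coeffs("bt601")) else image
  bd <- trace_boundary_polar(gray, ds, n_angles = n_angles, r_max = r_max,
                             sigma = sigma, smooth_window = smooth_window)
  mec <- min_enclosing_circle(bd$points)
  disc <- calibrate_disc(mec$center, mec$diameter)
  disc$boundary <- bd
  disc
}
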