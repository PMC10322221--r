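## Deterministic synthetic phantoms with analytic ground truth: bars,
## arcs, rings, Y-junctions, X-crossings, Sierpinski carpets, bright
## discs, and composite fundus scenes (bright disc + dark vessels on a
## mid-intensity background inside a circular camera aperture).
##
## Masks are rasterized by pixel-center inclusion and are never noised;
## Gaussian noise (seeded) is applied to the rendered image only, so
## measurement tests isolate morphometry from segmentation error.

#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
.pixel_grid <- function(size) {
  h <- size[1L]; w <- if (length(size) > 1L) size[2L] else size[1L]
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w), h = h, w = w)
}

#' @noRd
.capsule_mask <- function(g, p1, p2, width) {
  vx <- p2[1L] - p1[1L]; vy <- p2[2L] - p1[2L]
  l2 <- vx^2 + vy^2
  t_ <- if (l2 == 0) 0 else pmin(pmax(((g$x - p1[1L]) * vx +
                                         (g$y - p1[2L]) * vy) / l2, 0), 1)
  dx <- g$x - (p1[1L] + t_ * vx); dy <- g$y - (p1[2L] + t_ * vy)
  sqrt(dx^2 + dy^2) <= width / 2
}

#' @noRd
.disk_mask <- function(g, center, radius) {
  sqrt((g$x - center[1L])^2 + (g$y - center[2L])^2) <= radius
}

#' @noRd
.annulus_mask <- function(g, center, radius, width,
                          theta0 = 0, theta1 = 2 * pi) {
  r <- sqrt((g$x - center[1L])^2 + (g$y - center[2L])^2)
  m <- abs(r - radius) <= width / 2
  if (theta1 - theta0 < 2 * pi - 1e-9) {
    th <- atan2(g$y - center[2L], g$x - center[1L]) %% (2 * pi)
    t0 <- theta0 %% (2 * pi); t1 <- theta1 %% (2 * pi)
    sector <- if (t0 <= t1) th >= t0 & th <= t1 else th >= t0 | th <= t1
    m <- m & sector
  }
  m
}

#' @noRd
.check_in_frame <- function(g, xs, ys, margin = 1) {
  if (any(xs < 1 + margin) || any(xs > g$w - margin) ||
      any(ys < 1 + margin) || any(ys > g$h - margin))
    stop("phantom geometry exceeds the frame", call. = FALSE)
}

#' @noRd
.render_fundus <- function(mask, size, disc = NULL, noise_sd = 0, seed = 1,
                           aperture_frac = 0.49,
                           bg = 140, vessel = 80, disc_val = 220,
                           outside = 5) {
  g <- .pixel_grid(size)
  img <- matrix(bg, g$h, g$w)
  if (!is.null(disc))
    img[.disk_mask(g, disc$center, disc$radius)] <- disc_val
  img[mask] <- vessel
  aperture <- .disk_mask(g, c((g$w + 1) / 2, (g$h + 1) / 2),
                         aperture_frac * min(g$h, g$w))
  img[!aperture] <- outside
  if (noise_sd > 0)
    img <- img + .with_seed(seed, matrix(rnorm(g$h * g$w, 0, noise_sd),
                                         g$h, g$w))
  img <- pmin(pmax(img, 0), 255)
  rgb <- array(0, dim = c(g$h, g$w, 3L))
  rgb[, , 1L] <- img
  rgb[, , 2L] <- img * 0.75
  rgb[, , 3L] <- img * 0.45
  rgb
}

#' Generate a phantom
#'
#' Deterministic synthetic test scene with analytic ground truth. Kinds:
#' \describe{
#'   \item{bar}{straight vessel of given `width`, `length`, `angle_deg`.}
#'   \item{arc}{annular sector of given `radius`, `width`, `span_deg`;
#'     midline curvature ground truth `1/radius`.}
#'   \item{ring}{full annulus (closed loop).}
#'   \item{y_junction}{main bar plus one branch at `angle_deg` from the
#'     main direction.}
#'   \item{x_crossing}{two bars crossing at the center.}
#'   \item{sierpinski}{Sierpinski carpet, `iterations` levels, unit cells
#'     of `cell_px` pixels; fractal dimension ground truth log 8/log 3.}
#'   \item{disc}{bright disc of given `radius` (no vessels).}
#'   \item{composite_fundus}{bright optic disc plus dark radial vessels
#'     (artery/vein pairs with optional side branches) inside a camera
#'     aperture; see [phantom_fundus()].}
#' }
#'
#' @param spec list with `kind` and kind-specific parameters (see above);
#'   common: `size` (frame side), `noise_sd` (image noise), `seed`.
#' @return list: `image` (`H x W x 3`, 0-255), `mask` (logical),
#'   `av_mask` (integer labels), `truth` (ground-truth list).
#' @export
generate_phantom <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  kind <- spec$kind
  a <- function(name, default) if (!is.null(spec[[name]])) spec[[name]]
  else default
  size <- a("size", 256L)
  noise_sd <- a("noise_sd", 0)
  seed <- a("seed", 1L)
  g <- .pixel_grid(size)
  ctr <- c(round(g$w / 2), round(g$h / 2))
  finish <- function(mask, truth, av = NULL, disc = NULL) {
    if (is.null(av)) av <- matrix(0L, g$h, g$w) + 3L * mask
    list(image = .render_fundus(mask, c(g$h, g$w), disc = disc,
                                noise_sd = noise_sd, seed = seed),
         mask = mask, av_mask = av, truth = truth)
  }
  if (kind == "bar") {
    width <- a("width", 11); len <- a("length", 200)
    ang <- a("angle_deg", 0) * pi / 180
    stopifnot(width >= 3)
    d <- c(cos(ang), -sin(ang))   # angle measured upward from +x
    p1 <- ctr - len / 2 * d; p2 <- ctr + len / 2 * d
    .check_in_frame(g, c(p1[1L], p2[1L]), c(p1[2L], p2[2L]), width)
    finish(.capsule_mask(g, p1, p2, width),
           list(true_width_px = width, true_angle_deg = a("angle_deg", 0),
                endpoints = rbind(p1, p2)))
  } else if (kind == "arc") {
    radius <- a("radius", 100); width <- a("width", 9)
    span <- a("span_deg", 180) * pi / 180
    stopifnot(width >= 3, radius > width)
    .check_in_frame(g, ctr[1L] + c(-1, 1) * (radius + width / 2),
                    ctr[2L] + c(-1, 1) * (radius + width / 2))
    m <- .annulus_mask(g, ctr, radius, width, theta0 = 0, theta1 = span)
    finish(m, list(true_curvature_per_px = 1 / radius,
                   true_width_px = width, radius_px = radius))
  } else if (kind == "ring") {
    radius <- a("radius", 80); width <- a("width", 9)
    stopifnot(radius > width)
    .check_in_frame(g, ctr[1L] + c(-1, 1) * (radius + width / 2),
                    ctr[2L] + c(-1, 1) * (radius + width / 2))
    finish(.annulus_mask(g, ctr, radius, width),
           list(true_curvature_per_px = 1 / radius, true_width_px = width))
  } else if (kind == "y_junction") {
    mw <- a("main_width", 11); bw <- a("branch_width", 7)
    ang <- a("angle_deg", 45) * pi / 180
    ml <- a("main_length", round(0.8 * min(g$h, g$w)))
    bl <- a("branch_length", round(0.3 * min(g$h, g$w)))
    p1 <- c(ctr[1L] - ml / 2, ctr[2L]); p2 <- c(ctr[1L] + ml / 2, ctr[2L])
    bdir <- c(cos(ang), -sin(ang))
    b2 <- ctr + bl * bdir
    .check_in_frame(g, c(p1[1L], p2[1L], b2[1L]), c(p1[2L], p2[2L], b2[2L]),
                    mw)
    m <- .capsule_mask(g, p1, p2, mw) | .capsule_mask(g, ctr, b2, bw)
    finish(m, list(true_angle_deg = a("angle_deg", 45),
                   true_width_px = mw, branch_width_px = bw,
                   branch_xy = ctr))
  } else if (kind == "x_crossing") {
    width <- a("width", 9)
    len <- a("length", round(0.7 * min(g$h, g$w)))
    d1 <- c(cos(pi / 4), -sin(pi / 4)); d2 <- c(cos(pi / 4), sin(pi / 4))
    m <- .capsule_mask(g, ctr - len / 2 * d1, ctr + len / 2 * d1, width) |
      .capsule_mask(g, ctr - len / 2 * d2, ctr + len / 2 * d2, width)
    finish(m, list(true_width_px = width, crossing_xy = ctr))
  } else if (kind == "sierpinski") {
    iters <- a("iterations", 5L); cell <- a("cell_px", 3L)
    side <- 3L^iters * cell
    gg <- .pixel_grid(side)
    cx <- (gg$x - 1L) %/% cell; cy <- (gg$y - 1L) %/% cell
    keep <- matrix(TRUE, side, side)
    for (lev in seq_len(iters)) {
      p <- 3L^(iters - lev)
      keep <- keep & !((cx %/% p) %% 3L == 1L & (cy %/% p) %% 3L == 1L)
    }
    list(image = .render_fundus(keep, side, noise_sd = noise_sd,
                                seed = seed, aperture_frac = 10),
         mask = keep, av_mask = matrix(3L * keep, side, side),
         truth = list(true_fd = log(8) / log(3),
                      filled_cells = 8^iters, cell_px = cell))
  } else if (kind == "disc") {
    radius <- a("radius", 60)
    center <- a("center", ctr)
    .check_in_frame(g, center[1L] + c(-1, 1) * radius,
                    center[2L] + c(-1, 1) * radius)
    m <- matrix(FALSE, g$h, g$w)
    finish(m, list(disc_center_xy = center, disc_diameter_px = 2 * radius),
           disc = list(center = center, radius = radius))
  } else if (kind == "composite_fundus") {
    do.call(phantom_fundus, spec[setdiff(names(spec), "kind")])
  } else stop("unknown phantom kind: ", kind, call. = FALSE)
}

#' Composite fundus phantom
#'
#' A synthetic optic-disc-centred fundus scene: bright disc at the frame
#' center, four radial main vessels (upper/lower artery and vein pairs)
#' with optional side branches at a designed angle, dark on a
#' mid-intensity background inside a circular camera aperture. The
#' artery/vein label mask codes arteries 1 and veins 2; arteries are
#' rendered thinner than veins (`artery_ratio`).
#'
#' @param size frame side in pixels.
#' @param disc_radius disc radius in pixels (PD = `2 * disc_radius`).
#' @param vein_width vein width in pixels; artery width is
#'   `artery_ratio * vein_width`.
#' @param artery_ratio arteriole-to-venule width ratio (default 0.7).
#' @param n_branches number of mains carrying one side branch (0-4).
#' @param branch_angle_deg designed branch angle in degrees.
#' @param vessel_r0,vessel_r1 radial start/end of the mains, in pixels
#'   from the disc center.
#' @param noise_sd Gaussian image noise sd (masks stay exact).
#' @param seed noise seed.
#' @return same structure as [generate_phantom()].
#' @export
phantom_fundus <- function(size = 640L, disc_radius = 50, vein_width = 13,
                           artery_ratio = 0.7, n_branches = 2L,
                           branch_angle_deg = 50,
                           vessel_r0 = 35, vessel_r1 = NULL,
                           noise_sd = 4, seed = 1L) {
  g <- .pixel_grid(size)
  ctr <- c(round(g$w / 2), round(g$h / 2))
  if (is.null(vessel_r1)) vessel_r1 <- round(0.46 * size)
  aw <- artery_ratio * vein_width
  mains <- list(
    list(theta = -60 * pi / 180, width = vein_width, label = 2L),   # up-right
    list(theta = -120 * pi / 180, width = aw, label = 1L),          # up-left
    list(theta = 120 * pi / 180, width = vein_width, label = 2L),   # down-left
    list(theta = 60 * pi / 180, width = aw, label = 1L))            # down-right
  mask <- matrix(FALSE, g$h, g$w)
  av <- matrix(0L, g$h, g$w)
  truth_vessels <- list()
  ba <- branch_angle_deg * pi / 180
  for (i in seq_along(mains)) {
    mv <- mains[[i]]
    d <- c(cos(mv$theta), sin(mv$theta))
    p1 <- ctr + vessel_r0 * d; p2 <- ctr + vessel_r1 * d
    .check_in_frame(g, c(p1[1L], p2[1L]), c(p1[2L], p2[2L]), mv$width)
    cm <- .capsule_mask(g, p1, p2, mv$width)
    mask <- mask | cm
    av[cm] <- mv$label
    branch <- NULL
    if (i <= n_branches) {
      bp <- ctr + 0.6 * (vessel_r0 + vessel_r1) * d
      ## rotate the main direction by the designed angle (away from disc)
      rot <- matrix(c(cos(ba), sin(ba), -sin(ba), cos(ba)), 2L)
      bd <- as.numeric(rot %*% d)
      bw <- max(3, 0.6 * mv$width)
      b2 <- bp + 0.35 * (vessel_r1 - vessel_r0) * bd
      .check_in_frame(g, c(bp[1L], b2[1L]), c(bp[2L], b2[2L]), bw)
      bm <- .capsule_mask(g, bp, b2, bw)
      mask <- mask | bm
      av[bm & av == 0L] <- mv$label
      branch <- list(from = bp, to = b2, width = bw,
                     angle_deg = branch_angle_deg)
    }
    truth_vessels[[i]] <- list(theta = mv$theta, width = mv$width,
                               label = mv$label, branch = branch)
  }
  aperture <- .disk_mask(g, c((g$w + 1) / 2, (g$h + 1) / 2),
                         0.49 * min(g$h, g$w))
  truth <- list(disc_center_xy = ctr, disc_diameter_px = 2 * disc_radius,
                vein_width_px = vein_width, artery_width_px = aw,
                branch_angle_deg = branch_angle_deg,
                n_branches = n_branches,
                true_density = sum(mask & aperture) / sum(aperture),
                vessels = truth_vessels)
  list(image = .render_fundus(mask, c(g$h, g$w),
                              disc = list(center = ctr, radius = disc_radius),
                              noise_sd = noise_sd, seed = seed),
       mask = mask, av_mask = av, truth = truth)
}

#' Generate a cohort of composite fundus phantoms
#'
#' `n` composite phantoms with systematically graded parameters: vein
#' width ramps from 8 to 16 px and the branch count from 0 to 4 across
#' the cohort (so measured mean diameter and vascular density increase
#' monotonically), with per-phantom noise seeds derived from `seed`.
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed fixing all randomness.
#' @param size frame side in pixels.
#' @return list with `phantoms` (list of [phantom_fundus()] results) and
#'   `manifest` (data.frame of ground-truth parameters per phantom).
#' @export
generate_cohort <- function(n, seed = 1L, size = 640L) {
  stopifnot(n >= 1)
  widths <- if (n == 1L) 12 else seq(8, 16, length.out = n)
  branches <- round(seq(0, 4, length.out = max(n, 2L)))[seq_len(n)]
  phantoms <- lapply(seq_len(n), function(i)
    phantom_fundus(size = size, vein_width = widths[i],
                   n_branches = branches[i],
                   noise_sd = 4, seed = seed * 1000L + i))
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- phantoms[[i]]$truth
    data.frame(id = i, vein_width_px = tr$vein_width_px,
               artery_width_px = tr$artery_width_px,
               n_branches = tr$n_branches,
               true_density = tr$true_density,
               disc_diameter_px = tr$disc_diameter_px)
  }))
  list(phantoms = phantoms, manifest = manifest)
}
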