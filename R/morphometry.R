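## Quantitative core: pointwise vessel diameter, circumradius-curvature
## tortuosity, box-counting fractal dimension, vascular density, main
## vessel selection and branching angle, AVR.

#' @noRd
.seg_path_index <- function(s, h) (s$path[, "x"] - 1L) * h + s$path[, "y"]

#' @noRd
.fit_tangent <- function(pts) {
  ## principal axis of the local path points (robust to vertical runs)
  ctr <- colMeans(pts)
  d <- sweep(pts, 2L, ctr)
  cv <- crossprod(d) / nrow(pts)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  v / sqrt(sum(v^2))
}

#' Vessel diameter at a centerline point
#'
#' Fits the local tangent by a least-squares line over `tangent_window`
#' path pixels on either side of the point, casts rays along the normal in
#' both directions until they exit the vessel mask, and returns the
#' Euclidean distance between the two boundary exit points.
#'
#' @param mask logical vessel mask.
#' @param path n x 2 (x, y) centerline path matrix.
#' @param idx index of the measurement point on the path.
#' @param tangent_window half-window in path pixels for the tangent fit.
#' @param mm_per_px optional calibration for the micrometre value.
#' @param max_ray maximum ray length in pixels (guards runaway rays).
#' @return list: `center`, `tangent`, `d_px`, `d_um` (`NA` without
#'   calibration), `boundary` (2 x 2 exit points). `d_px` is `NA` when a
#'   ray leaves the image before exiting the mask (unmeasurable).
#' @export
diameter_at <- function(mask, path, idx, tangent_window = 7L,
                        mm_per_px = NULL, max_ray = 100) {
  n <- nrow(path)
  stopifnot(idx >= 1L, idx <= n)
  i0 <- max(1L, idx - tangent_window)
  i1 <- min(n, idx + tangent_window)
  p <- as.numeric(path[idx, ])
  tangent <- .fit_tangent(path[i0:i1, , drop = FALSE])
  normal <- c(-tangent[2L], tangent[1L])
  h <- nrow(mask); w <- ncol(mask)
  march <- function(dir) {
    t_ <- 0
    repeat {
      t_ <- t_ + 0.25
      if (t_ > max_ray) return(NA_real_)
      q <- p + t_ * dir
      xi <- round(q[1L]); yi <- round(q[2L])
      if (xi < 1 || xi > w || yi < 1 || yi > h) return(NA_real_)
      if (!mask[yi, xi]) return(t_ - 0.125)  # midpoint of last in / first out
    }
  }
  t_pos <- march(normal)
  t_neg <- march(-normal)
  d_px <- if (is.na(t_pos) || is.na(t_neg)) NA_real_ else t_pos + t_neg
  list(center = p, tangent = tangent, d_px = d_px,
       d_um = if (!is.null(mm_per_px) && !is.na(d_px))
         d_px * mm_per_px * 1000 else NA_real_,
       boundary = rbind(p + t_pos * normal, p - t_neg * normal))
}

#' Sample diameters along the centerline graph
#'
#' One cross-section every `step` path pixels along every segment,
#' skipping points closer than `tangent_window` to a segment end (node),
#' where the tangent is ill-defined.
#'
#' @param mask logical vessel mask.
#' @param graph `centerline_graph`.
#' @param step sampling interval along the vessel direction in pixels
#'   (default 5).
#' @param tangent_window half-window for the tangent fit.
#' @param disc optional `optic_disc` for micrometre conversion.
#' @return data.frame: `x`, `y`, `d_px`, `d_um`, `segment`, `av_label`.
#' @export
sample_diameters <- function(mask, graph, step = 5L, tangent_window = 7L,
                             disc = NULL) {
  mmpp <- if (!is.null(disc)) disc$mm_per_px else NULL
  rows <- lapply(graph$segments, function(s) {
    n <- nrow(s$path)
    if (n < 2L * tangent_window + 1L) return(NULL)
    at <- seq(tangent_window + 1L, n - tangent_window, by = step)
    if (!length(at)) return(NULL)
    cs <- lapply(at, function(i)
      diameter_at(mask, s$path, i, tangent_window, mmpp))
    data.frame(x = s$path[at, "x"], y = s$path[at, "y"],
               d_px = vapply(cs, `[[`, 0, "d_px"),
               d_um = vapply(cs, `[[`, 0, "d_um"),
               segment = s$id, av_label = s$av_label)
  })
  out <- do.call(rbind, c(rows, list(.empty_sections())))
  out[!is.na(out$d_px), , drop = FALSE]
}

#' @noRd
.empty_sections <- function() {
  data.frame(x = numeric(), y = numeric(), d_px = numeric(),
             d_um = numeric(), segment = integer(), av_label = character())
}

#' Average vessel diameter
#'
#' Arithmetic mean of the cross-section diameters, optionally restricted
#' to one artery/vein label.
#'
#' @param sections data.frame from [sample_diameters()].
#' @param label `"all"`, `"artery"` or `"vein"`.
#' @param unit `"um"` (requires calibration) or `"px"`.
#' @return mean diameter, or `NA` if no section matches.
#' @export
average_diameter <- function(sections, label = c("all", "artery", "vein"),
                             unit = c("um", "px")) {
  label <- match.arg(label)
  unit <- match.arg(unit)
  if (label != "all") sections <- sections[sections$av_label == label, ]
  v <- if (unit == "um") sections$d_um else sections$d_px
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else mean(v)
}

#' Arteriole-to-venule ratio
#'
#' @param artery_mean,vein_mean mean arteriolar and venular diameters in
#'   the same unit; `vein_mean` must be positive.
#' @return `artery_mean / vein_mean` (`NA` if either input is `NA`).
#' @export
avr <- function(artery_mean, vein_mean) {
  if (is.na(artery_mean) || is.na(vein_mean)) return(NA_real_)
  if (vein_mean <= 0) stop("vein mean diameter must be positive",
                           call. = FALSE)
  artery_mean / vein_mean
}

#' Curvature at a centerline point
#'
#' Three-point circumradius curvature: points B and C are taken on either
#' side of point A at equal arc distance `arc_half` along the centerline;
#' with `a = |BC|` and the interior angle at A, the circumradius of
#' triangle ABC is `R_A = a / (2 sin A)` and the curvature is
#' `C_A = 1 / R_A`. Collinear triples (sin A below 1e-6) give curvature 0.
#'
#' @param path n x 2 (x, y) path matrix.
#' @param idx index of point A; must be at least `arc_half` of arc length
#'   from both segment ends.
#' @param arc_half arc distance to B and C in pixels (default 25,
#'   matching the 25-px end exclusion).
#' @param s optional precomputed cumulative arc length along the path.
#' @return list: `point`, `B`, `C`, `chord_a`, `angle_A`, `R_A`,
#'   `curvature` (1/px), or `NULL` when the arc condition fails.
#' @export
curvature_at <- function(path, idx, arc_half = 25, s = NULL) {
  n <- nrow(path)
  if (is.null(s))
    s <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  if (s[idx] - s[1L] < arc_half || s[n] - s[idx] < arc_half) return(NULL)
  bi <- findInterval(s[idx] - arc_half, s)              # arc >= arc_half
  ci <- min(n, findInterval(s[idx] + arc_half - 1e-9, s) + 1L)
  A <- as.numeric(path[idx, ]); B <- as.numeric(path[bi, ])
  C <- as.numeric(path[ci, ])
  ab <- B - A; ac <- C - A
  la <- sqrt(sum(ab^2)); lc <- sqrt(sum(ac^2))
  if (la < 1e-9 || lc < 1e-9) return(NULL)
  cosA <- max(-1, min(1, sum(ab * ac) / (la * lc)))
  sinA <- sqrt(1 - cosA^2)
  a <- sqrt(sum((C - B)^2))
  curv <- if (sinA < 1e-6) 0 else 2 * sinA / a      # 1/R_A, R_A = a/(2 sin A)
  list(point = A, B = B, C = C, chord_a = a,
       angle_A = acos(cosA), R_A = if (curv == 0) Inf else 1 / curv,
       curvature = curv)
}

#' Sample curvatures along the centerline graph
#'
#' One curvature sample every `step` path pixels on every segment, with
#' the first and last `arc_half` pixels of each segment excluded (the
#' three-point construction is undefined there).
#'
#' @param graph `centerline_graph`.
#' @param step sampling interval in path pixels.
#' @param arc_half see [curvature_at()].
#' @return data.frame: `x`, `y`, `curvature` (1/px), `segment`,
#'   `av_label`.
#' @export
sample_curvatures <- function(graph, step = 5L, arc_half = 25) {
  rows <- lapply(graph$segments, function(seg) {
    n <- nrow(seg$path)
    if (n < 3L) return(NULL)
    s <- c(0, cumsum(sqrt(rowSums(diff(seg$path)^2))))
    ok <- which(s - s[1L] >= arc_half & s[n] - s >= arc_half)
    if (!length(ok)) return(NULL)
    at <- ok[seq(1L, length(ok), by = step)]
    cs <- lapply(at, function(i) curvature_at(seg$path, i, arc_half, s))
    keep <- !vapply(cs, is.null, logical(1L))
    if (!any(keep)) return(NULL)
    at <- at[keep]; cs <- cs[keep]
    data.frame(x = seg$path[at, "x"], y = seg$path[at, "y"],
               curvature = vapply(cs, `[[`, 0, "curvature"),
               segment = seg$id, av_label = seg$av_label)
  })
  do.call(rbind, c(rows, list(data.frame(x = numeric(), y = numeric(),
                                         curvature = numeric(),
                                         segment = integer(),
                                         av_label = character()))))
}

#' Vascular tortuosity
#'
#' Mean pointwise curvature over the centerline samples. The pooled mode
#' averages all samples together (default); `per_vessel_mean` averages
#' per-segment means. Values are in 1/px; reporting layers conventionally
#' multiply by 1000.
#'
#' @param curvatures data.frame from [sample_curvatures()].
#' @param pooling `"pooled"` or `"per_vessel_mean"`.
#' @return mean curvature (1/px), `NA` when there are no samples.
#' @export
tortuosity <- function(curvatures, pooling = c("pooled", "per_vessel_mean")) {
  pooling <- match.arg(pooling)
  if (is.null(curvatures) || nrow(curvatures) == 0L) return(NA_real_)
  if (pooling == "pooled") mean(curvatures$curvature)
  else mean(tapply(curvatures$curvature, curvatures$segment, mean))
}

#' Box-counting fractal dimension
#'
#' Covers the mask with square grids of edge length `epsilon`, counts the
#' boxes intersecting the vasculature, and fits `log N` against
#' `log(1/epsilon)` by ordinary least squares; the slope is the fractal
#' dimension. The default schedule is powers of 2 from 4 px to
#' `min(H, W)/4`. At each scale the count is the minimum over a small set
#' of grid offsets (quarter-box shifts in each axis), the minimal-covering
#' variant of box counting; a single anchored grid quantizes coarse
#' scales enough to make the slope drift under image translation.
#'
#' @param mask logical matrix, non-empty.
#' @param epsilons optional explicit box edge lengths (>= 2 values).
#' @param n_offsets number of grid offsets per axis (1 = a single grid
#'   anchored at the origin).
#' @return list of class `boxcount`: `fd` (slope), `epsilons`, `counts`.
#' @export
fractal_dimension <- function(mask, epsilons = NULL, n_offsets = 4L) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  if (is.null(epsilons)) {
    emax <- min(h, w) / 4
    epsilons <- 2^(2:30)
    epsilons <- epsilons[epsilons <= emax]
    if (length(epsilons) < 3L) epsilons <- c(2, 4, 8)
  }
  stopifnot(length(epsilons) >= 2L, n_offsets >= 1L)
  idx <- which(mask)
  ys <- (idx - 1L) %% h; xs <- (idx - 1L) %/% h   # 0-based pixel coords
  counts <- vapply(epsilons, function(e) {
    offs <- unique(round(seq(0, e, length.out = n_offsets + 1L)[seq_len(n_offsets)]))
    min(vapply(offs, function(ox) min(vapply(offs, function(oy) {
      bx <- (xs + ox) %/% e; by <- (ys + oy) %/% e
      length(unique(bx * (h %/% e + 3L) + by))
    }, numeric(1L))), numeric(1L)))
  }, numeric(1L))
  fit <- lm(log(counts) ~ log(1 / epsilons))
  structure(list(fd = unname(coef(fit)[2L]), epsilons = epsilons,
                 counts = counts),
            class = "boxcount")
}

#' @export
print.boxcount <- function(x, ...) {
  cat(sprintf("box-counting fractal dimension: %.4f (%d scales, eps %s)\n",
              x$fd, length(x$epsilons),
              paste(x$epsilons, collapse = ", ")))
  invisible(x)
}

#' Vascular density
#'
#' Ratio of the vessel area to the fundus (ROI) area,
#' `rho = S' / S`, as an exact pixel-count ratio.
#'
#' @param mask logical vessel mask.
#' @param roi logical fundus ROI mask (non-empty); the vessel mask is
#'   intersected with it.
#' @return list: `S_prime` (vessel px), `S` (ROI px), `rho`.
#' @export
vascular_density <- function(mask, roi) {
  if (!all(dim(mask) == dim(roi))) stop("shape mismatch", call. = FALSE)
  S <- sum(roi)
  if (S == 0L) stop("empty ROI", call. = FALSE)
  Sp <- sum(mask & roi)
  list(S_prime = Sp, S = S, rho = Sp / S)
}

#' @noRd
.seg_mean_diam <- function(sections) {
  if (nrow(sections) == 0L) return(numeric())
  tapply(sections$d_px, sections$segment, mean)
}

#' @noRd
.border_dist_pd <- function(x, y, disc) {
  (sqrt((x - disc$center_xy[1L])^2 + (y - disc$center_xy[2L])^2) -
     disc$diameter_px / 2) / disc$diameter_px
}

#' Select the upper and lower main vessels
#'
#' Within 2 PD of the optic disc border, the retina is split into upper
#' and lower halves at the disc center, and in each half the segment
#' chain with the largest mean diameter is taken as the main vessel. The
#' chain starts at the eligible segment of largest mean diameter and is
#' extended through branch nodes, at each node continuing into the
#' incident eligible segment with the largest mean diameter. Ties go to
#' the lower segment id.
#'
#' @param graph `centerline_graph`.
#' @param sections data.frame from [sample_diameters()].
#' @param disc calibrated `optic_disc`.
#' @param max_dist_pd eligibility distance from the disc border in PD
#'   units (default 2).
#' @return list with `upper` and `lower`, each a vector of segment ids
#'   (empty when the half has no eligible segment).
#' @export
select_main_vessels <- function(graph, sections, disc, max_dist_pd = 2) {
  md <- .seg_mean_diam(sections)
  if (!length(md)) return(list(upper = integer(), lower = integer()))
  seg_ids <- as.integer(names(md))
  cent <- t(vapply(graph$segments[seg_ids], function(s)
    colMeans(s$path), numeric(2L)))
  eligible <- .border_dist_pd(cent[, 1L], cent[, 2L], disc) <= max_dist_pd
  upper_half <- cent[, 2L] < disc$center_xy[2L]
  pick_chain <- function(in_half) {
    ids <- seg_ids[eligible & in_half]
    if (!length(ids)) return(integer())
    start <- ids[which.max(md[as.character(ids)])]
    chain <- start
    for (end_node in graph$segments[[start]]$nodes) {
      cur_seg <- start
      node <- end_node
      while (!is.na(node) && graph$nodes$kind[node] == "branch") {
        incident <- Filter(function(s)
          s$id != cur_seg && !(s$id %in% chain) && node %in% s$nodes &&
            s$id %in% ids,
          graph$segments)
        if (!length(incident)) break
        inc_ids <- vapply(incident, `[[`, 0L, "id")
        nxt <- inc_ids[which.max(md[as.character(inc_ids)])]
        chain <- c(chain, nxt)
        ends <- graph$segments[[nxt]]$nodes
        node <- if (identical(ends[1L], node)) ends[2L] else ends[1L]
        cur_seg <- nxt
      }
    }
    sort(chain)
  }
  list(upper = pick_chain(upper_half), lower = pick_chain(!upper_half))
}

#' @noRd
.arm_direction <- function(path, from_end, offset, skip = offset) {
  ## least-squares line over the path pixels at arc distance
  ## [skip, skip + offset] from the given end, oriented away from it.
  ## The first `skip` pixels are excluded because thinning distorts the
  ## centerline inside the junction plateau. NULL when the arm is too
  ## short.
  n <- nrow(path)
  pts <- if (from_end == 1L) path else path[n:1L, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  sel <- which(s >= skip & s <= skip + offset)
  if (length(sel) < 2L) return(NULL)
  v <- .fit_tangent(pts[sel, , drop = FALSE])
  far <- as.numeric(pts[max(sel), ]) - as.numeric(pts[min(sel), ])
  if (sum(v * far) < 0) v <- -v
  v
}

#' Branching angles along the main vessels
#'
#' For every branch node on a main vessel within `max_dist_pd` PD of the
#' disc border: a line is fitted to the main-vessel centerline over the 10
#' path pixels downstream of the node (downstream = increasing distance
#' from the disc center), a second line to the branch centerline over its
#' first 10 pixels, and the angle between the two fitted lines is the
#' branching angle. Branch arms shorter than `offset` are skipped.
#'
#' @param graph `centerline_graph`.
#' @param mains result of [select_main_vessels()].
#' @param disc calibrated `optic_disc`.
#' @param offset line-fit length in path pixels (default 10).
#' @param max_dist_pd node eligibility distance from the disc border (PD).
#' @return list: `angles` data.frame (`node`, `x`, `y`, `angle_deg`,
#'   `main_segment`, `branch_segment`) and `mean_deg` (`NA` when empty).
#' @export
branching_angles <- function(graph, mains, disc, offset = 10L,
                             max_dist_pd = 2) {
  main_ids <- unique(c(mains$upper, mains$lower))
  empty <- data.frame(node = integer(), x = numeric(), y = numeric(),
                      angle_deg = numeric(), main_segment = integer(),
                      branch_segment = integer())
  if (!length(main_ids)) return(list(angles = empty, mean_deg = NA_real_))
  out <- list()
  dist_to_disc <- function(p) sqrt(sum((p - disc$center_xy)^2))
  for (nid in graph$nodes$id[graph$nodes$kind == "branch"]) {
    node_xy <- c(graph$nodes$x[nid], graph$nodes$y[nid])
    if (.border_dist_pd(node_xy[1L], node_xy[2L], disc) > max_dist_pd) next
    incident <- Filter(function(s) nid %in% s$nodes, graph$segments)
    inc_ids <- vapply(incident, `[[`, 0L, "id")
    on_main <- inc_ids %in% main_ids
    if (!any(on_main) || all(on_main)) next
    ## main direction: the incident main segment whose far end is farther
    ## from the disc center (downstream)
    main_segs <- incident[on_main]
    far_d <- vapply(main_segs, function(s) {
      end <- if (identical(s$nodes[1L], nid)) nrow(s$path) else 1L
      dist_to_disc(as.numeric(s$path[end, ]))
    }, numeric(1L))
    ms <- main_segs[[which.max(far_d)]]
    from_end <- if (identical(ms$nodes[1L], nid)) 1L else 2L
    u_main <- .arm_direction(ms$path, from_end, offset)
    if (is.null(u_main)) next
    for (bs in incident[!on_main]) {
      b_end <- if (identical(bs$nodes[1L], nid)) 1L else 2L
      u_br <- .arm_direction(bs$path, b_end, offset)
      if (is.null(u_br)) next   # arm too short for the line fit
      ang <- acos(max(-1, min(1, sum(u_main * u_br)))) * 180 / pi
      out[[length(out) + 1L]] <- data.frame(
        node = nid, x = node_xy[1L], y = node_xy[2L], angle_deg = ang,
        main_segment = ms$id, branch_segment = bs$id)
    }
  }
  angles <- if (length(out)) do.call(rbind, out) else empty
  list(angles = angles,
       mean_deg = if (nrow(angles)) mean(angles$angle_deg) else NA_real_)
}
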