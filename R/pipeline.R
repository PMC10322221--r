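## Pipeline orchestration and reporting: configuration, the analyze()
## entry point (preprocess -> segment/ingest -> disc -> skeleton ->
## measure -> zones), mask evaluation, JSON/CSV serialization.

#' Analysis configuration
#'
#' All tunable parameters of the pipeline in one flat list; round-trips
#' losslessly through [write_config()] / [read_config()].
#'
#' @param preprocess [preprocess_config()].
#' @param min_elongation,max_width_px,min_area_px vessel preselection
#'   rules, see [preselect_vessels()].
#' @param eval_full_frame evaluate segmentation over the full frame
#'   instead of ROI pixels only.
#' @param n_angles,r_max_frac disc boundary trace: angular samples and
#'   maximum radius as a fraction of the frame side.
#' @param step diameter/curvature sampling interval along the centerline
#'   in pixels (default 5).
#' @param tangent_window tangent-fit half window in path pixels.
#' @param arc_half curvature arc half-length in path pixels (default 25).
#' @param prune_px spur-pruning threshold in pixels.
#' @param branch_offset branch-angle line-fit length in path pixels.
#' @param main_dist_pd main-vessel/branch-node eligibility distance from
#'   the disc border in PD units.
#' @param tortuosity_scale reporting scale for tortuosity (default 1000,
#'   the conventional table scaling).
#' @param tortuosity_pooling `"pooled"` or `"per_vessel_mean"`.
#' @param curvature_unit `"per_px"` or `"per_mm"` (converted via the disc
#'   calibration).
#' @param exclude_disc_interior drop samples closer than 0.5 PD to the
#'   disc border from the global means.
#' @param zones [zone_spec()].
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(preprocess = preprocess_config(),
                            min_elongation = 3, max_width_px = 40,
                            min_area_px = 50, eval_full_frame = FALSE,
                            n_angles = 360L, r_max_frac = 0.4,
                            step = 5L, tangent_window = 7L, arc_half = 25,
                            prune_px = 10, branch_offset = 10L,
                            main_dist_pd = 2, tortuosity_scale = 1000,
                            tortuosity_pooling = "pooled",
                            curvature_unit = c("per_px", "per_mm"),
                            exclude_disc_interior = FALSE,
                            zones = zone_spec()) {
  structure(list(preprocess = preprocess, min_elongation = min_elongation,
                 max_width_px = max_width_px, min_area_px = min_area_px,
                 eval_full_frame = eval_full_frame, n_angles = n_angles,
                 r_max_frac = r_max_frac, step = step,
                 tangent_window = tangent_window, arc_half = arc_half,
                 prune_px = prune_px, branch_offset = branch_offset,
                 main_dist_pd = main_dist_pd,
                 tortuosity_scale = tortuosity_scale,
                 tortuosity_pooling = tortuosity_pooling,
                 curvature_unit = match.arg(curvature_unit),
                 exclude_disc_interior = exclude_disc_interior,
                 zones = zones),
            class = "analysis_config")
}

#' Analyze one fundus image
#'
#' Runs the full pipeline and returns the metric bundle. A vessel mask
#' may be supplied (ingestion mode); without one, the classical stages
#' (Otsu dark region + morphology preselection) produce a candidate mask
#' with a warning. Disc-dependent metrics (micrometre diameters, AVR,
#' branching angle, zones) are `NA` when no disc can be derived.
#' Non-fatal stage failures are recorded in `warnings` with the affected
#' metrics set missing.
#'
#' @param image RGB array, grayscale matrix, or file path; `NULL` for
#'   mask-only invocation.
#' @param mask logical vessel mask or file path; `NULL` triggers
#'   classical segmentation.
#' @param av_mask optional artery/vein label mask or file path.
#' @param disc_seed optional `c(x, y)` disc seed.
#' @param disc optional precomputed `optic_disc` (skips disc
#'   segmentation; useful for mask-only runs with a known PD).
#' @param image_id identifier carried into the output.
#' @param config [analysis_config()].
#' @return list of class `metrics_bundle`: `image_id`, `disc`, `global`
#'   (named metrics), `zones` (per-zone data.frame), `counts`,
#'   `warnings`.
#' @export
analyze <- function(image = NULL, mask = NULL, av_mask = NULL,
                    disc_seed = NULL, disc = NULL, image_id = "image",
                    config = analysis_config()) {
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)
  if (is.character(image)) image <- read_image(image)
  if (is.character(mask)) mask <- read_mask(mask)
  if (is.character(av_mask)) av_mask <- read_av_mask(av_mask)
  if (is.null(image) && is.null(mask))
    stop("need an image or a vessel mask", call. = FALSE)
  roi <- NULL
  gray <- NULL
  if (!is.null(image)) {
    if (!is.null(mask) && !all(dim(mask) == dim(image)[1:2]))
      stop("mask dimensions do not match the image", call. = FALSE)
    pp <- tryCatch(preprocess_keep_size(image, config$preprocess),
                   error = function(e) {
                     note(paste("preprocessing failed:",
                                conditionMessage(e)))
                     NULL
                   })
    if (!is.null(pp)) {
      roi <- pp$roi; gray <- pp$gray
    }
  }
  if (is.null(mask)) {
    note("no vessel mask supplied: classical segmentation stages used")
    mask <- tryCatch({
      thr <- otsu_threshold(pp$gray, roi)
      dark <- pp$gray < thr & roi
      preselect_vessels(dark, roi, config$min_elongation,
                        config$max_width_px, config$min_area_px)
    }, error = function(e) {
      note(paste("classical segmentation failed:", conditionMessage(e)))
      NULL
    })
    if (is.null(mask)) stop("no vessel mask available", call. = FALSE)
  }
  if (!is.null(av_mask) && !all(dim(av_mask) == dim(mask)))
    stop("av_mask dimensions do not match", call. = FALSE)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  ## optic disc
  if (is.null(disc) && !is.null(image)) {
    disc <- tryCatch(
      segment_disc(image, roi = roi, seed = disc_seed, gray = gray,
                   n_angles = config$n_angles,
                   r_max = config$r_max_frac * min(dim(mask))),
      error = function(e) {
        note(paste("disc segmentation failed:", conditionMessage(e)))
        NULL
      })
  }
  ## centerline graph + samples
  graph <- centerline_graph(mask, prune_px = config$prune_px,
                            av_mask = av_mask)
  sections <- sample_diameters(mask, graph, step = config$step,
                               tangent_window = config$tangent_window,
                               disc = disc)
  curvatures <- sample_curvatures(graph, step = config$step,
                                  arc_half = config$arc_half)
  gsec <- sections
  gcur <- curvatures
  if (config$exclude_disc_interior && !is.null(disc)) {
    keep_s <- .border_dist_pd(gsec$x, gsec$y, disc) >= 0.5
    keep_c <- .border_dist_pd(gcur$x, gcur$y, disc) >= 0.5
    gsec <- gsec[keep_s, , drop = FALSE]
    gcur <- gcur[keep_c, , drop = FALSE]
  }
  dens <- vascular_density(mask, roi)
  fd <- tryCatch(fractal_dimension(mask)$fd, error = function(e) {
    note(paste("fractal dimension failed:", conditionMessage(e)))
    NA_real_
  })
  tort <- tortuosity(gcur, config$tortuosity_pooling)
  if (config$curvature_unit == "per_mm" && !is.null(disc) && !is.na(tort))
    tort <- tort / disc$mm_per_px
  d_all <- average_diameter(gsec, "all")
  d_art <- average_diameter(gsec, "artery")
  d_ven <- average_diameter(gsec, "vein")
  av_ratio <- if (is.na(d_art) || is.na(d_ven) || d_ven <= 0) NA_real_
  else d_art / d_ven
  angle_mean <- NA_real_
  zones <- NULL
  if (!is.null(disc)) {
    mains <- select_main_vessels(graph, sections, disc,
                                 config$main_dist_pd)
    ba <- branching_angles(graph, mains, disc,
                           offset = config$branch_offset,
                           max_dist_pd = config$main_dist_pd)
    angle_mean <- ba$mean_deg
    zones <- aggregate_zones(sections, curvatures, disc, config$zones)
  } else {
    note("disc unavailable: micrometre, AVR, branch-angle and zonal metrics missing")
  }
  structure(list(
    image_id = image_id,
    disc = if (!is.null(disc))
      list(center_xy = disc$center_xy, diameter_px = disc$diameter_px,
           mm_per_px = disc$mm_per_px) else NULL,
    global = c(diameter_um = d_all, diameter_artery_um = d_art,
               diameter_vein_um = d_ven, avr = av_ratio,
               diameter_px = average_diameter(gsec, "all", unit = "px"),
               fractal_dimension = fd,
               branching_angle_deg = angle_mean,
               tortuosity = if (is.na(tort)) NA_real_
               else tort * config$tortuosity_scale,
               density = dens$rho),
    zones = zones,
    counts = c(n_sections = nrow(gsec), n_curvatures = nrow(gcur),
               n_segments = length(graph$segments),
               n_branch_nodes = sum(graph$nodes$kind == "branch")),
    warnings = warnings), class = "metrics_bundle")
}

#' @noRd
preprocess_keep_size <- function(image, cfg) {
  cfg$target_size <- NULL   # analysis runs at native resolution so that
  preprocess(image, cfg)    # supplied masks stay aligned
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat("metrics bundle:", x$image_id, "\n")
  print(round(x$global, 4))
  if (!is.null(x$zones)) {
    cat("zones:\n")
    print(x$zones, digits = 4)
  }
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, "\n"))
  invisible(x)
}

#' Flatten a metrics bundle to one CSV row
#'
#' Stable, documented column order: `image_id`, disc fields, global
#' metrics, per-zone metrics suffixed `_C1`..`_C4`, sample counts.
#'
#' @param x `metrics_bundle`.
#' @param ... unused.
#' @return one-row data.frame.
#' @export
as.data.frame.metrics_bundle <- function(x, ...) {
  row <- data.frame(image_id = x$image_id,
                    disc_x = if (!is.null(x$disc)) x$disc$center_xy[1L]
                    else NA_real_,
                    disc_y = if (!is.null(x$disc)) x$disc$center_xy[2L]
                    else NA_real_,
                    disc_diameter_px = if (!is.null(x$disc))
                      x$disc$diameter_px else NA_real_,
                    mm_per_px = if (!is.null(x$disc)) x$disc$mm_per_px
                    else NA_real_)
  row <- cbind(row, as.data.frame(as.list(x$global)))
  if (!is.null(x$zones)) {
    for (i in seq_len(nrow(x$zones))) {
      z <- x$zones[i, ]
      zn <- z$zone
      zrow <- data.frame(z$diameter_um, z$diameter_artery_um,
                         z$diameter_vein_um, z$avr, z$tortuosity,
                         z$n_diameter, z$n_curvature)
      names(zrow) <- paste0(c("diameter_um_", "diameter_artery_um_",
                              "diameter_vein_um_", "avr_", "tortuosity_",
                              "n_diameter_", "n_curvature_"), zn)
      row <- cbind(row, zrow)
    }
  }
  cbind(row, as.data.frame(as.list(x$counts)))
}

#' Serialize a metrics bundle to JSON
#'
#' @param x `metrics_bundle`.
#' @param path output path; `NULL` returns the JSON string.
#' @return the path (or JSON string), invisibly.
#' @export
write_metrics_json <- function(x, path = NULL) {
  obj <- list(image_id = x$image_id, disc = x$disc,
              global = as.list(x$global),
              zones = x$zones, counts = as.list(x$counts),
              warnings = x$warnings)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Evaluate segmentation masks (file- or matrix-level)
#'
#' Pixelwise segmentation scores for one pair or a list of pairs; with
#' several pairs, `"pooled"` accumulates one confusion matrix over all
#' images and `"per_image"` averages per-image scores.
#'
#' @param pred,truth masks or file paths, or lists thereof.
#' @param roi optional ROI mask(s) or path(s).
#' @param mode `"pooled"` (default) or `"per_image"`.
#' @return list with `scores` and (pooled mode) `counts`.
#' @export
evaluate_masks <- function(pred, truth, roi = NULL,
                           mode = c("pooled", "per_image")) {
  mode <- match.arg(mode)
  as_list <- function(x) if (is.list(x) && !is.data.frame(x)) x else list(x)
  load1 <- function(x) if (is.character(x)) read_mask(x) else x
  preds <- lapply(as_list(pred), load1)
  truths <- lapply(as_list(truth), load1)
  rois <- if (is.null(roi)) vector("list", length(preds))
  else lapply(as_list(roi), load1)
  stopifnot(length(preds) == length(truths))
  counts <- mapply(function(p, t_, r) confusion_counts(p, t_, r),
                   preds, truths, rois, SIMPLIFY = FALSE)
  if (mode == "pooled") {
    total <- Reduce(`+`, counts)
    list(mode = mode, counts = total, scores = seg_scores(total))
  } else {
    per <- t(vapply(counts, seg_scores, numeric(5L)))
    list(mode = mode, scores = colMeans(per, na.rm = TRUE),
         per_image = per)
  }
}

#' Write a flat key=value config file
#'
#' @param config [analysis_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  flat <- .flatten_config(config)
  writeLines(paste0(names(flat), " = ", vapply(flat, function(v)
    paste(format(v, digits = 17), collapse = ","), character(1L))), path)
  invisible(path)
}

#' Read a flat key=value config file
#'
#' @param path file written by [write_config()].
#' @return `analysis_config` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  flat <- stats::setNames(as.list(vals), keys)
  .unflatten_config(flat)
}

#' @noRd
.flatten_config <- function(cfg) {
  pp <- cfg$preprocess
  c(list(
    "preprocess.roi_threshold_fraction" = pp$roi_threshold_fraction,
    "preprocess.median_kernel" = pp$median_kernel,
    "preprocess.clahe_clip" = pp$clahe_clip,
    "preprocess.clahe_tiles" = pp$clahe_tiles,
    "preprocess.gray_coeffs" = pp$gray_coeffs,
    "preprocess.mean_mode" = pp$mean_mode,
    "preprocess.opening_radius" = pp$opening_radius),
    cfg[c("min_elongation", "max_width_px", "min_area_px", "n_angles",
          "r_max_frac", "step", "tangent_window", "arc_half", "prune_px",
          "branch_offset", "main_dist_pd", "tortuosity_scale",
          "tortuosity_pooling", "curvature_unit")],
    list("zones.name" = cfg$zones$name, "zones.inner" = cfg$zones$inner,
         "zones.outer" = cfg$zones$outer))
}

#' @noRd
.unflatten_config <- function(flat) {
  num <- function(k, d) if (is.null(flat[[k]])) d
  else as.numeric(strsplit(flat[[k]], ",")[[1L]])
  chr <- function(k, d) if (is.null(flat[[k]])) d
  else strsplit(flat[[k]], ",")[[1L]]
  analysis_config(
    preprocess = preprocess_config(
      roi_threshold_fraction = num("preprocess.roi_threshold_fraction", 1 / 3),
      median_kernel = num("preprocess.median_kernel", 3),
      clahe_clip = num("preprocess.clahe_clip", 2),
      clahe_tiles = num("preprocess.clahe_tiles", c(8, 8)),
      gray_coeffs = num("preprocess.gray_coeffs", gray_coeffs()),
      mean_mode = chr("preprocess.mean_mode", "additive"),
      opening_radius = num("preprocess.opening_radius", 5)),
    min_elongation = num("min_elongation", 3),
    max_width_px = num("max_width_px", 40),
    min_area_px = num("min_area_px", 50),
    n_angles = num("n_angles", 360),
    r_max_frac = num("r_max_frac", 0.4),
    step = num("step", 5),
    tangent_window = num("tangent_window", 7),
    arc_half = num("arc_half", 25),
    prune_px = num("prune_px", 10),
    branch_offset = num("branch_offset", 10),
    main_dist_pd = num("main_dist_pd", 2),
    tortuosity_scale = num("tortuosity_scale", 1000),
    tortuosity_pooling = chr("tortuosity_pooling", "pooled"),
    curvature_unit = chr("curvature_unit", "per_px"),
    zones = zone_spec(chr("zones.name", c("C1", "C2", "C3", "C4")),
                      num("zones.inner", c(0.5, 1, 1.5, 2)),
                      num("zones.outer", c(1, 1.5, 2, 2.5))))
}
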