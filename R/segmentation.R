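## Classical vessel-candidate extraction (Otsu dark region + brightness/
## morphology preselection) and pixelwise segmentation evaluation metrics.

#' Otsu threshold over ROI pixels
#'
#' Finds the intensity threshold maximizing the between-class variance of
#' the (rounded, 0-255) histogram of the pixels inside the ROI. The dark
#' region is `{pixel < threshold}`.
#'
#' @param gray grayscale matrix (0-255).
#' @param roi optional logical mask restricting the histogram; `NULL` uses
#'   the full frame.
#' @return numeric threshold in (0, 255].
#' @export
otsu_threshold <- function(gray, roi = NULL) {
  vals <- if (is.null(roi)) gray else gray[roi]
  if (length(vals) == 0L) stop("ROI is empty", call. = FALSE)
  v <- pmin(pmax(as.integer(round(vals)), 0L), 255L)
  if (min(v) == max(v))
    stop("no threshold: image is constant over the ROI", call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  # class 0 = {v < t} for candidate thresholds t = 1..255
  w0 <- cumsum(p)[1:255]
  mu0 <- cumsum(p * levels)[1:255]
  mu_t <- sum(p * levels)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * w1[valid])
  best <- which(sigma_b == max(sigma_b))
  mean(best)  # threshold t: dark region = {pixel < t}; ties -> midpoint
}

#' Vessel-candidate preselection by brightness and morphology
#'
#' Filters the connected components of the Otsu dark region, retaining
#' those that look like vessels: elongated (major/minor second-moment axis
#' ratio above `min_elongation`), thin (maximum inscribed width at most
#' `max_width_px`), and not tiny (area at least `min_area_px`).
#'
#' @param dark logical matrix of dark-region pixels.
#' @param roi optional ROI mask; components are clipped to it first.
#' @param min_elongation minimum major/minor axis ratio (default 3).
#' @param max_width_px maximum component width in pixels (default 40 at a
#'   1024-px working size).
#' @param min_area_px minimum component area in pixels (default 50).
#' @return logical vessel mask (possibly empty).
#' @export
preselect_vessels <- function(dark, roi = NULL, min_elongation = 3,
                              max_width_px = 40, min_area_px = 50) {
  if (!is.null(roi)) dark <- dark & roi
  if (!any(dark)) return(dark)
  lab <- .label_components_8(dark)
  n <- max(lab)
  idx <- which(dark)
  ids <- lab[idx]
  ys <- (idx - 1L) %% nrow(dark) + 1L
  xs <- (idx - 1L) %/% nrow(dark) + 1L
  area <- tabulate(ids, nbins = n)
  # per-component centred second moments -> elongation
  sx <- tapply(xs, ids, sum); sy <- tapply(ys, ids, sum)
  sxx <- tapply(xs^2, ids, sum); syy <- tapply(ys^2, ids, sum)
  sxy <- tapply(xs * ys, ids, sum)
  k <- as.integer(names(sx))
  vxx <- sxx / area[k] - (sx / area[k])^2
  vyy <- syy / area[k] - (sy / area[k])^2
  vxy <- sxy / area[k] - (sx / area[k]) * (sy / area[k])
  tr <- vxx + vyy
  det_ <- vxx * vyy - vxy^2
  disc <- sqrt(pmax(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 0)
  elong <- ifelse(l2 < 1e-9, Inf, sqrt(l1 / l2))
  # component width via max inscribed radius (distance transform)
  dm <- t(EBImage::imageData(EBImage::distmap(.as_ebimage(dark * 255))))
  width <- 2 * tapply(dm[idx], ids, max)
  keep <- k[elong >= min_elongation & width <= max_width_px &
              area[k] >= min_area_px]
  out <- dark & FALSE
  out[idx[ids %in% keep]] <- TRUE
  out
}

#' Confusion counts between two masks
#'
#' @param pred,truth logical matrices of identical shape.
#' @param roi optional logical mask; counting is restricted to it.
#' @return named integer vector with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth, roi = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth have different shapes", call. = FALSE)
  if (!is.null(roi)) {
    if (!all(dim(roi) == dim(pred)))
      stop("roi shape mismatch", call. = FALSE)
    pred <- pred[roi]; truth <- truth[roi]
  }
  c(TP = sum(pred & truth), TN = sum(!pred & !truth),
    FP = sum(pred & !truth), FN = sum(!pred & truth))
}

#' Segmentation scores from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, IoU `TP/(TP+FP+FN)` and DICE `2TP/(FP+2TP+FN)`. Undefined
#' ratios (0/0) are reported as `NA`, distinguishing "no positives exist"
#' from "all missed".
#'
#' @param counts named vector from [confusion_counts()].
#' @return named numeric vector `acc`, `sensitivity`, `specificity`,
#'   `iou`, `dice`.
#' @export
seg_scores <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(acc = ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    iou = ratio(tp, tp + fp + fn),
    dice = ratio(2 * tp, fp + 2 * tp + fn))
}

#' Evaluate a segmentation against a reference
#'
#' @inheritParams confusion_counts
#' @return list with `counts` and `scores` (see [seg_scores()]).
#' @export
evaluate_segmentation <- function(pred, truth, roi = NULL) {
  counts <- confusion_counts(pred, truth, roi)
  list(counts = counts, scores = seg_scores(counts))
}
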