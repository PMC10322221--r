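test_that("Otsu threshold maximizes between-class variance", {
  # two equal spikes: threshold strictly between them, dark = low spike
  gimg <- matrix(c(rep(50, 5000), rep(200, 5000)), 100, 100)
  t1 <- otsu_threshold(gimg)
  expect_gt(t1, 50)
  expect_lte(t1, 200)
  expect_equal(sum(gimg < t1), 5000)
  # 90/10 mix at 0 and 255
  gimg2 <- matrix(c(rep(0, 9000), rep(255, 1000)), 100, 100)
  t2 <- otsu_threshold(gimg2)
  expect_equal(sum(gimg2 < t2), 9000)
  # oracle: the returned threshold achieves the global maximum of the
  # between-class variance over all 255 candidate thresholds
  set.seed(21)
  for (rep in 1:5) {
    vals <- sample(0:255, 4000, replace = TRUE,
                   prob = dnorm(0:255, sample(60:200, 1), 40) + 0.001)
    gm <- matrix(vals, 40, 100)
    t_ <- otsu_threshold(gm)
    scan <- vapply(1:255, function(t) between_class_variance(vals, t),
                   numeric(1))
    expect_equal(between_class_variance(vals, ceiling(t_)), max(scan),
                 tolerance = 1e-9)
  }
  expect_error(otsu_threshold(matrix(7, 10, 10)), "constant")
})

test_that("Otsu agrees with the EBImage reference on full frames", {
  set.seed(5)
  g <- matrix(c(rnorm(3000, 80, 15), rnorm(1000, 190, 20)), 40, 100)
  g <- pmin(pmax(g, 0), 255)
  t_mine <- otsu_threshold(g)
  t_ref <- EBImage::otsu(EBImage::Image(t(g) / 255)) * 255
  expect_lt(abs(t_mine - t_ref), 2)
})

test_that("Otsu threshold respects the ROI restriction", {
  g <- matrix(128, 60, 60)
  roi <- matrix(FALSE, 60, 60)
  roi[, 1:30] <- TRUE
  g[, 1:15] <- 40
  g[, 16:30] <- 200
  # outside ROI the image is flat 128; inside it is bimodal
  t_ <- otsu_threshold(g, roi)
  expect_gt(t_, 40)
  expect_lte(t_, 200)
})

test_that("vessel preselection keeps elongated thin components", {
  m <- matrix(FALSE, 300, 300)
  m[40:44, 30:229] <- TRUE          # 5 x 200 bar: elongation ~ 40
  m[150:189, 150:189] <- TRUE       # 40 x 40 blob: elongation 1
  kept <- preselect_vessels(m)
  expect_true(all(kept[42, 50:200]))
  expect_false(any(kept[150:189, 150:189]))
  # output is a subset of the input
  expect_true(all(!kept | m))
  expect_false(any(preselect_vessels(matrix(FALSE, 50, 50))))
  m2 <- matrix(FALSE, 300, 300)
  m2[40:44, 30:229] <- TRUE
  m2[200:206, 30:229] <- TRUE
  kept2 <- preselect_vessels(m2)
  lab <- EBImage::bwlabel(EBImage::Image(t(kept2) * 1))
  expect_equal(max(lab), 2)          # both bars retained
})

test_that("segmentation scores follow the printed formulas", {
  sc <- seg_scores(c(TP = 8, TN = 88, FP = 2, FN = 2))
  expect_equal(unname(sc["acc"]), 0.96)
  expect_equal(unname(sc["sensitivity"]), 0.8)
  expect_equal(unname(sc["specificity"]), 88 / 90, tolerance = 1e-12)
  expect_equal(unname(sc["iou"]), 8 / 12, tolerance = 1e-12)
  expect_equal(unname(sc["dice"]), 0.8)
})

test_that("degenerate masks give the documented scores and NA on 0/0", {
  truth <- matrix(FALSE, 10, 10)
  truth[3:6, 3:6] <- TRUE
  same <- evaluate_segmentation(truth, truth)
  expect_true(all(same$scores == 1))
  none <- evaluate_segmentation(matrix(FALSE, 10, 10), truth)
  expect_equal(unname(none$scores["sensitivity"]), 0)
  expect_equal(unname(none$scores["iou"]), 0)
  expect_equal(unname(none$scores["dice"]), 0)
  expect_equal(unname(none$scores["specificity"]), 1)
  # empty truth and empty prediction: sensitivity/IoU/DICE undefined
  empty <- evaluate_segmentation(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5))
  expect_true(is.na(empty$scores["sensitivity"]))
  expect_true(is.na(empty$scores["iou"]))
  expect_equal(unname(empty$scores["acc"]), 1)
})

test_that("DICE-IoU identity and symmetry hold on random masks", {
  set.seed(31)
  for (i in 1:100) {
    a <- matrix(runif(400) < runif(1), 20, 20)
    b <- matrix(runif(400) < runif(1), 20, 20)
    sa <- seg_scores(confusion_counts(a, b))
    if (!is.na(sa["iou"]))
      expect_equal(unname(sa["dice"]),
                   2 * sa[["iou"]] / (1 + sa[["iou"]]), tolerance = 1e-12)
    sb <- seg_scores(confusion_counts(b, a))
    expect_equal(sa[["acc"]], sb[["acc"]])
    expect_equal(sa[["iou"]], sb[["iou"]])
    expect_equal(sa[["dice"]], sb[["dice"]])
  }
})

test_that("scores restricted to an ROI ignore outside pixels", {
  pred <- matrix(TRUE, 10, 10)
  truth <- matrix(FALSE, 10, 10)
  roi <- matrix(FALSE, 10, 10)
  roi[1:5, ] <- TRUE
  truth[1:5, ] <- TRUE
  sc <- evaluate_segmentation(pred, truth, roi)$scores
  expect_equal(unname(sc["acc"]), 1)   # disagreement lies outside the ROI
  expect_error(confusion_counts(pred, truth[1:5, ]), "shape")
})
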