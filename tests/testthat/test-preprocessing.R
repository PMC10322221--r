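test_that("grayscale conversion applies the weighted channel sum", {
  px <- array(0, c(1, 1, 3))
  px[1, 1, ] <- c(255, 0, 0)
  expect_equal(as.numeric(to_grayscale(px)), 76.245)
  px[1, 1, ] <- c(0, 0, 0)
  expect_equal(as.numeric(to_grayscale(px)), 0)
  px[1, 1, ] <- c(100, 100, 100)
  # pipeline weights sum to 1.03, so neutral gray maps to 103
  expect_equal(as.numeric(to_grayscale(px)), 103)
  expect_equal(as.numeric(to_grayscale(px, gray_coeffs("bt601"))), 100)
})

test_that("grayscale conversion is linear in the image", {
  set.seed(11)
  img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  for (a in c(0.25, 0.5, 1)) {
    expect_equal(to_grayscale(img * a), a * to_grayscale(img),
                 tolerance = 1e-12)
  }
})

test_that("ROI extraction recovers a bright disk and is idempotent", {
  img <- gray_rgb(matrix(0, 400, 400))
  dsk <- disk_mask(400, c(200, 200), 100)
  img[, , 1][dsk] <- 200
  img[, , 2][dsk] <- 150
  img[, , 3][dsk] <- 100
  roi <- extract_roi(img)
  expect_lt(abs(sum(roi) / (pi * 100^2) - 1), 0.02)
  # single connected component (oracle: flood fill from one ROI pixel)
  filled <- matrix(FALSE, 400, 400)
  start <- which(roi)[1]
  queue <- start
  filled[start] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    y <- (i - 1) %% 400 + 1; x <- (i - 1) %/% 400 + 1
    for (dy in -1:1) for (dx in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= 400 && xx >= 1 && xx <= 400 &&
          roi[yy, xx] && !filled[yy, xx]) {
        filled[yy, xx] <- TRUE
        queue <- c(queue, (xx - 1) * 400 + yy)
      }
    }
  }
  expect_equal(sum(filled), sum(roi))
  # idempotence: masking the image to the ROI and re-extracting
  img2 <- img
  img2[, , 1][!roi] <- 0
  expect_identical(extract_roi(img2), roi)
})

test_that("ROI of a uniform image is the full frame; all-zero errors", {
  img <- gray_rgb(matrix(128, 64, 64))
  expect_true(all(extract_roi(img)))
  expect_error(extract_roi(gray_rgb(matrix(0, 64, 64))), "empty ROI")
})

test_that("median denoising follows the sort-and-pick contract", {
  expect_identical(median_denoise(matrix(42, 9, 9), 3), matrix(42, 9, 9))
  m <- matrix(0, 21, 21)
  m[11, 11] <- 255
  expect_equal(median_denoise(m, 3)[11, 11], 0)
  mm <- matrix(5, 7, 7)
  mm[3:5, 3:5] <- matrix(1:9, 3, 3)
  expect_equal(median_denoise(mm, 3)[4, 4], 5)   # median of 1..9
  expect_error(median_denoise(m, 4), "odd")
  expect_error(median_denoise(m, 1), "odd")
})

test_that("median denoising stays within [0, 255] and handles RGB", {
  set.seed(3)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  out <- median_denoise(img, 5)
  expect_true(all(out >= 0 & out <= 255))
  expect_equal(dim(out), dim(img))
})

test_that("mean calibration reaches the reference means", {
  set.seed(7)
  img <- array(runif(64 * 64 * 3) * 150 + 20, c(64, 64, 3))
  out <- normalize_image(img, reference_means = c(120, 110, 100))
  expect_equal(apply(out, 3, mean), c(120, 110, 100), tolerance = 0.5)
  # additive contract: mean 80 shifted to reference 120 is a +40 shift
  flat <- gray_rgb(matrix(80, 16, 16))
  out2 <- normalize_image(flat, reference_means = c(120, 120, 120))
  expect_equal(unique(as.numeric(out2)), 120)
  # multiplicative alternative
  out3 <- normalize_image(flat, reference_means = c(160, 160, 160),
                          mode = "multiplicative")
  expect_equal(unique(as.numeric(out3)), 160)
})

test_that("bilinear resampling is corner-aligned", {
  const <- gray_rgb(matrix(37, 8, 8))
  out <- normalize_image(const, target_size = 4)
  expect_equal(dim(out), c(4L, 4L, 3L))
  expect_equal(unique(as.numeric(out)), 37)
  chk <- matrix(c(0, 100, 100, 0), 2, 2)
  up <- bilinear_resize(chk, 3, 3)
  expect_equal(up[2, 2], 50)            # closed-form bilinear weight
  expect_equal(up[1, 1], 0)
  expect_equal(up[3, 3], 0)
  expect_error(bilinear_resize(chk, 1, 3), "degenerate")
})

test_that("CLAHE preserves flatness, order, and increases a ramp's range", {
  expect_equal(max(abs(clahe_enhance(matrix(77, 64, 64)) - 77)), 0)
  two <- matrix(50, 64, 64)
  two[, 33:64] <- 200
  en <- clahe_enhance(two)
  expect_lt(max(en[, 1:32]), min(en[, 33:64]))   # monotone mapping
  ramp <- matrix(rep(seq(100, 140, length.out = 64), each = 64), 64, 64)
  enr <- clahe_enhance(ramp)
  expect_gt(diff(range(enr)), diff(range(ramp)))
  expect_true(all(enr >= 0 & enr <= 255))
})

test_that("the preprocessing chain returns aligned outputs", {
  ph <- phantom_fundus(size = 320, disc_radius = 30, vein_width = 9,
                       noise_sd = 2, seed = 4)
  pp <- preprocess(ph$image, preprocess_config(target_size = NULL))
  expect_equal(dim(pp$gray), dim(ph$image)[1:2])
  expect_equal(dim(pp$roi), dim(pp$gray))
  expect_gt(sum(pp$roi), 0)
  expect_true(all(pp$gray >= 0 & pp$gray <= 255))
  # resampling carries the ROI along
  pp2 <- preprocess(ph$image, preprocess_config(target_size = 160))
  expect_equal(dim(pp2$gray), c(160L, 160L))
  expect_equal(dim(pp2$roi), c(160L, 160L))
})
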