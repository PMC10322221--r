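test_that("bar diameters are recovered within 1 px at several angles", {
  for (w in c(5, 9, 15, 21)) {
    for (a in c(0, 30, 45, 60)) {
      ph <- generate_phantom(list(kind = "bar", width = w, length = 200,
                                  angle_deg = a, size = 300))
      g <- centerline_graph(ph$mask)
      sec <- sample_diameters(ph$mask, g)
      expect_gt(nrow(sec), 10)
      expect_lt(abs(mean(sec$d_px) - w), 1)
    }
  }
})

test_that("micrometre conversion uses the 1.5 mm papillary reference", {
  ph <- generate_phantom(list(kind = "bar", width = 11, length = 200,
                              size = 300))
  g <- centerline_graph(ph$mask)
  disc <- calibrate_disc(c(20, 20), 300)    # PD = 300 px -> 5 um/px
  sec <- sample_diameters(ph$mask, g, disc = disc)
  expect_equal(mean(sec$d_um), 55, tolerance = 5 / 55)
  expect_equal(sec$d_um / sec$d_px, rep(5, nrow(sec)), tolerance = 1e-12)
})

test_that("diameter sampling density follows the 5-px interval rule", {
  ph <- generate_phantom(list(kind = "bar", width = 9, length = 200,
                              size = 256))
  g <- centerline_graph(ph$mask)
  sec <- sample_diameters(ph$mask, g, step = 5, tangent_window = 7)
  # ~ (200 - 2*7)/5 samples on a single 200-px path
  expect_gt(nrow(sec), 33)
  expect_lt(nrow(sec), 41)
  # step 1 vs step 5 on a constant-width bar: same mean
  sec1 <- sample_diameters(ph$mask, g, step = 1, tangent_window = 7)
  expect_lt(abs(mean(sec1$d_px) - mean(sec$d_px)), 0.2)
  # empty graph -> empty frame
  ge <- centerline_graph(matrix(FALSE, 50, 50))
  expect_equal(nrow(sample_diameters(matrix(FALSE, 50, 50), ge)), 0)
})

test_that("average diameter and AVR follow their definitions", {
  secs <- data.frame(x = 1:3, y = 1, d_px = c(10, 12, 14),
                     d_um = c(50, 60, 70), segment = 1:3,
                     av_label = c("artery", "vein", "artery"))
  expect_equal(average_diameter(secs), 60)
  expect_equal(average_diameter(secs, "artery"), 60)
  expect_equal(average_diameter(secs, "vein"), 60)
  expect_true(is.na(average_diameter(secs[0, ])))
  expect_equal(avr(49.3, 70.4), 0.7003, tolerance = 1e-4)
  expect_equal(avr(55, 55), 1)
  expect_equal(avr(0, 70), 0)
  expect_true(is.na(avr(NA, 70)))
  expect_error(avr(50, 0), "positive")
})

test_that("two-width phantom averages to the midpoint width", {
  m <- matrix(FALSE, 300, 300)
  m[71:78, 30:270] <- TRUE        # 8 px
  m[201:216, 30:270] <- TRUE      # 16 px
  g <- centerline_graph(m)
  sec <- sample_diameters(m, g)
  expect_lt(abs(mean(sec$d_px) - 12), 1)
})

test_that("circumradius curvature recovers circle radii within 5%", {
  for (r in c(50, 100, 200, 400)) {
    ph <- generate_phantom(list(kind = "arc", radius = r, width = 9,
                                size = 2 * (r + 30)))
    g <- centerline_graph(ph$mask)
    cur <- sample_curvatures(g)
    expect_gt(nrow(cur), 5)
    expect_lt(abs(mean(cur$curvature) * r - 1), 0.05)
  }
})

test_that("straight paths have zero curvature and short segments none", {
  ph <- generate_phantom(list(kind = "bar", width = 9, length = 220,
                              size = 256))
  g <- centerline_graph(ph$mask)
  cur <- sample_curvatures(g)
  expect_true(all(cur$curvature <= 1e-4))
  # a path shorter than twice the arc half-length yields no samples
  short <- g$segments[[1]]
  expect_null(curvature_at(short$path[1:30, ], 15, arc_half = 25))
})

test_that("tortuosity pools sample curvatures as stated", {
  cur <- data.frame(x = 1, y = 1, curvature = c(rep(0.01, 50), rep(0, 50)),
                    segment = rep(1:2, each = 50),
                    av_label = "unknown")
  expect_equal(tortuosity(cur), 0.005)
  expect_equal(tortuosity(cur, "per_vessel_mean"), 0.005)
  expect_true(is.na(tortuosity(cur[0, ])))
  # single arc vessel of radius 100: ~0.01 (x1000 -> 10)
  ph <- generate_phantom(list(kind = "arc", radius = 100, width = 9,
                              size = 260))
  g <- centerline_graph(ph$mask)
  tt <- tortuosity(sample_curvatures(g))
  expect_equal(tt * 1000, 10, tolerance = 0.05)
})

test_that("box-counting dimension matches line, disk and carpet", {
  line <- matrix(FALSE, 1024, 1024)
  line[512, ] <- TRUE
  fd_line <- fractal_dimension(line)$fd
  expect_gte(fd_line, 0.95)
  expect_lte(fd_line, 1.10)
  disk <- disk_mask(700, c(350, 350), 300)
  fd_disk <- fractal_dimension(disk)$fd
  expect_gte(fd_disk, 1.85)
  expect_lte(fd_disk, 2.00)
  sp <- generate_phantom(list(kind = "sierpinski", iterations = 5,
                              cell_px = 3))
  fd_carpet <- fractal_dimension(sp$mask)$fd
  expect_lt(abs(fd_carpet - log(8) / log(3)), 0.05)
})

test_that("box counts are monotone and the series is well-formed", {
  ph <- generate_phantom(list(kind = "y_junction", size = 300))
  bc <- fractal_dimension(ph$mask)
  expect_true(all(diff(bc$counts) <= 0))     # N non-increasing in epsilon
  expect_true(bc$fd >= 0 && bc$fd <= 2)
  # removing a vessel never increases any box count
  m2 <- ph$mask
  m2[, 1:150] <- FALSE
  bc2 <- fractal_dimension(m2, epsilons = bc$epsilons)
  expect_true(all(bc2$counts <= bc$counts))
  expect_error(fractal_dimension(matrix(FALSE, 10, 10)), "empty")
})

test_that("fractal dimension is stable under translation and rotation", {
  ph <- generate_phantom(list(kind = "y_junction", size = 300))
  fd0 <- fractal_dimension(ph$mask)$fd
  shifted <- matrix(FALSE, 300, 300)
  shifted[8:300, 6:300] <- ph$mask[1:293, 1:295]
  expect_lt(abs(fractal_dimension(shifted)$fd - fd0), 0.02)
  rotated <- t(ph$mask)[300:1, ]             # 90 degree rotation
  expect_lt(abs(fractal_dimension(rotated)$fd - fd0), 0.02)
})

test_that("vascular density is an exact pixel ratio", {
  roi <- matrix(FALSE, 40, 40)
  roi[1:25, 1:40] <- TRUE                    # 1000 ROI px
  mask <- matrix(FALSE, 40, 40)
  mask[1:10, 1:10] <- TRUE                   # 100 vessel px
  expect_identical(vascular_density(mask, roi)$rho, 0.1)
  expect_identical(vascular_density(roi, roi)$rho, 1)
  expect_identical(vascular_density(matrix(FALSE, 40, 40), roi)$rho, 0)
  # monotone: adding vessel pixels never decreases rho
  mask2 <- mask
  mask2[20, 20] <- TRUE
  expect_gt(vascular_density(mask2, roi)$rho,
            vascular_density(mask, roi)$rho)
  expect_error(vascular_density(mask, matrix(FALSE, 40, 40)), "empty")
})

test_that("main vessel selection takes the widest chain per half", {
  # disc at center; a wide and a narrow vessel above, one below
  m <- matrix(FALSE, 400, 400)
  m[93:108, 60:340] <- TRUE       # 16 px, upper
  m[153:160, 60:340] <- TRUE      # 8 px, upper
  m[293:300, 60:340] <- TRUE      # 8 px, lower
  disc <- calibrate_disc(c(200, 200), 80)
  g <- centerline_graph(m)
  sec <- sample_diameters(m, g, disc = disc)
  mains <- select_main_vessels(g, sec, disc)
  expect_length(mains$upper, 1)
  expect_length(mains$lower, 1)
  seg_y <- vapply(mains["upper"], function(i)
    mean(g$segments[[i[1]]]$path[, "y"]), numeric(1))
  expect_lt(seg_y, 120)           # the 16-px vessel was chosen
  # vessels only below the disc center: upper main missing
  m2 <- matrix(FALSE, 400, 400)
  m2[293:300, 60:340] <- TRUE
  g2 <- centerline_graph(m2)
  sec2 <- sample_diameters(m2, g2, disc = disc)
  mains2 <- select_main_vessels(g2, sec2, disc)
  expect_length(mains2$upper, 0)
  expect_length(mains2$lower, 1)
})

test_that("branch angles on designed Y junctions are within 3 degrees", {
  for (a in c(30, 45, 60, 90)) {
    ph <- generate_phantom(list(kind = "y_junction", angle_deg = a,
                                size = 400))
    g <- centerline_graph(ph$mask)
    disc <- calibrate_disc(c(30, 200), 60)  # left of the main: downstream +x
    sec <- sample_diameters(ph$mask, g, disc = disc)
    mains <- select_main_vessels(g, sec, disc, max_dist_pd = 10)
    ba <- branching_angles(g, mains, disc, max_dist_pd = 10)
    expect_equal(nrow(ba$angles), 1)
    expect_lt(abs(ba$mean_deg - a), 3)
  }
})

test_that("graphs without branch nodes yield no angles", {
  ph <- generate_phantom(list(kind = "bar", width = 9, length = 200,
                              size = 256))
  g <- centerline_graph(ph$mask)
  disc <- calibrate_disc(c(30, 128), 60)
  sec <- sample_diameters(ph$mask, g, disc = disc)
  mains <- select_main_vessels(g, sec, disc, max_dist_pd = 10)
  ba <- branching_angles(g, mains, disc, max_dist_pd = 10)
  expect_equal(nrow(ba$angles), 0)
  expect_true(is.na(ba$mean_deg))
})

test_that("doubling vessel width doubles diameter, keeps tortuosity", {
  ph1 <- generate_phantom(list(kind = "arc", radius = 120, width = 7,
                               size = 320))
  ph2 <- generate_phantom(list(kind = "arc", radius = 120, width = 14,
                               size = 320))
  g1 <- centerline_graph(ph1$mask)
  g2 <- centerline_graph(ph2$mask)
  d1 <- mean(sample_diameters(ph1$mask, g1)$d_px)
  d2 <- mean(sample_diameters(ph2$mask, g2)$d_px)
  expect_equal(d2 / d1, 2, tolerance = 0.05)
  t1 <- tortuosity(sample_curvatures(g1))
  t2 <- tortuosity(sample_curvatures(g2))
  expect_equal(t2 / t1, 1, tolerance = 0.10)
})
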