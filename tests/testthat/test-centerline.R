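test_that("skeletonizing a bar yields a single midline path", {
  ph <- generate_phantom(list(kind = "bar", width = 11, length = 200,
                              size = 256))
  sk <- skeletonize(ph$mask)
  expect_true(all(!sk | ph$mask))            # skeleton within the mask
  g <- extract_segments(sk)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$kind == "branch"), 0)
  expect_equal(length(g$segments), 1)
  # path stays within 1 px of the designed midline
  midy <- round(256 / 2)
  expect_true(all(abs(g$segments[[1]]$path[, "y"] - midy) <= 1))
  expect_equal(g$segments[[1]]$length_px, 200, tolerance = 0.05)
})

test_that("skeleton topology matches ring, Y and X phantoms", {
  ring <- generate_phantom(list(kind = "ring", radius = 80, size = 250))
  gr <- centerline_graph(ring$mask)
  expect_equal(nrow(gr$nodes), 0)
  expect_equal(length(gr$segments), 1)
  expect_true(gr$segments[[1]]$closed)

  y <- generate_phantom(list(kind = "y_junction", size = 300))
  gy <- centerline_graph(y$mask)
  expect_equal(sum(gy$nodes$kind == "branch"), 1)
  expect_equal(sum(gy$nodes$kind == "endpoint"), 3)
  expect_equal(length(gy$segments), 3)
  bid <- gy$nodes$id[gy$nodes$kind == "branch"]
  expect_true(all(vapply(gy$segments, function(s) bid %in% s$nodes,
                         logical(1))))

  x <- generate_phantom(list(kind = "x_crossing", size = 300))
  gx <- centerline_graph(x$mask)
  expect_equal(sum(gx$nodes$kind == "branch"), 1)   # merged degree-4 node
  expect_equal(sum(gx$nodes$kind == "endpoint"), 4)
  expect_equal(length(gx$segments), 4)
})

test_that("skeletonization preserves connected-component count", {
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(FALSE, 200, 200)
    for (k in 1:4) {
      c0 <- runif(2, 40, 160)
      ang <- runif(1, 0, pi)
      d <- c(cos(ang), sin(ang))
      g <- grid_xy(200)
      p1 <- c0 - 40 * d; p2 <- c0 + 40 * d
      l2 <- sum((p2 - p1)^2)
      t_ <- pmin(pmax(((g$x - p1[1]) * (p2[1] - p1[1]) +
                         (g$y - p1[2]) * (p2[2] - p1[2])) / l2, 0), 1)
      m <- m | sqrt((g$x - (p1[1] + t_ * (p2[1] - p1[1])))^2 +
                      (g$y - (p1[2] + t_ * (p2[2] - p1[2])))^2) <= 3.5
    }
    sk <- skeletonize(m)
    expect_equal(count_components8(sk), count_components8(m))
    expect_true(all(!sk | m))
  }
})

test_that("segments plus nodes partition the skeleton pixels", {
  for (kind in c("bar", "y_junction", "x_crossing", "ring")) {
    ph <- generate_phantom(list(kind = kind, size = 300))
    sk <- skeletonize(ph$mask)
    g <- extract_segments(sk)
    h <- nrow(sk)
    covered <- matrix(0L, h, ncol(sk))
    for (s in g$segments) {
      idx <- (s$path[, "x"] - 1L) * h + s$path[, "y"]
      interior <- idx[g$node_px[idx] == 0L]
      covered[interior] <- covered[interior] + 1L
    }
    # every non-node skeleton pixel in exactly one segment
    nonnode <- sk & g$node_px == 0L
    expect_true(all(covered[nonnode] == 1L))
    expect_true(all(covered[!nonnode] == 0L))
    # node pixels + interior pixels = skeleton pixels
    expect_equal(sum(nonnode) + sum(g$node_px > 0), sum(sk))
  }
})

test_that("two disjoint bars give a disconnected two-segment graph", {
  m <- matrix(FALSE, 200, 200)
  m[48:52, 20:180] <- TRUE
  m[148:152, 20:180] <- TRUE
  g <- centerline_graph(m)
  expect_equal(length(g$segments), 2)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4)
})

test_that("pruning removes short spurs and restores the through-path", {
  # Y with one short spur: main bar + 6-px stub
  m <- matrix(FALSE, 200, 200)
  m[98:102, 20:180] <- TRUE
  m[92:97, 99:103] <- TRUE          # short vertical stub
  g0 <- centerline_graph(m, prune_px = 0, junction_merge_px = 0)
  g <- centerline_graph(m, prune_px = 12)
  expect_equal(sum(g$nodes$kind == "branch"), 0)
  expect_equal(length(g$segments), 1)
  expect_gte(length(g0$segments), length(g$segments))
  # min_length 0 leaves the graph unchanged
  gid <- centerline_graph(m, prune_px = 0, junction_merge_px = 0)
  expect_identical(prune_graph(gid, 0), gid)
})

test_that("graph extraction is deterministic", {
  ph <- generate_phantom(list(kind = "y_junction", size = 300))
  g1 <- centerline_graph(ph$mask)
  g2 <- centerline_graph(ph$mask)
  expect_identical(g1, g2)
})

test_that("artery/vein labels attach by majority vote", {
  ph <- phantom_fundus(size = 400, disc_radius = 30, vein_width = 9,
                       noise_sd = 0)
  g <- centerline_graph(ph$mask, av_mask = ph$av_mask)
  labs <- vapply(g$segments, `[[`, "", "av_label")
  expect_true(any(labs == "artery"))
  expect_true(any(labs == "vein"))
  expect_error(label_segments(g, matrix(0L, 10, 10)), "mismatch")
})
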