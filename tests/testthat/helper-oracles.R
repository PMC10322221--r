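# Independent oracles and small fixture builders shared across tests.

# Brute-force Otsu: between-class variance computed directly on the value
# vector for one candidate threshold (dark class = {v < t}).
between_class_variance <- function(vals, t) {
  v <- round(vals)
  g0 <- v[v < t]
  g1 <- v[v >= t]
  if (!length(g0) || !length(g1)) return(-Inf)
  w0 <- length(g0) / length(v)
  w0 * (1 - w0) * (mean(g0) - mean(g1))^2
}

# Exhaustive minimum enclosing circle: every pair diameter-circle and
# every triple circumcircle, smallest one covering all points.
mec_oracle <- function(P) {
  n <- nrow(P)
  best <- list(radius = Inf)
  covers <- function(ctr, r) all(sqrt((P[, 1] - ctr[1])^2 +
                                        (P[, 2] - ctr[2])^2) <= r + 1e-9)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ctr <- (P[i, ] + P[j, ]) / 2
    r <- sqrt(sum((P[i, ] - P[j, ])^2)) / 2
    if (r < best$radius && covers(ctr, r)) best <- list(center = ctr,
                                                        radius = r)
  }
  if (n >= 3) for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1))
    for (k in (j + 1):n) {
      a <- P[i, ]; b <- P[j, ]; c <- P[k, ]
      M <- 2 * rbind(b - a, c - a)
      if (abs(det(M)) < 1e-12) next
      rhs <- c(sum(b^2) - sum(a^2), sum(c^2) - sum(a^2))
      ctr <- as.numeric(solve(M, rhs))
      r <- sqrt(sum((a - ctr)^2))
      if (r < best$radius && covers(ctr, r)) best <- list(center = ctr,
                                                          radius = r)
    }
  best
}

# Coordinate grid for building masks directly in tests.
grid_xy <- function(h, w = h) {
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w))
}

disk_mask <- function(h, center, radius, w = h) {
  g <- grid_xy(h, w)
  sqrt((g$x - center[1])^2 + (g$y - center[2])^2) <= radius
}

# 8-connected component count by breadth-first flood fill (independent of
# the package's labeling).
count_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0
  todo <- which(mask)
  for (start in todo) {
    if (seen[start]) next
    n <- n + 1
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      y <- (i - 1) %% h + 1; x <- (i - 1) %/% h + 1
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
            mask[yy, xx] && !seen[yy, xx]) {
          seen[yy, xx] <- TRUE
          queue <- c(queue, (xx - 1) * h + yy)
        }
      }
    }
  }
  n
}

# Grayscale matrix replicated into an RGB array.
gray_rgb <- function(m) {
  a <- array(0, dim = c(nrow(m), ncol(m), 3))
  a[, , 1] <- m; a[, , 2] <- m; a[, , 3] <- m
  a
}
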