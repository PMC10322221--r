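## Vessel centerline extraction: topology-preserving thinning to a 1-px
## skeleton, 8-neighbourhood node classification (endpoints, branch
## points), decomposition into ordered vessel segments, spur pruning.

#' @noRd
.nbr <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  ys <- max(1L, 1L - dy):min(h, h - dy)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

## Zhang-Suen neighbour order: P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW,
## P8=W, P9=NW (y grows downward, x grows rightward).
.ZS_OFF <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

#' Skeletonize a vessel mask
#'
#' Reduces the mask to a 1-pixel-wide, 8-connected centerline by iterative
#' thinning (Zhang-Suen parallel deletion of simple boundary pixels),
#' which preserves the connected-component and loop structure of the
#' mask — the contract the downstream diameter and tortuosity math needs.
#'
#' @param mask logical matrix.
#' @return logical matrix, the skeleton (subset of `mask`).
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask), nrow = nrow(mask))
  if (!any(m == 1L)) return(mask & FALSE)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(.ZS_OFF, function(o) .nbr(m, o[1L], o[2L]))
      B <- Reduce(`+`, P)
      seqP <- c(P, P[1L])
      A <- Reduce(`+`, lapply(1:8, function(i)
        (seqP[[i]] == 0L) * (seqP[[i + 1L]] == 1L)))
      if (step == 1L) {
        e1 <- P[[1L]] * P[[3L]] * P[[5L]]   # P2*P4*P6
        e2 <- P[[3L]] * P[[5L]] * P[[7L]]   # P4*P6*P8
      } else {
        e1 <- P[[1L]] * P[[3L]] * P[[7L]]   # P2*P4*P8
        e2 <- P[[1L]] * P[[5L]] * P[[7L]]   # P2*P6*P8
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & e1 == 0L & e2 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  .remove_staircase_corners(m == 1L)
}

## Parallel thinning leaves redundant pixels (staircase corners and
## two-pixel-thick diagonal joints) that show up as spurious degree-3
## neighbourhoods. A pixel is redundant when its foreground neighbours
## remain a single 8-connected component without it (so its removal
## changes no topology) and it is neither an endpoint nor interior to a
## 2-px-wide run (its neighbours would fall apart). Removing redundant
## pixels sequentially yields a minimal 8-connected skeleton.
#' @noRd
.remove_staircase_corners <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  repeat {
    cand <- which(skel & .neighbor_count(skel) >= 2L)
    removed <- FALSE
    for (i in cand) {
      y <- (i - 1L) %% h + 1L; x <- (i - 1L) %/% h + 1L
      nb <- matrix(0, 0L, 2L)
      for (o in .ZS_OFF) {
        yy <- y + o[1L]; xx <- x + o[2L]
        if (yy >= 1L && yy <= h && xx >= 1L && xx <= w && skel[yy, xx])
          nb <- rbind(nb, c(yy, xx))
      }
      k <- nrow(nb)
      if (k < 2L || k > 6L) next
      ## neighbours must stay one 8-connected component without the pixel
      comp <- seq_len(k)
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
        if (all(abs(nb[a, ] - nb[b, ]) <= 1L))
          comp[comp == comp[b]] <- comp[a]
      if (length(unique(comp)) == 1L) {
        skel[i] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) return(skel)
  }
}

#' @noRd
.neighbor_count <- function(skel) {
  m <- matrix(as.integer(skel), nrow = nrow(skel))
  Reduce(`+`, lapply(.ZS_OFF, function(o) .nbr(m, o[1L], o[2L])))
}

#' Classify skeleton nodes
#'
#' Counts each centerline pixel's 8-neighbourhood: pixels with exactly one
#' neighbour are endpoints; pixels with three or more are branch-point
#' candidates. Adjacent branch candidates (within 2 px) are merged into a
#' single node at their centroid, since digital skeletons render one
#' anatomical bifurcation as a small cluster of high-degree pixels (and a
#' 4-way crossing as several degree-3 pixels).
#'
#' @param skel logical skeleton matrix.
#' @return list with `nodes` (data.frame: `id`, `x`, `y`, `kind`, `size`)
#'   and `node_px` (integer matrix mapping skeleton pixels to node ids,
#'   0 elsewhere).
#' @export
classify_nodes <- function(skel) {
  h <- nrow(skel)
  nc <- .neighbor_count(skel)
  node_px <- matrix(0L, h, ncol(skel))
  nodes <- list()
  nid <- 0L
  branch <- skel & nc >= 3L
  if (any(branch)) {
    grown <- .from_ebimage(EBImage::dilate(
      .as_ebimage(branch * 255), EBImage::makeBrush(3L, "box"))) > 127
    glab <- .label_components(grown)
    bidx <- which(branch)
    cl <- glab[bidx]
    for (g in sort(unique(cl))) {
      nid <- nid + 1L
      px <- bidx[cl == g]
      node_px[px] <- nid
      ys <- (px - 1L) %% h + 1L
      xs <- (px - 1L) %/% h + 1L
      nodes[[nid]] <- data.frame(id = nid, x = mean(xs), y = mean(ys),
                                 kind = "branch", size = length(px))
    }
  }
  eidx <- which(skel & nc == 1L & node_px == 0L)
  for (px in eidx) {
    nid <- nid + 1L
    node_px[px] <- nid
    nodes[[nid]] <- data.frame(id = nid, x = (px - 1L) %/% h + 1L,
                               y = (px - 1L) %% h + 1L,
                               kind = "endpoint", size = 1L)
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes)
  else data.frame(id = integer(), x = numeric(), y = numeric(),
                  kind = character(), size = integer())
  list(nodes = nodes, node_px = node_px)
}

#' @noRd
.px_xy <- function(idx, h) cbind(x = (idx - 1L) %/% h + 1L,
                                 y = (idx - 1L) %% h + 1L)

#' @noRd
.path_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Decompose a skeleton into ordered vessel segments
#'
#' Walks the skeleton between nodes, producing ordered pixel paths whose
#' first and last pixels are node pixels; every non-node skeleton pixel
#' appears in exactly one path. Isolated cycles (no nodes) become closed
#' segments. The walk order is a fixed pixel scan, so the decomposition
#' is deterministic.
#'
#' @param skel logical skeleton matrix.
#' @param nodes result of [classify_nodes()]; computed when `NULL`.
#' @return list of class `centerline_graph` with `skeleton`, `nodes`,
#'   `node_px`, `segments` (each: `id`, `path` n x 2 (x, y) matrix,
#'   `nodes` length-2 node ids (`NA` for loop ends), `length_px`,
#'   `closed`, `av_label`).
#' @export
extract_segments <- function(skel, nodes = NULL) {
  if (is.null(nodes)) nodes <- classify_nodes(skel)
  h <- nrow(skel); w <- ncol(skel)
  node_px <- nodes$node_px
  doff <- vapply(.ZS_OFF, function(o) o[1L] + o[2L] * h, integer(1L))
  ## prefer 4-adjacent continuations over diagonal ones (indices 1,3,5,7
  ## in .ZS_OFF are N, E, S, W)
  doff <- doff[c(1L, 3L, 5L, 7L, 2L, 4L, 6L, 8L)]
  dy <- vapply(.ZS_OFF, `[`, integer(1L), 1L)[c(1L, 3L, 5L, 7L, 2L, 4L, 6L, 8L)]
  in_frame <- function(i, d, dyv) {
    y <- (i - 1L) %% h + 1L
    yn <- y + dyv
    j <- i + d
    yn >= 1L & yn <= h & j >= 1L & j <= h * w
  }
  nbrs_of <- function(i) {
    j <- i + doff
    j[in_frame(i, doff, dy) & skel[pmin(pmax(j, 1L), h * w)]]
  }
  visited <- node_px > 0L
  segments <- list()
  sid <- 0L
  pair_keys <- character()
  add_segment <- function(path_idx, n1, n2, closed = FALSE) {
    sid <<- sid + 1L
    xy <- .px_xy(path_idx, h)
    segments[[sid]] <<- list(id = sid, path = xy, nodes = c(n1, n2),
                             length_px = .path_length(xy), closed = closed,
                             av_label = "unknown")
  }
  walk_from <- function(start, first) {
    path <- c(start, first)
    visited[first] <<- TRUE
    prev <- start; cur <- first
    repeat {
      cand <- setdiff(nbrs_of(cur), prev)
      nodecand <- cand[node_px[cand] > 0L]
      stepcand <- cand[node_px[cand] == 0L & !visited[cand]]
      if (length(stepcand)) {
        ## continue along unvisited interior; but if a different node is
        ## directly adjacent too, terminate there only when no interior
        ## continuation exists (keeps the path maximal)
        nxt <- stepcand[1L]
        path <- c(path, nxt)
        visited[nxt] <<- TRUE
        prev <- cur; cur <- nxt
      } else if (length(nodecand)) {
        path <- c(path, nodecand[1L])
        return(list(path = path, end = node_px[nodecand[1L]]))
      } else {
        return(list(path = path, end = NA_integer_))
      }
    }
  }
  node_pixels <- which(node_px > 0L)
  for (np in node_pixels) {
    for (q in nbrs_of(np)) {
      if (node_px[q] > 0L) {
        if (node_px[q] != node_px[np]) {   # two nodes directly adjacent
          key <- paste(sort(c(np, q)), collapse = "-")
          if (!key %in% pair_keys) {
            pair_keys <- c(pair_keys, key)
            add_segment(c(np, q), node_px[np], node_px[q])
          }
        }
      } else if (!visited[q]) {
        wk <- walk_from(np, q)
        add_segment(wk$path, node_px[np], wk$end)
      }
    }
  }
  ## leftover pixels: isolated cycles or isolated pixels
  remaining <- which(skel & !visited)
  for (start in remaining) {
    if (visited[start]) next
    visited[start] <- TRUE
    nb <- nbrs_of(start)
    if (length(nb) == 0L) {           # isolated single pixel
      add_segment(start, NA_integer_, NA_integer_)
      next
    }
    wk <- walk_from(start, nb[1L])
    path <- wk$path
    closed <- length(path) > 2L &&
      any(nbrs_of(path[length(path)]) == start)
    if (closed) path <- c(path, start)
    add_segment(path, NA_integer_, NA_integer_, closed = closed)
  }
  structure(list(skeleton = skel, nodes = nodes$nodes, node_px = node_px,
                 segments = segments, dim = c(h, w)),
            class = "centerline_graph")
}

#' Build the centerline graph of a vessel mask
#'
#' Convenience wrapper: skeletonize, classify nodes, extract segments,
#' and optionally prune spurs and attach artery/vein labels.
#'
#' @param mask logical vessel mask.
#' @param prune_px spur-pruning threshold in pixels (0 disables);
#'   default 10, below the 25-px curvature end exclusion so pruning never
#'   silently removes measurable geometry.
#' @param junction_merge_px junctions of wide vessels skeletonize into
#'   small clusters of nearby branch nodes; branch nodes joined by
#'   segments up to this length are contracted into one node (0
#'   disables).
#' @param av_mask optional integer artery/vein label mask (1 = artery,
#'   2 = vein).
#' @return `centerline_graph`.
#' @export
centerline_graph <- function(mask, prune_px = 10, junction_merge_px = 10,
                             av_mask = NULL) {
  g <- extract_segments(skeletonize(mask))
  if (prune_px > 0) g <- prune_graph(g, prune_px)
  if (junction_merge_px > 0) g <- .contract_junctions(g, junction_merge_px)
  if (!is.null(av_mask)) g <- label_segments(g, av_mask)
  g
}

## Contract branch-branch segments shorter than max_len into single
## nodes (union-find over their end nodes); their interior pixels, and
## those of short junction self-loops, become node pixels. This restores
## the one-node-per-bifurcation picture that wide-vessel junctions lose.
#' @noRd
.contract_junctions <- function(graph, max_len = 10) {
  nodes <- graph$nodes
  if (!nrow(nodes)) return(graph)
  segs <- graph$segments
  parent <- seq_len(nrow(nodes))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  absorb <- logical(length(segs))
  for (s in segs) {
    e <- s$nodes
    if (any(is.na(e))) next
    if (s$length_px <= max_len && all(nodes$kind[e] == "branch")) {
      absorb[s$id] <- TRUE
      if (e[1L] != e[2L]) parent[find(e[2L])] <- find(e[1L])
    }
  }
  if (!any(absorb)) return(graph)
  root <- vapply(seq_len(nrow(nodes)), find, 0L)
  h <- graph$dim[1L]
  node_px <- graph$node_px
  node_px[node_px > 0L] <- root[node_px[node_px > 0L]]
  for (s in segs[absorb]) {
    idx <- (s$path[, "x"] - 1L) * h + s$path[, "y"]
    r <- root[s$nodes[1L]]
    node_px[idx[node_px[idx] == 0L]] <- r
  }
  used <- sort(unique(node_px[node_px > 0L]))
  newid <- integer(nrow(nodes))
  newid[used] <- seq_along(used)
  node_px[node_px > 0L] <- newid[node_px[node_px > 0L]]
  new_nodes <- do.call(rbind, lapply(seq_along(used), function(i) {
    px <- which(node_px == i)
    members <- which(newid[root] == i)
    data.frame(id = i, x = mean((px - 1L) %/% h + 1L),
               y = mean((px - 1L) %% h + 1L),
               kind = if (any(nodes$kind[members] == "branch")) "branch"
               else "endpoint",
               size = length(px))
  }))
  kept <- segs[!absorb]
  kept <- lapply(seq_along(kept), function(i) {
    s <- kept[[i]]
    s$id <- i
    s$nodes <- vapply(s$nodes, function(e)
      if (is.na(e)) NA_integer_ else newid[root[e]], integer(1L))
    s
  })
  graph$nodes <- new_nodes
  graph$node_px <- node_px
  graph$segments <- kept
  graph
}

#' @export
print.centerline_graph <- function(x, ...) {
  cat(sprintf(
    "centerline graph: %d skeleton px, %d nodes (%d branch), %d segments\n",
    sum(x$skeleton), nrow(x$nodes), sum(x$nodes$kind == "branch"),
    length(x$segments)))
  invisible(x)
}

#' Prune short terminal segments (spurs)
#'
#' Removes terminal segments (those ending in an endpoint node) shorter
#' than `min_length_px`; branch nodes reduced to degree 2 by a removal are
#' merged back into a single through-path. Segments joining two branch
#' nodes are never removed. Applied repeatedly until stable.
#'
#' @param graph `centerline_graph`.
#' @param min_length_px minimum terminal segment length to keep.
#' @return pruned `centerline_graph`.
#' @export
prune_graph <- function(graph, min_length_px = 10) {
  if (min_length_px <= 0) return(graph)
  skel <- graph$skeleton
  repeat {
    n_before <- sum(skel)
    kinds <- graph$nodes$kind
    spur <- Filter(function(s) {
      ends <- s$nodes
      if (s$closed) return(FALSE)
      terminal <- any(is.na(ends)) ||
        any(kinds[ends[!is.na(ends)]] == "endpoint")
      both_branch <- !any(is.na(ends)) && all(kinds[ends] == "branch") &&
        ends[1L] != ends[2L]
      terminal && !both_branch && s$length_px < min_length_px
    }, graph$segments)
    if (!length(spur)) return(graph)
    h <- nrow(skel)
    for (s in spur) {
      idx <- (s$path[, "x"] - 1L) * h + s$path[, "y"]
      keep <- graph$node_px[idx] > 0L &
        graph$nodes$kind[pmax(graph$node_px[idx], 1L)] == "branch"
      skel[idx[!keep]] <- FALSE
    }
    if (sum(skel) == n_before) return(graph)  # nothing removable
    graph <- extract_segments(skel)
  }
}

#' Attach artery/vein labels to segments
#'
#' Each segment is labelled by majority vote of the artery/vein label mask
#' over its path pixels (1 = artery, 2 = vein; ties or no labelled pixels
#' give "unknown").
#'
#' @param graph `centerline_graph`.
#' @param av_mask integer matrix with labels 0..3.
#' @return graph with `av_label` set on each segment.
#' @export
label_segments <- function(graph, av_mask) {
  if (!all(dim(av_mask) == graph$dim))
    stop("av_mask shape mismatch", call. = FALSE)
  h <- graph$dim[1L]
  graph$segments <- lapply(graph$segments, function(s) {
    idx <- (s$path[, "x"] - 1L) * h + s$path[, "y"]
    labs <- av_mask[idx]
    na_ <- sum(labs == 1L); nv <- sum(labs == 2L)
    s$av_label <- if (na_ > nv) "artery" else if (nv > na_) "vein"
    else "unknown"
    s
  })
  graph
}
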