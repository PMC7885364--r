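# Independent oracles. None of these share code with the package geometry:
# the rasterizer classifies cell centers by point-to-segment distance, the
# reachability oracle runs Dijkstra on a densely subdivided graph.

# logical cell-center mask of the union of segments dilated by w
.raster_mask <- function(segs, w, cell) {
  segs <- matrix(segs, ncol = 4)
  xr <- range(c(segs[, 1], segs[, 3])) + c(-w - cell, w + cell)
  yr <- range(c(segs[, 2], segs[, 4])) + c(-w - cell, w + cell)
  xs <- seq(xr[1] + cell / 2, xr[2], by = cell)
  ys <- seq(yr[1] + cell / 2, yr[2], by = cell)
  inside <- matrix(FALSE, length(xs), length(ys))
  for (k in seq_len(nrow(segs))) {
    dx <- segs[k, 3] - segs[k, 1]; dy <- segs[k, 4] - segs[k, 2]
    l2 <- dx^2 + dy^2
    px <- outer(xs - segs[k, 1], rep(1, length(ys)))
    py <- outer(rep(1, length(xs)), ys - segs[k, 2])
    t <- if (l2 > 0) pmin(1, pmax(0, (px * dx + py * dy) / l2)) else 0
    d2 <- (px - t * dx)^2 + (py - t * dy)^2
    inside <- inside | (d2 <= w^2)
  }
  list(inside = inside, xs = xs, ys = ys, cell = cell)
}

# area of the union of segments dilated by w (cell-center counting)
raster_buffer_area <- function(segs, w, cell = 0.5) {
  m <- .raster_mask(segs, w, cell)
  sum(m$inside) * cell^2
}

# per-class areas of buffer-union ∩ axis-aligned rectangles
raster_class_areas <- function(segs, w, rects, cell = 0.5) {
  m <- .raster_mask(segs, w, cell)
  out <- numeric(0)
  for (k in seq_len(nrow(rects))) {
    inx <- m$xs >= rects$x0[k] & m$xs < rects$x1[k]
    iny <- m$ys >= rects$y0[k] & m$ys < rects$y1[k]
    a <- sum(m$inside[inx, iny]) * cell^2
    cl <- rects$class[k]
    out[cl] <- if (cl %in% names(out)) out[cl] + a else a
  }
  out
}

# total reachable network length within distance d of an origin node:
# Dijkstra on a graph whose edges are subdivided into `step`-long pieces
subdivision_reach_length <- function(nodes, edges, origin_node, d, step = 1) {
  n_sub <- pmax(1L, ceiling(edges$length / step))
  n_extra <- sum(n_sub - 1L)
  n_base <- nrow(nodes)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  next_extra <- n_base
  for (k in seq_len(nrow(edges))) {
    ns <- n_sub[k]
    chain <- c(match(edges$from[k], nodes$id),
               if (ns > 1L) next_extra + seq_len(ns - 1L),
               match(edges$to[k], nodes$id))
    next_extra <- next_extra + ns - 1L
    from <- c(from, chain[-length(chain)])
    to <- c(to, chain[-1L])
    wt <- c(wt, rep(edges$length[k] / ns, ns))
  }
  g <- igraph::make_empty_graph(n = n_base + n_extra, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  dist <- igraph::distances(g, v = match(origin_node, nodes$id))[1, ]
  tot <- 0
  for (k in seq_along(wt)) {
    du <- dist[from[k]]; dv <- dist[to[k]]; len <- wt[k]
    r1 <- if (is.finite(du) && d > du) min(len, d - du) else 0
    r2 <- if (is.finite(dv) && d > dv) min(len, d - dv) else 0
    tot <- tot + min(len, r1 + r2)
  }
  tot
}
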