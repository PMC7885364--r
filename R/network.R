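# Road network construction, residence snapping, network-distance
# reachability with exact edge cutting, and sausage buffers.

#' Construct a set of road segments
#'
#' @param geometry list of two-column coordinate matrices (planar meters),
#'   one polyline per segment, each with at least two vertices.
#' @param segment_id character or integer identifiers, unique.
#' @param accessible logical: may pedestrians/cyclists use the segment?
#'   Inaccessible roads (e.g. highways) are dropped when the network is
#'   built so that buffers only follow reachable streets.
#' @param crs optional CRS label carried along for provenance (no
#'   reprojection is performed; coordinates must already be planar meters).
#' @return An object of class `road_segments`.
#' @export
road_segments <- function(geometry, segment_id = seq_along(geometry),
                          accessible = TRUE, crs = NULL) {
  if (!is.list(geometry) || length(geometry) == 0L)
    stop("'geometry' must be a non-empty list of coordinate matrices")
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    if (ncol(g) != 2L || nrow(g) < 2L)
      stop("each segment needs a two-column matrix with >= 2 vertices")
    g
  })
  segment_id <- as.character(segment_id)
  if (anyDuplicated(segment_id)) stop("segment_id values must be unique")
  accessible <- rep_len(as.logical(accessible), length(geometry))
  assert_planar_coords(unlist(lapply(geometry, function(g) g[, 1])),
                       unlist(lapply(geometry, function(g) g[, 2])),
                       "road segment coordinates")
  len <- vapply(geometry, function(g) {
    sum(sqrt(rowSums((g[-1L, , drop = FALSE] - g[-nrow(g), , drop = FALSE])^2)))
  }, numeric(1))
  structure(list(segment_id = segment_id, geometry = geometry,
                 accessible = accessible, length_m = len, crs = crs),
            class = "road_segments")
}

#' @export
print.road_segments <- function(x, ...) {
  cat(sprintf("<road_segments> %d segments (%d accessible), total %.0f m\n",
              length(x$segment_id), sum(x$accessible), sum(x$length_m)))
  invisible(x)
}

# single-linkage merge of endpoints within `tol`; returns integer cluster ids
.merge_points <- function(xy, tol) {
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  if (tol <= 0) tol <- 1e-12
  kx <- floor(xy[, 1] / tol)
  ky <- floor(xy[, 2] / tol)
  # candidate pairs: points sharing a bucket or an adjacent bucket
  key <- paste(kx, ky)
  pairs_i <- integer(0); pairs_j <- integer(0)
  bucket <- split(seq_len(n), key)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (nm in names(bucket)) assign(nm, bucket[[nm]], envir = lookup)
  for (idx in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      nb <- get0(paste(kx[idx] + dx, ky[idx] + dy), envir = lookup)
      if (is.null(nb)) next
      nb <- nb[nb > idx]
      if (!length(nb)) next
      d2 <- (xy[nb, 1] - xy[idx, 1])^2 + (xy[nb, 2] - xy[idx, 2])^2
      hit <- nb[d2 <= tol^2]
      if (length(hit)) {
        pairs_i <- c(pairs_i, rep.int(idx, length(hit)))
        pairs_j <- c(pairs_j, hit)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(pairs_i))
    g <- igraph::add_edges(g, rbind(pairs_i, pairs_j))
  igraph::components(g)$membership
}

#' Build the accessible road network
#'
#' Drops segments not accessible to pedestrians/cyclists, merges segment
#' endpoints within `snap_tolerance_m` into shared nodes (topology repair),
#' and assembles the weighted graph used for network-distance reachability.
#'
#' @param segments a [road_segments()] object, or a list of such objects
#'   (all must share one CRS).
#' @param snap_tolerance_m node-merge tolerance in meters (default 0.01 m:
#'   repairs digitization jitter without bridging distinct roads).
#' @return An object of class `road_network` with elements `nodes`
#'   (data.frame: id, x, y), `edges` (data.frame: segment_id, from, to,
#'   length_m plus a list column `geometry`), and the `igraph` graph.
#' @export
build_network <- function(segments, snap_tolerance_m = 0.01) {
  if (is.list(segments) && !inherits(segments, "road_segments")) {
    crss <- unique(vapply(segments, function(s)
      if (is.null(s$crs)) NA_character_ else s$crs, character(1)))
    crss <- crss[!is.na(crss)]
    if (length(crss) > 1L)
      stop("segments mix coordinate reference systems: ",
           paste(crss, collapse = ", "))
    segments <- road_segments(
      geometry = unlist(lapply(segments, `[[`, "geometry"), recursive = FALSE),
      segment_id = unlist(lapply(segments, `[[`, "segment_id")),
      accessible = unlist(lapply(segments, `[[`, "accessible")),
      crs = if (length(crss)) crss else NULL)
  }
  keep <- segments$accessible
  if (!any(keep))
    stop("no accessible segments: cannot build a pedestrian/cyclist network")
  geom <- segments$geometry[keep]
  sid <- segments$segment_id[keep]
  len <- segments$length_m[keep]

  ends <- do.call(rbind, lapply(geom, function(g) g[c(1L, nrow(g)), ]))
  memb <- .merge_points(ends, snap_tolerance_m)
  n_nodes <- max(memb)
  nx <- tapply(ends[, 1], memb, mean)
  ny <- tapply(ends[, 2], memb, mean)
  nodes <- data.frame(id = seq_len(n_nodes),
                      x = as.numeric(nx), y = as.numeric(ny))
  from <- memb[seq(1L, by = 2L, length.out = length(geom))]
  to <- memb[seq(2L, by = 2L, length.out = length(geom))]
  edges <- data.frame(segment_id = sid, from = from, to = to, length_m = len)
  edges$geometry <- geom

  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- len
  igraph::E(g)$segment_id <- sid

  # flat sub-segment table for fast point snapping
  sub <- lapply(seq_along(geom), function(i) {
    p <- geom[[i]]
    ns <- nrow(p) - 1L
    sl <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-(ns + 1L), , drop = FALSE])^2))
    cbind(edge = i, x0 = p[-(ns + 1L), 1], y0 = p[-(ns + 1L), 2],
          x1 = p[-1L, 1], y1 = p[-1L, 2], len = sl,
          cum0 = cumsum(c(0, sl))[seq_len(ns)])
  })
  sub <- do.call(rbind, sub)

  structure(list(nodes = nodes, edges = edges, graph = g, subsegments = sub,
                 crs = segments$crs, snap_tolerance_m = snap_tolerance_m),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, total length %.0f m\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m)))
  invisible(x)
}

#' Snap a point to the nearest location on the network
#'
#' @param point numeric length-2 (x, y) in the network's CRS.
#' @param net a [build_network()] result.
#' @param max_snap_m maximum allowed snap distance; farther points raise an
#'   error of class `lumrewb_unlocatable` carrying the distance (these
#'   residences are reported and excluded downstream, mirroring the
#'   exclusion of ungeocodable addresses).
#' @return An object of class `network_location`: edge index, offset in
#'   meters from the edge's `from` node, the source and snapped points and
#'   the snap distance. Ties are broken towards the lowest `segment_id`.
#' @export
snap_to_network <- function(point, net, max_snap_m = 100) {
  stopifnot(inherits(net, "road_network"), length(point) == 2L)
  s <- net$subsegments
  dx <- s[, "x1"] - s[, "x0"]
  dy <- s[, "y1"] - s[, "y0"]
  l2 <- dx * dx + dy * dy
  t <- ((point[1] - s[, "x0"]) * dx + (point[2] - s[, "y0"]) * dy) /
    pmax(l2, 1e-18)
  t <- pmin(1, pmax(0, t))
  px <- s[, "x0"] + t * dx
  py <- s[, "y0"] + t * dy
  d <- sqrt((point[1] - px)^2 + (point[2] - py)^2)
  dmin <- min(d)
  if (dmin > max_snap_m) {
    cond <- structure(
      class = c("lumrewb_unlocatable", "error", "condition"),
      list(message = sprintf(
        "unlocatable residence: nearest road is %.1f m away (max_snap_m = %g)",
        dmin, max_snap_m), call = sys.call(), distance_m = dmin))
    stop(cond)
  }
  cand <- which(d <= dmin + 1e-9)
  # deterministic tie-break: lowest segment_id, then smallest offset
  sid <- net$edges$segment_id[s[cand, "edge"]]
  off <- s[cand, "cum0"] + t[cand] * s[cand, "len"]
  ord <- order(sid, off)
  k <- cand[ord[1L]]
  edge <- s[k, "edge"]
  structure(list(edge = as.integer(edge),
                 segment_id = net$edges$segment_id[edge],
                 offset_m = as.numeric(s[k, "cum0"] + t[k] * s[k, "len"]),
                 source_point = as.numeric(point),
                 snapped_point = c(px[k], py[k]),
                 snap_distance_m = as.numeric(d[k])),
            class = "network_location")
}

# interpolate points along a polyline at arc-length positions s0..s1
.cut_polyline <- function(p, s0, s1) {
  ns <- nrow(p) - 1L
  sl <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-(ns + 1L), , drop = FALSE])^2))
  cum <- cumsum(c(0, sl))
  total <- cum[ns + 1L]
  s0 <- max(0, min(s0, total)); s1 <- max(0, min(s1, total))
  if (s1 - s0 <= 1e-9) return(NULL)
  interp <- function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), ns)
    f <- if (sl[i] > 0) (s - cum[i]) / sl[i] else 0
    p[i, ] + f * (p[i + 1L, ] - p[i, ])
  }
  inner <- which(cum > s0 + 1e-9 & cum < s1 - 1e-9)
  pts <- rbind(interp(s0),
               if (length(inner)) p[inner, , drop = FALSE],
               interp(s1))
  pts
}

# union of numeric intervals given as 2-col matrix
.union_intervals <- function(iv) {
  iv <- iv[iv[, 2] - iv[, 1] > 1e-9, , drop = FALSE]
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    k <- nrow(out)
    if (iv[i, 1] <= out[k, 2] + 1e-9) out[k, 2] <- max(out[k, 2], iv[i, 2])
    else out <- rbind(out, iv[i, ])
  }
  out
}

#' Network-reachable edge portions within distance d of an origin
#'
#' Single-source shortest paths from the snapped origin with exact edge
#' cutting: an edge traversed partially is cut at the point whose network
#' distance from the origin equals `d` (linear interpolation along the
#' polyline), rather than selecting whole edges. The origin's own edge is
#' walked bidirectionally from the origin offset.
#'
#' @param net a [build_network()] result.
#' @param origin a [snap_to_network()] result.
#' @param d network distance in meters, `>= 0`.
#' @return Object of class `reachable_edges`: list of polyline pieces
#'   (two-column matrices) with attributes `total_length_m` and `origin`.
#' @export
reachable_subnetwork <- function(net, origin, d) {
  stopifnot(inherits(net, "road_network"), inherits(origin, "network_location"),
            is.numeric(d), d >= 0)
  pieces <- list()
  total <- 0
  if (d > 0) {
    e0 <- origin$edge
    u0 <- net$edges$from[e0]; v0 <- net$edges$to[e0]
    len0 <- net$edges$length_m[e0]
    o <- origin$offset_m
    du <- as.numeric(igraph::distances(net$graph, v = u0)[1, ])
    dv <- as.numeric(igraph::distances(net$graph, v = v0)[1, ])
    # network distance origin -> node k, leaving via either endpoint
    dk <- pmin(o + du, (len0 - o) + dv)
    for (i in seq_len(nrow(net$edges))) {
      u <- net$edges$from[i]; v <- net$edges$to[i]
      len <- net$edges$length_m[i]
      iv <- matrix(numeric(0), ncol = 2L)
      if (is.finite(dk[u]) && d > dk[u])
        iv <- rbind(iv, c(0, min(len, d - dk[u])))
      if (is.finite(dk[v]) && d > dk[v])
        iv <- rbind(iv, c(max(0, len - (d - dk[v])), len))
      if (i == e0) iv <- rbind(iv, c(max(0, o - d), min(len, o + d)))
      iv <- .union_intervals(iv)
      if (nrow(iv) == 0L) next
      for (r in seq_len(nrow(iv))) {
        cut <- .cut_polyline(net$edges$geometry[[i]], iv[r, 1], iv[r, 2])
        if (!is.null(cut)) {
          pieces[[length(pieces) + 1L]] <- cut
          total <- total + (iv[r, 2] - iv[r, 1])
        }
      }
    }
  }
  structure(pieces, total_length_m = total, origin = origin,
            network_distance_m = d, class = "reachable_edges")
}

#' Sausage network buffer around a snapped origin
#'
#' Dilates the network-reachable edge portions by the corridor half-width
#' `w` with round caps and joins, unions the result (overlaps counted
#' once) and computes its exact area. An empty reachable set (d = 0 or an
#' isolated origin) degenerates to a disk of radius `w` around the snapped
#' point and is flagged `degenerate` so downstream can exclude it.
#'
#' @param reachable a [reachable_subnetwork()] result.
#' @param w corridor half-width in meters (default 25, the standard sausage
#'   buffer line radius).
#' @param arc_segments circle-approximation fineness, see [disk_ring()].
#' @return Object of class `sausage_buffer`: rings, `area_m2`,
#'   `network_distance_m`, `corridor_halfwidth_m`, `origin`, `degenerate`.
#' @export
sausage_buffer <- function(reachable, w = 25, arc_segments = 24L) {
  stopifnot(inherits(reachable, "reachable_edges"), w > 0)
  origin <- attr(reachable, "origin")
  degenerate <- length(reachable) == 0L
  rings <- if (degenerate) {
    list(disk_ring(origin$snapped_point[1], origin$snapped_point[2], w,
                   arc_segments))
  } else {
    polyline_capsules(reachable, w, arc_segments)
  }
  structure(list(rings = rings,
                 area_m2 = rings_union_area(rings),
                 network_distance_m = attr(reachable, "network_distance_m"),
                 corridor_halfwidth_m = w,
                 origin = origin,
                 degenerate = degenerate),
            class = "sausage_buffer")
}

#' @export
print.sausage_buffer <- function(x, ...) {
  cat(sprintf(
    "<sausage_buffer> d = %g m, w = %g m, area = %.1f m^2%s\n",
    x$network_distance_m, x$corridor_halfwidth_m, x$area_m2,
    if (x$degenerate) " (degenerate: disk around origin)" else ""))
  invisible(x)
}

#' Convenience: snap, reach and buffer in one call
#'
#' @inheritParams snap_to_network
#' @inheritParams reachable_subnetwork
#' @inheritParams sausage_buffer
#' @param d network buffer size in meters.
#' @export
network_buffer <- function(point, net, d, w = 25, max_snap_m = 100,
                           arc_segments = 24L) {
  loc <- snap_to_network(point, net, max_snap_m)
  sausage_buffer(reachable_subnetwork(net, loc, d), w, arc_segments)
}
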