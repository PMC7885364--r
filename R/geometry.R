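# Planar geometry primitives: capsule (buffered segment) rings and exact
# overlay areas via the C++ slab-scanline engine.

#' @useDynLib lumrewb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Polygon ring approximating a disk
#'
#' @param cx,cy center coordinates (meters).
#' @param r radius (meters).
#' @param arc_segments number of chords per semicircle; the full circle is
#'   an inscribed `2 * arc_segments`-gon (relative area error about
#'   `1 - sin(t)/t` with `t = pi/arc_segments`; < 0.3% for the default 24).
#' @return A closed ring as a two-column matrix (not repeating the first
#'   vertex).
#' @keywords internal
disk_ring <- function(cx, cy, r, arc_segments = 24L) {
  th <- seq(0, 2 * pi, length.out = 2L * arc_segments + 1L)[-(2L * arc_segments + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Capsule ring: a straight segment dilated by half-width w with round caps
#' @keywords internal
capsule_ring <- function(x0, y0, x1, y1, w, arc_segments = 24L) {
  dx <- x1 - x0
  dy <- y1 - y0
  len <- sqrt(dx * dx + dy * dy)
  if (len < 1e-9) return(disk_ring(x0, y0, w, arc_segments))
  phi <- atan2(dy, dx)
  th1 <- seq(phi - pi / 2, phi + pi / 2, length.out = arc_segments + 1L)
  th2 <- seq(phi + pi / 2, phi + 3 * pi / 2, length.out = arc_segments + 1L)
  rbind(
    cbind(x1 + w * cos(th1), y1 + w * sin(th1)), # cap around far end
    cbind(x0 + w * cos(th2), y0 + w * sin(th2))  # cap around near end
  )
}

#' Dilate polylines into capsule rings (one per sub-segment)
#'
#' Round joins arise from the union of the per-segment round caps, the
#' standard sausage-buffer construction.
#'
#' @param lines list of two-column coordinate matrices (polylines).
#' @param w corridor half-width in meters.
#' @param arc_segments chords per semicircle, see [disk_ring()].
#' @return list of rings.
#' @keywords internal
polyline_capsules <- function(lines, w, arc_segments = 24L) {
  rings <- list()
  for (ln in lines) {
    if (is.null(dim(ln))) ln <- matrix(ln, ncol = 2L, byrow = TRUE)
    n <- nrow(ln)
    if (n == 1L) {
      rings[[length(rings) + 1L]] <- disk_ring(ln[1, 1], ln[1, 2], w, arc_segments)
      next
    }
    for (i in seq_len(n - 1L)) {
      seg_len <- sqrt(sum((ln[i + 1L, ] - ln[i, ])^2))
      if (seg_len < 1e-9 && n > 2L) next
      rings[[length(rings) + 1L]] <-
        capsule_ring(ln[i, 1], ln[i, 2], ln[i + 1L, 1], ln[i + 1L, 2], w, arc_segments)
    }
  }
  rings
}

.flatten_rings <- function(rings) {
  if (length(rings) == 0L) {
    return(list(x = numeric(0), y = numeric(0), len = integer(0)))
  }
  list(
    x = unlist(lapply(rings, function(r) r[, 1]), use.names = FALSE),
    y = unlist(lapply(rings, function(r) r[, 2]), use.names = FALSE),
    len = vapply(rings, nrow, integer(1))
  )
}

#' Exact overlay areas between a ring union and a collection of shapes
#'
#' @param rings_a list of rings (two-column matrices); interpreted as the
#'   union of their interiors (overlaps counted once).
#' @param shapes_b list of shapes; each shape is a list of rings, itself a
#'   union. May be empty.
#' @return list with `area_a` (area of the union of `rings_a`) and `area_b`,
#'   a numeric vector with the area of the intersection of each shape with
#'   the `rings_a` union.
#' @keywords internal
overlay_areas <- function(rings_a, shapes_b = list()) {
  a <- .flatten_rings(rings_a)
  b_rings <- list()
  b_shape <- integer(0)
  for (i in seq_along(shapes_b)) {
    sh <- shapes_b[[i]]
    if (is.matrix(sh)) sh <- list(sh)
    for (r in sh) {
      b_rings[[length(b_rings) + 1L]] <- r
      b_shape <- c(b_shape, i - 1L)
    }
  }
  b <- .flatten_rings(b_rings)
  res <- overlay_areas_cpp(a$x, a$y, a$len, b$x, b$y, b$len, b_shape,
                           length(shapes_b))
  list(area_a = res$area_a, area_b = as.numeric(res$area_b))
}

#' Area of a union of polygon rings
#' @keywords internal
rings_union_area <- function(rings) overlay_areas(rings)$area_a

.ring_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) range(r[, 1])))
  ys <- unlist(lapply(rings, function(r) range(r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Reject coordinates that look geographic (degrees)
#'
#' All distances in the pipeline are metric; a projected planar CRS in
#' meters (e.g. RD New, EPSG:28992) is required. Coordinates whose
#' magnitudes all fit inside the longitude/latitude range are almost surely
#' degrees and are refused.
#' @keywords internal
assert_planar_coords <- function(x, y, what = "coordinates") {
  if (length(x) == 0L) return(invisible(TRUE))
  # lon/lat magnitudes AND a sub-degree extent: meters-scale data of < 2 m
  # extent is nonsensical, degree-scale study areas always look like this
  extent <- max(diff(range(x, na.rm = TRUE)), diff(range(y, na.rm = TRUE)))
  if (max(abs(x), na.rm = TRUE) <= 360 && max(abs(y), na.rm = TRUE) <= 90 &&
      extent <= 2) {
    stop(sprintf(paste0(
      "%s look geographic (degrees): values lie within [-360, 360] x ",
      "[-90, 90] with a sub-degree extent. Provide a projected planar CRS ",
      "in meters (e.g. EPSG:28992)."), what), call. = FALSE)
  }
  invisible(TRUE)
}
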