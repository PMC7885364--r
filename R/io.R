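# Plain-text IO: GeoJSON for vector layers (roads, parcels, buffers),
# CSV for tables, YAML for run configuration. Coordinates are planar
# meters throughout; geographic (degree) input is refused.

#' Read road segments from GeoJSON
#'
#' Accepts LineString and MultiLineString features. The accessibility
#' attribute name is configurable (YAML config `fields.accessible`);
#' absent attributes default to accessible.
#'
#' @param path GeoJSON file.
#' @param accessible_field property holding the pedestrian/cyclist
#'   accessibility flag.
#' @param id_field property holding segment identifiers (default: feature
#'   order).
#' @param crs CRS label to attach (GeoJSON itself is assumed planar).
#' @return a [road_segments()] object.
#' @export
read_roads_geojson <- function(path, accessible_field = "accessible",
                               id_field = NULL, crs = NULL) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  geoms <- list(); acc <- logical(0); ids <- character(0)
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    gtype <- f$geometry$type
    lines <- switch(gtype,
      LineString = list(f$geometry$coordinates),
      MultiLineString = f$geometry$coordinates,
      stop("unsupported geometry type for roads: ", gtype))
    a <- f$properties[[accessible_field]]
    a <- if (is.null(a)) TRUE else isTRUE(a) || identical(a, 1L) ||
      identical(a, 1) || identical(tolower(as.character(a)), "true")
    id0 <- if (is.null(id_field)) as.character(k)
           else as.character(f$properties[[id_field]])
    for (li in seq_along(lines)) {
      m <- do.call(rbind, lapply(lines[[li]], function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      geoms[[length(geoms) + 1L]] <- m
      acc <- c(acc, a)
      ids <- c(ids, if (length(lines) > 1L) paste0(id0, ".", li) else id0)
    }
  }
  road_segments(geoms, segment_id = ids, accessible = acc, crs = crs)
}

.ring_to_coords <- function(r) {
  r <- rbind(r, r[1, ]) # close the ring
  lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
}

#' Write road segments to GeoJSON
#' @param segments a [road_segments()] object.
#' @param path output file.
#' @export
write_roads_geojson <- function(segments, path) {
  feats <- lapply(seq_along(segments$segment_id), function(k) {
    m <- segments$geometry[[k]]
    list(type = "Feature",
         properties = list(segment_id = segments$segment_id[k],
                           accessible = segments$accessible[k],
                           length_m = segments$length_m[k]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)), function(i)
                           c(m[i, 1], m[i, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read land-use parcels from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; interior rings (holes) are
#' not supported by the overlay engine and are rejected.
#'
#' @param path GeoJSON file.
#' @param class_field property holding the land-use class.
#' @param year_field optional property holding the snapshot year (else
#'   pass `valid_year`).
#' @param valid_year snapshot year when not stored per feature.
#' @param scheme class scheme, default the 11-class scheme.
#' @param class_map optional named character vector mapping raw attribute
#'   values onto scheme classes (YAML config `class_map`).
#' @return a [land_parcels()] object.
#' @export
read_parcels_geojson <- function(path, class_field = "class",
                                 year_field = NULL, valid_year = NA,
                                 scheme = lum_default_scheme(),
                                 class_map = NULL) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  geoms <- list(); cls <- character(0); ids <- character(0)
  yr <- valid_year
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    gtype <- f$geometry$type
    polys <- switch(gtype,
      Polygon = list(f$geometry$coordinates),
      MultiPolygon = f$geometry$coordinates,
      stop("unsupported geometry type for parcels: ", gtype))
    rings <- list()
    for (pg in polys) {
      if (length(pg) > 1L)
        stop("polygon holes (interior rings) are not supported")
      m <- do.call(rbind, lapply(pg[[1]], function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      rings[[length(rings) + 1L]] <- m
    }
    cl <- as.character(f$properties[[class_field]])
    if (!is.null(class_map) && cl %in% names(class_map)) cl <- class_map[[cl]]
    cls <- c(cls, cl)
    ids <- c(ids, if (!is.null(f$properties$parcel_id))
      as.character(f$properties$parcel_id) else as.character(k))
    geoms[[length(geoms) + 1L]] <- rings
    if (!is.null(year_field) && !is.null(f$properties[[year_field]]))
      yr <- as.integer(f$properties[[year_field]])
  }
  land_parcels(geoms, cls, parcel_id = ids, valid_year = yr, scheme = scheme)
}

#' Write land-use parcels to GeoJSON
#' @param parcels a [land_parcels()] object.
#' @param path output file.
#' @export
write_parcels_geojson <- function(parcels, path) {
  feats <- lapply(seq_along(parcels$parcel_id), function(k) {
    rings <- parcels$geometry[[k]]
    list(type = "Feature",
         properties = list(parcel_id = parcels$parcel_id[k],
                           class = parcels$class_label[k],
                           valid_year = parcels$valid_year[1]),
         geometry = list(
           type = "MultiPolygon",
           coordinates = lapply(rings, function(r)
             list(.ring_to_coords(r)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a sausage buffer to GeoJSON for inspection
#'
#' The buffer is exported as the MultiPolygon of its (overlapping) capsule
#' parts; viewers render the union visually.
#' @param buffer a [sausage_buffer()].
#' @param path output file.
#' @export
write_buffer_geojson <- function(buffer, path) {
  feat <- list(type = "Feature",
               properties = list(
                 network_distance_m = buffer$network_distance_m,
                 corridor_halfwidth_m = buffer$corridor_halfwidth_m,
                 area_m2 = buffer$area_m2,
                 degenerate = buffer$degenerate),
               geometry = list(
                 type = "MultiPolygon",
                 coordinates = lapply(buffer$rings, function(r)
                   list(.ring_to_coords(r)))))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a generated world to disk in the formats the pipeline reads
#'
#' Roads and per-year parcel mosaics as GeoJSON, residences as CSV, the
#' generating configuration (ground truth) as JSON.
#' @param world a [generate_world()] result.
#' @param dir output directory (created).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roads_geojson(world$roads, file.path(dir, "roads.geojson"))
  for (yr in names(world$parcels_by_year))
    write_parcels_geojson(world$parcels_by_year[[yr]],
                          file.path(dir, sprintf("landuse_%s.geojson", yr)))
  utils::write.csv(world$residences, file.path(dir, "residences.csv"),
                   row.names = FALSE)
  # named vectors -> JSON objects (preserve names through serialization)
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  cfg <- namedify(unclass(world$config))
  jsonlite::write_json(cfg, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
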