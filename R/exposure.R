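# Land-use-mix exposure: clipping the land-use mosaic to a buffer,
# the entropy score, and linking exposure records to person-waves.

#' Default 11-class land-use scheme
#'
#' A configurable placeholder for an 11-class national land-use grouping
#' relevant to walking and cycling. Only the number of classes enters the
#' entropy denominator; the labels are free.
#' @export
lum_default_scheme <- function() {
  c("residential", "retail", "offices", "industrial", "public_services",
    "recreation_sports", "parks_green", "agriculture", "forest_nature",
    "water", "infrastructure")
}

#' Land-use parcels
#'
#' @param geometry list of polygon rings (two-column matrices) or lists of
#'   rings (multi-part parcels).
#' @param class_label land-use class per parcel; must be in `scheme`.
#' @param parcel_id identifiers.
#' @param valid_year calendar year of the land-use snapshot.
#' @param scheme character vector of all classes (default the 11-class
#'   scheme); its length is the `N` of the entropy formula.
#' @export
land_parcels <- function(geometry, class_label, parcel_id = seq_along(geometry),
                         valid_year = NA_integer_,
                         scheme = lum_default_scheme()) {
  geometry <- lapply(geometry, function(g) if (is.matrix(g)) list(g) else g)
  class_label <- as.character(class_label)
  bad <- setdiff(unique(class_label), scheme)
  if (length(bad))
    stop("class labels outside the configured scheme: ",
         paste(bad, collapse = ", "))
  xs <- unlist(lapply(geometry, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(geometry, function(p) lapply(p, function(r) r[, 2])))
  assert_planar_coords(xs, ys, "land-use parcel coordinates")
  bbox <- t(vapply(geometry, function(p) .ring_bbox(p), numeric(4)))
  structure(list(parcel_id = as.character(parcel_id), geometry = geometry,
                 class_label = class_label,
                 valid_year = as.integer(valid_year),
                 scheme = scheme, bbox = bbox),
            class = "land_parcels")
}

#' @export
print.land_parcels <- function(x, ...) {
  cat(sprintf("<land_parcels> %d parcels, %d/%d classes present, year %s\n",
              length(x$parcel_id), length(unique(x$class_label)),
              length(x$scheme),
              if (is.na(x$valid_year[1])) "?" else x$valid_year[1]))
  invisible(x)
}

#' Per-class area table for a buffer
#'
#' @param area_m2 named numeric vector of per-class areas (subset of the
#'   scheme); absent classes are filled with zero.
#' @param scheme all classes of the configured scheme; `N = length(scheme)`.
#' @return Object of class `class_area_table` with areas, shares `p_j`
#'   (summing to 1 over the covered area) and `N`.
#' @export
class_area_table <- function(area_m2, scheme = lum_default_scheme()) {
  if (is.null(names(area_m2)) && length(area_m2) == length(scheme))
    names(area_m2) <- scheme
  bad <- setdiff(names(area_m2), scheme)
  if (length(bad))
    stop("areas for classes outside the scheme: ", paste(bad, collapse = ", "))
  if (any(area_m2 < 0)) stop("negative class areas")
  a <- stats::setNames(numeric(length(scheme)), scheme)
  a[names(area_m2)] <- area_m2
  tot <- sum(a)
  structure(list(area_m2 = a,
                 share = if (tot > 0) a / tot else a * 0,
                 total_area_m2 = tot,
                 N = length(scheme), scheme = scheme),
            class = "class_area_table")
}

#' @export
print.class_area_table <- function(x, ...) {
  cat(sprintf("<class_area_table> N = %d classes, covered area %.1f m^2\n",
              x$N, x$total_area_m2))
  present <- x$share > 0
  if (any(present)) {
    df <- data.frame(class = x$scheme[present],
                     area_m2 = round(x$area_m2[present], 1),
                     share = round(x$share[present], 4))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Clip the land-use mosaic to a sausage buffer
#'
#' Intersects the buffer polygon with every parcel of the snapshot and
#' accumulates per-class areas. Shares are computed over the covered area;
#' data gaps (the mosaic should be wall-to-wall) above `gap_warn_frac` of
#' the buffer area trigger a warning, zero coverage is an error.
#'
#' @param buffer a [sausage_buffer()].
#' @param parcels a [land_parcels()] snapshot for the exposure year.
#' @param gap_warn_frac tolerated uncovered fraction before warning
#'   (default 0.05).
#' @return A [class_area_table()] with attributes `buffer_area_m2`,
#'   `covered_area_m2` and `gap_fraction`.
#' @export
clip_land_use <- function(buffer, parcels, gap_warn_frac = 0.05) {
  stopifnot(inherits(buffer, "sausage_buffer"), inherits(parcels, "land_parcels"))
  bb <- .ring_bbox(buffer$rings)
  cand <- which(parcels$bbox[, 3] >= bb["xmin"] & parcels$bbox[, 1] <= bb["xmax"] &
                parcels$bbox[, 4] >= bb["ymin"] & parcels$bbox[, 2] <= bb["ymax"])
  if (length(cand) == 0L)
    stop("no land-use coverage: no parcels intersect the buffer's extent")
  ov <- overlay_areas(buffer$rings, parcels$geometry[cand])
  areas <- tapply(ov$area_b, parcels$class_label[cand], sum)
  tab <- class_area_table(areas[areas > 0], scheme = parcels$scheme)
  covered <- sum(ov$area_b)
  if (covered <= 0)
    stop("no land-use coverage: parcels do not overlap the buffer")
  gap <- max(0, 1 - covered / ov$area_a)
  if (gap > gap_warn_frac)
    warning(sprintf(
      "land-use mosaic covers only %.1f%% of the buffer (gap %.1f%% > %.0f%%)",
      100 * (1 - gap), 100 * gap, 100 * gap_warn_frac))
  attr(tab, "buffer_area_m2") <- ov$area_a
  attr(tab, "covered_area_m2") <- covered
  attr(tab, "gap_fraction") <- gap
  tab
}

#' Land-use-mix entropy score
#'
#' Computes `LUM = -[ sum_j p_j ln(p_j) ] / ln(N)` over the N classes of
#' the configured scheme, with the convention `0 * ln(0) = 0`. N is the
#' scheme size (default 11), not the number of classes present in the
#' buffer, so scores are comparable across buffers and years. The score
#' lies in [0, 1]: 0 for a single class, 1 for a perfectly even mix.
#'
#' @param table a [class_area_table()], or a bare numeric vector of shares
#'   (then `N = length(table)`).
#' @return entropy score in `[0, 1]`.
#' @export
entropy_lum <- function(table) {
  if (inherits(table, "class_area_table")) {
    p <- table$share
    N <- table$N
    if (table$total_area_m2 <= 0)
      stop("entropy undefined: zero covered area")
  } else {
    p <- as.numeric(table)
    N <- length(p)
    if (any(p < 0)) stop("negative shares")
    s <- sum(p)
    if (s <= 0) stop("entropy undefined: shares sum to zero")
    p <- p / s
  }
  if (N < 2L) stop("entropy undefined for N < 2 classes")
  pos <- p > 0
  val <- -sum(p[pos] * log(p[pos])) / log(N)
  min(1, max(0, val))
}

#' Build exposure records for buffers against a yearly land-use snapshot
#'
#' @param buffers named list of [sausage_buffer()]s (one per person/
#'   residence) for a single buffer size.
#' @param parcels the [land_parcels()] snapshot of the exposure year.
#' @param person_id,wave_id identifiers recycled against `buffers`.
#' @return data.frame with person_id, wave_id, buffer_size_m,
#'   exposure_year, lum_entropy and lum_scaled (= 10 x entropy: the
#'   per-10%-of-mix scale on which model coefficients are reported).
#' @export
exposure_records <- function(buffers, parcels, person_id, wave_id) {
  stopifnot(length(buffers) == length(person_id))
  ent <- vapply(buffers, function(b)
    entropy_lum(clip_land_use(b, parcels)), numeric(1))
  data.frame(person_id = as.character(person_id),
             wave_id = rep_len(wave_id, length(buffers)),
             buffer_size_m = vapply(buffers, `[[`, numeric(1),
                                    "network_distance_m"),
             exposure_year = parcels$valid_year[1],
             lum_entropy = as.numeric(ent),
             lum_scaled = 10 * as.numeric(ent))
}

#' Link exposure records to person-waves
#'
#' Joins each person-wave row of the panel to its buffer-size-specific
#' exposure from the mapped exposure year, enforcing that exposure precedes
#' (or coincides with) outcome: `wave_to_year[wave] <= fieldwork_year`.
#' Rows lacking an exposure record (e.g. unlocatable residences) are
#' excluded with a count.
#'
#' @param panel data.frame with at least person_id, wave_id and
#'   fieldwork_year.
#' @param exposures data.frame as produced by [exposure_records()]
#'   (stacked over buffer sizes and years).
#' @param wave_to_year named vector mapping wave_id to exposure year.
#' @return panel with `lum_entropy_<size>` / `lum_scaled_<size>` columns
#'   per buffer size; attribute `n_excluded_no_exposure` counts dropped
#'   rows.
#' @export
link_exposure <- function(panel, exposures, wave_to_year) {
  waves <- unique(as.character(panel$wave_id))
  miss <- setdiff(waves, names(wave_to_year))
  if (length(miss))
    stop("configuration error: no exposure year mapped for wave(s) ",
         paste(miss, collapse = ", "))
  fy <- tapply(panel$fieldwork_year, as.character(panel$wave_id), max)
  late <- waves[as.numeric(wave_to_year[waves]) > as.numeric(fy[waves])]
  if (length(late))
    stop("configuration error: exposure year later than fieldwork year for ",
         "wave(s) ", paste(late, collapse = ", "),
         " (exposure must precede outcome)")
  out <- panel
  sizes <- sort(unique(exposures$buffer_size_m))
  for (sz in sizes) {
    ex <- exposures[exposures$buffer_size_m == sz &
                      exposures$exposure_year ==
                        as.numeric(wave_to_year[as.character(exposures$wave_id)]), ]
    key_p <- paste(out$person_id, out$wave_id)
    key_e <- paste(ex$person_id, ex$wave_id)
    i <- match(key_p, key_e)
    out[[sprintf("lum_entropy_%g", sz)]] <- ex$lum_entropy[i]
    out[[sprintf("lum_scaled_%g", sz)]] <- ex$lum_scaled[i]
  }
  cols <- sprintf("lum_scaled_%g", sizes)
  ok <- stats::complete.cases(out[, cols, drop = FALSE])
  n_excl <- sum(!ok)
  if (n_excl > 0)
    message(sprintf("link_exposure: excluded %d person-wave row(s) without %s",
                    n_excl, "exposure records"))
  out <- out[ok, , drop = FALSE]
  attr(out, "n_excluded_no_exposure") <- n_excl
  out
}
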