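# End-to-end orchestration: buffers -> exposure -> harmonize -> decompose
# -> fit -> pool, with exclusion accounting and a reproducible manifest.

#' Run configuration
#'
#' @param buffer_sizes_m network buffer sizes in meters (default
#'   500/1000/1600, the main exposure plus sensitivity sizes).
#' @param corridor_halfwidth_m sausage line-buffer radius (default 25 m).
#' @param snap_tolerance_m maximum residence snap distance (default 100 m;
#'   residences farther from any road are reported and excluded).
#' @param wave_to_year named mapping from wave_id to the exposure year
#'   (must precede or equal the wave's fieldwork year).
#' @param m number of imputations.
#' @param seed RNG seed for imputation.
#' @param outcomes outcome columns to model.
#' @param covariates adjustment covariates.
#' @param estimator `"REML"` or `"ML"`.
#' @param scheme land-use class scheme.
#' @param n_waves required waves for the non-mover sample.
#' @param paths optional named list of input paths (roads, landuse_<year>,
#'   panel, residences) for file-based runs.
#' @param output_dir where [run_pipeline()] writes results.
#' @return object of class `run_config`.
#' @export
run_config <- function(buffer_sizes_m = c(500, 1000, 1600),
                       corridor_halfwidth_m = 25,
                       snap_tolerance_m = 100,
                       wave_to_year = c("1" = 2003, "2" = 2010, "3" = 2013),
                       m = 5L, seed = 1L,
                       outcomes = c("walk_min_wk", "cycle_min_wk"),
                       covariates = c("sex", "education", "age",
                                      "marital_status", "income",
                                      "employment", "cohort_id"),
                       estimator = "REML",
                       scheme = lum_default_scheme(),
                       n_waves = 3L,
                       paths = NULL,
                       output_dir = NULL) {
  stopifnot(all(buffer_sizes_m > 0), !anyDuplicated(buffer_sizes_m),
            corridor_halfwidth_m > 0, m >= 1L)
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments; unknown keys are
#' rejected so typos surface early.
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$wave_to_year)) y$wave_to_year <- unlist(y$wave_to_year)
  if (!is.null(y$scheme)) y$scheme <- unlist(y$scheme)
  if (!is.null(y$covariates)) y$covariates <- unlist(y$covariates)
  if (!is.null(y$outcomes)) y$outcomes <- unlist(y$outcomes)
  if (!is.null(y$buffer_sizes_m)) y$buffer_sizes_m <- unlist(y$buffer_sizes_m)
  do.call(run_config, y)
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(structure(class = c("lumrewb_stage_error", "error", "condition"),
                   list(message = sprintf("[stage:%s] %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

#' Compute exposure records for every residence, wave and buffer size
#'
#' Snaps each person-wave residence to the accessible network, builds the
#' sausage buffers, clips the exposure-year mosaic and scores the entropy.
#' Unlocatable residences are excluded and counted. Buffers are reused
#' across waves for persons who did not move.
#'
#' @param net a [build_network()] result.
#' @param parcels_by_year named list of [land_parcels()] (names = years).
#' @param residences person-wave data.frame (person_id, wave_id, res_x,
#'   res_y).
#' @param config a [run_config()].
#' @return exposure data.frame (see [exposure_records()]); attribute
#'   `n_unlocatable` counts excluded person-waves.
#' @export
compute_exposures <- function(net, parcels_by_year, residences, config) {
  w2y <- config$wave_to_year
  miss <- setdiff(as.character(unique(residences$wave_id)), names(w2y))
  if (length(miss))
    stop("chronology error: no exposure year configured for wave(s) ",
         paste(miss, collapse = ", "))
  yrs <- as.character(w2y[as.character(residences$wave_id)])
  missing_years <- setdiff(unique(yrs), names(parcels_by_year))
  if (length(missing_years))
    stop("chronology error: no land-use snapshot for exposure year(s) ",
         paste(missing_years, collapse = ", "))

  # unique residence locations (movers contribute several)
  key <- paste(residences$person_id, round(residences$res_x, 3),
               round(residences$res_y, 3))
  uloc <- !duplicated(key)
  loc_tab <- residences[uloc, c("person_id", "res_x", "res_y")]
  loc_key <- key[uloc]

  snapped <- vector("list", nrow(loc_tab))
  unlocatable <- logical(nrow(loc_tab))
  for (i in seq_len(nrow(loc_tab))) {
    snapped[[i]] <- tryCatch(
      snap_to_network(c(loc_tab$res_x[i], loc_tab$res_y[i]), net,
                      config$snap_tolerance_m),
      lumrewb_unlocatable = function(e) NULL)
    unlocatable[i] <- is.null(snapped[[i]])
  }
  buf_cache <- new.env(parent = emptyenv())
  get_buffers <- function(i) { # all sizes for one location
    ck <- as.character(i)
    b <- get0(ck, envir = buf_cache)
    if (!is.null(b)) return(b)
    b <- lapply(config$buffer_sizes_m, function(d)
      sausage_buffer(reachable_subnetwork(net, snapped[[i]], d),
                     config$corridor_halfwidth_m))
    assign(ck, b, envir = buf_cache)
    b
  }
  out <- list()
  for (r in seq_len(nrow(residences))) {
    li <- match(key[r], loc_key)
    if (unlocatable[li]) next
    bufs <- get_buffers(li)
    yr <- yrs[r]
    parc <- parcels_by_year[[yr]]
    for (b in bufs) {
      ent <- entropy_lum(clip_land_use(b, parc))
      out[[length(out) + 1L]] <- data.frame(
        person_id = residences$person_id[r],
        wave_id = residences$wave_id[r],
        buffer_size_m = b$network_distance_m,
        exposure_year = as.integer(yr),
        lum_entropy = ent, lum_scaled = 10 * ent)
    }
  }
  res <- do.call(rbind, out)
  n_unloc <- sum(unlocatable[match(key, loc_key)])
  attr(res, "n_unlocatable") <- n_unloc
  if (n_unloc > 0)
    message(sprintf("compute_exposures: %d person-wave(s) unlocatable %s",
                    n_unloc, "(excluded)"))
  res
}

#' Harmonize instrument items to minutes/week in place
#'
#' Cohort A rows are scored with the SQUASH rules (median substitution per
#' wave and activity within cohort), cohort B rows with the LAPAQ rule.
#' @param panel generated or read panel with instrument item columns.
#' @return panel with walk_min_wk / cycle_min_wk columns filled.
#' @export
harmonize_outcomes <- function(panel) {
  for (act in c("walk", "cycle")) {
    ycol <- paste0(act, "_min_wk")
    is_a <- panel$cohort_id == "A"
    med <- squash_median(panel[[paste0("squash_min_per_day_", act)]],
                         panel[[paste0("squash_days_", act)]],
                         strata = list(wave = panel$wave_id))
    y <- rep(NA_real_, nrow(panel))
    y[is_a] <- squash_minutes_per_week(
      panel[[paste0("squash_days_", act)]][is_a],
      panel[[paste0("squash_min_per_day_", act)]][is_a],
      median_min_per_day = med[is_a])
    y[!is_a] <- lapaq_minutes_per_week(
      panel[[paste0("lapaq_sessions_", act)]][!is_a],
      panel[[paste0("lapaq_min_per_session_", act)]][!is_a])
    panel[[ycol]] <- y
  }
  panel
}

#' Run the full pipeline
#'
#' Stages: build network -> buffers + exposure -> harmonize outcomes ->
#' non-mover restriction -> imputation (per cohort) -> pooling -> exposure
#' linkage -> REWB fits pooled over imputations. Writes exposure CSV,
#' results CSV and a JSON manifest (seeds, m, package version, exclusion
#' accounting) when `config$output_dir` is set. Deterministic given config
#' and seed. Any stage failure halts with the stage name in the error.
#'
#' @param world a [generate_world()] result (or a list with `roads`,
#'   `parcels_by_year`, `residences`).
#' @param panel the person-wave panel (e.g. from [generate_panel()]).
#' @param config a [run_config()].
#' @return list: results (tidy table from [run_all_models()]), exposures,
#'   manifest.
#' @export
run_pipeline <- function(world, panel, config = run_config()) {
  t0 <- Sys.time()
  net <- .stage("network", build_network(world$roads))
  exposures <- .stage("exposure",
    compute_exposures(net, world$parcels_by_year,
                      panel[, c("person_id", "wave_id", "res_x", "res_y")],
                      config))
  panel <- .stage("harmonize", harmonize_outcomes(panel))
  n_persons_in <- length(unique(panel$person_id))
  panel_nm <- .stage("nonmovers",
                     suppressMessages(filter_nonmovers(panel,
                                                       n_waves = config$n_waves)))
  excl <- list(
    persons_in = n_persons_in,
    persons_incomplete = attr(panel_nm, "n_excluded_incomplete"),
    persons_moved = attr(panel_nm, "n_excluded_moved"),
    persons_kept = length(unique(panel_nm$person_id)))

  # impute per cohort first, then pool the completed datasets
  imputed <- .stage("impute", {
    coh <- split(panel_nm, panel_nm$cohort_id)
    per_cohort <- lapply(seq_along(coh), function(i)
      impute_missing(coh[[i]], m = config$m, seed = config$seed + i))
    lapply(seq_len(config$m), function(j) {
      parts <- lapply(per_cohort, `[[`, j)
      Reduce(pool_cohorts, parts)
    })
  })
  linked <- .stage("link", lapply(imputed, function(d)
    suppressMessages(link_exposure(d, exposures, config$wave_to_year))))
  excl$rows_no_exposure <- attr(linked[[1]], "n_excluded_no_exposure")

  results <- .stage("fit",
    run_all_models(linked, outcomes = config$outcomes,
                   buffer_sizes = config$buffer_sizes_m,
                   covariates = config$covariates,
                   estimator = config$estimator))

  manifest <- list(
    seed = config$seed, m = config$m,
    buffer_sizes_m = config$buffer_sizes_m,
    corridor_halfwidth_m = config$corridor_halfwidth_m,
    wave_to_year = as.list(config$wave_to_year),
    exclusions = excl,
    n_unlocatable_person_waves = attr(exposures, "n_unlocatable"),
    package_version = as.character(utils::packageVersion("lumrewb")),
    r_version = R.version.string,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(exposures,
                     file.path(config$output_dir, "exposures.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = results, exposures = exposures, manifest = manifest,
       panel_nonmovers = panel_nm)
}
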