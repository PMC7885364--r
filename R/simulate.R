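# Synthetic world generator: grid road network with inaccessible edges, an
# evolving 11-class land-use mosaic, residences, and a 3-wave panel drawn
# from the REWB outcome equation with known coefficients.

#' Configuration of the synthetic world
#'
#' Defaults state the emulated study conditions: a three-wave panel of
#' about 2000 pooled persons, cross-sectional mean land-use-mix entropy
#' around 0.30 in 1000-m buffers, roughly 44% of person-observations with
#' an entropy change (mean decrease about -0.05, mean increase about +0.03
#' on the entropy scale, increases about twice as frequent as decreases),
#' true within effect -5 and between effect +10 minutes/week per 10% of
#' mix for walking, random-intercept variance 2500 and residual variance
#' 10000. `dominant_share` and `change_prob` are calibration presets fixed
#' once against those targets (see the methods vignette).
#'
#' @param grid_n number of grid cells per side of the road network.
#' @param spacing_m grid spacing in meters (must exceed twice the corridor
#'   half-width).
#' @param inaccessible_frac fraction of road edges closed to pedestrians
#'   and cyclists (highways); sampled so the accessible network stays
#'   connected.
#' @param scheme land-use class labels (default 11 generic classes).
#' @param dominant_class,dominant_share the mosaic draws each parcel as the
#'   dominant class with probability `dominant_share`, else uniformly among
#'   the remaining classes (calibrated to mean buffer entropy ~ 0.30).
#' @param change_prob per-block probability of redevelopment at each wave
#'   transition (calibrated to ~44% changed person-observations).
#' @param change_block_cells side length, in parcels, of the square
#'   redevelopment blocks: a changing block turns into a single new class,
#'   emulating concentrated land-use change rather than parcel-level
#'   speckle.
#' @param change_dominant_share dominant-class probability when a parcel
#'   redraws its class (lower than `dominant_share`, so changes diversify
#'   slightly more often than they homogenize).
#' @param n_persons_a,n_persons_b persons per cohort (SQUASH cohort A,
#'   LAPAQ cohort B).
#' @param waves number of panel waves.
#' @param fieldwork_years survey years per wave.
#' @param exposure_years land-use snapshot years, each preceding its wave.
#' @param buffer_sizes_m,corridor_halfwidth_m,snap_tolerance_m buffer
#'   geometry parameters.
#' @param beta0,beta1_within,beta2_between named (walk, cycle) truths of the
#'   outcome equation, in minutes/week (exposure on the per-10%-LUM scale).
#' @param var_v,var_eps random-intercept and residual variances.
#' @param covariate_effects list of additive covariate effects (minutes/
#'   week) applied to both outcomes.
#' @param missing_rates MCAR covariate missingness rates.
#' @param mover_frac fraction of persons relocating between waves.
#' @param n_unlocatable persons deliberately placed beyond the snap
#'   tolerance (error-path preset).
#' @param seed RNG seed (mandatory: the generated world is a function of
#'   the seed alone).
#' @return validated object of class `world_config`.
#' @export
world_config <- function(grid_n = 40L, spacing_m = 100,
                         inaccessible_frac = 0.10,
                         scheme = lum_default_scheme(),
                         dominant_class = "residential",
                         dominant_share = 0.86,
                         change_prob = 0.033,
                         change_block_cells = 2L,
                         change_dominant_share = 0.60,
                         n_persons_a = 1100L, n_persons_b = 900L,
                         waves = 3L,
                         fieldwork_years = c(2004, 2011, 2014),
                         exposure_years = c(2003, 2010, 2013),
                         buffer_sizes_m = c(500, 1000, 1600),
                         corridor_halfwidth_m = 25,
                         snap_tolerance_m = 100,
                         beta0 = c(walk = 280, cycle = 260),
                         beta1_within = c(walk = -5, cycle = -5),
                         beta2_between = c(walk = 10, cycle = 5),
                         var_v = 2500, var_eps = 10000,
                         covariate_effects = list(
                           sex_male = 10, education_per_level = 5,
                           age_per_year = -0.5, employment = 10,
                           income_per_level = 5,
                           marital = c(married = 0, never_married = -10,
                                       divorced = -5, widowed = -15),
                           cohort_b = -20),
                         missing_rates = c(income = 0.10, employment = 0.05,
                                           education = 0.04, bmi = 0.05),
                         mover_frac = 0.05,
                         n_unlocatable = 0L,
                         seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(grid_n >= 2L, spacing_m > 2 * corridor_halfwidth_m,
            inaccessible_frac >= 0, inaccessible_frac < 1,
            dominant_share > 0, dominant_share <= 1,
            change_prob >= 0, change_prob <= 1,
            mover_frac >= 0, mover_frac <= 1,
            length(scheme) >= 2L,
            length(fieldwork_years) == waves,
            length(exposure_years) == waves,
            all(exposure_years <= fieldwork_years),
            all(buffer_sizes_m > 0), !anyDuplicated(buffer_sizes_m),
            all(missing_rates >= 0 & missing_rates <= 1))
  if (!dominant_class %in% scheme)
    stop("dominant_class must be one of the scheme classes")
  structure(as.list(environment()), class = "world_config")
}

.draw_classes <- function(n, scheme, dominant, q) {
  others <- setdiff(scheme, dominant)
  ifelse(stats::runif(n) < q, dominant,
         others[sample.int(length(others), n, replace = TRUE)])
}

#' Generate the synthetic world: roads, evolving mosaic, residences
#'
#' @param config a [world_config()].
#' @return object of class `lum_world`: `roads` ([road_segments()],
#'   including the inaccessible ones), `parcels_by_year` (named list of
#'   [land_parcels()]), `residences` (person-wave data.frame with mover
#'   flags) and the config.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  g <- config$grid_n
  s <- config$spacing_m
  L <- g * s

  # grid road segments
  node_xy <- function(i, j) c((i - 1L) * s, (j - 1L) * s)
  geoms <- list(); ends <- list()
  for (j in seq_len(g + 1L)) for (i in seq_len(g)) { # horizontal
    geoms[[length(geoms) + 1L]] <- rbind(node_xy(i, j), node_xy(i + 1L, j))
  }
  for (i in seq_len(g + 1L)) for (j in seq_len(g)) { # vertical
    geoms[[length(geoms) + 1L]] <- rbind(node_xy(i, j), node_xy(i, j + 1L))
  }
  n_edges <- length(geoms)
  accessible <- rep(TRUE, n_edges)
  target_closed <- round(config$inaccessible_frac * n_edges)
  if (target_closed > 0) {
    # greedy closure preserving connectivity of the accessible subgraph
    ep <- t(vapply(geoms, function(gm) c(gm[1, ], gm[2, ]), numeric(4)))
    key <- function(x, y) paste(round(x / s), round(y / s))
    vid <- match(key(c(ep[, 1], ep[, 3]), c(ep[, 2], ep[, 4])),
                 unique(key(c(ep[, 1], ep[, 3]), c(ep[, 2], ep[, 4]))))
    from <- vid[seq_len(n_edges)]; to <- vid[n_edges + seq_len(n_edges)]
    gr <- igraph::make_empty_graph(n = max(vid), directed = FALSE)
    gr <- igraph::add_edges(gr, rbind(from, to))
    closed <- 0L
    for (e in sample.int(n_edges)) {
      if (closed >= target_closed) break
      gr2 <- igraph::delete_edges(
        gr, igraph::get_edge_ids(gr, c(from[e], to[e])))
      if (igraph::is_connected(gr2)) {
        gr <- gr2
        accessible[e] <- FALSE
        closed <- closed + 1L
      }
    }
  }
  roads <- road_segments(geoms, segment_id = sprintf("s%04d", seq_len(n_edges)),
                         accessible = accessible, crs = "synthetic:meters")

  # wall-to-wall parcel mosaic, padded one cell beyond the road extent so
  # buffers at the boundary stay covered
  cells <- expand.grid(i = 0:(g + 1L), j = 0:(g + 1L))
  x0 <- (cells$i - 1L) * s
  y0 <- (cells$j - 1L) * s
  n_par <- nrow(cells)
  rects <- lapply(seq_len(n_par), function(k)
    cbind(c(x0[k], x0[k] + s, x0[k] + s, x0[k]),
          c(y0[k], y0[k], y0[k] + s, y0[k] + s)))
  cls <- .draw_classes(n_par, config$scheme, config$dominant_class,
                       config$dominant_share)
  # redevelopment operates on square blocks of parcels: a changing block
  # becomes a single new class
  bc <- config$change_block_cells
  block <- paste(cells$i %/% bc, cells$j %/% bc)
  block_ids <- unique(block)
  parcels_by_year <- list()
  for (w in seq_len(config$waves)) {
    if (w > 1L) {
      ch_blocks <- block_ids[stats::runif(length(block_ids)) <
                               config$change_prob]
      for (b in ch_blocks) {
        cls[block == b] <- .draw_classes(1L, config$scheme,
                                         config$dominant_class,
                                         config$change_dominant_share)
      }
    }
    yr <- config$exposure_years[w]
    parcels_by_year[[as.character(yr)]] <-
      land_parcels(rects, cls, parcel_id = sprintf("p%05d", seq_len(n_par)),
                   valid_year = yr, scheme = config$scheme)
  }

  # residences: random point on a random accessible edge, jittered off the
  # carriageway; movers get a fresh draw from their mover wave onward
  n_tot <- config$n_persons_a + config$n_persons_b
  acc_idx <- which(accessible)
  draw_residence <- function(n) {
    e <- sample(acc_idx, n, replace = TRUE)
    t <- stats::runif(n)
    side <- sample(c(-1, 1), n, replace = TRUE)
    off <- stats::runif(n, 5, 20)
    p <- t(vapply(seq_len(n), function(k) {
      gm <- geoms[[e[k]]]
      d <- gm[2, ] - gm[1, ]
      len <- sqrt(sum(d^2))
      nrm <- c(-d[2], d[1]) / len
      gm[1, ] + t[k] * d + side[k] * off[k] * nrm
    }, numeric(2)))
    p
  }
  base <- draw_residence(n_tot)
  person_id <- c(sprintf("A%05d", seq_len(config$n_persons_a)),
                 sprintf("B%05d", seq_len(config$n_persons_b)))
  mover <- stats::runif(n_tot) < config$mover_frac
  mover_wave <- ifelse(mover, sample(2:config$waves, n_tot, replace = TRUE),
                       NA_integer_)
  new_home <- draw_residence(n_tot)
  if (config$n_unlocatable > 0L) {
    far <- L + 2 * config$snap_tolerance_m + 100
    idx <- seq_len(min(config$n_unlocatable, n_tot))
    base[idx, 1] <- far + seq_along(idx) * 10
    base[idx, 2] <- far
    mover[idx] <- FALSE
  }
  res <- do.call(rbind, lapply(seq_len(config$waves), function(w) {
    use_new <- mover & !is.na(mover_wave) & w >= mover_wave
    data.frame(person_id = person_id,
               cohort_id = rep(c("A", "B"),
                               c(config$n_persons_a, config$n_persons_b)),
               wave_id = w,
               fieldwork_year = config$fieldwork_years[w],
               res_x = ifelse(use_new, new_home[, 1], base[, 1]),
               res_y = ifelse(use_new, new_home[, 2], base[, 2]),
               moved_since_previous_wave =
                 mover & !is.na(mover_wave) & w == mover_wave)
  }))
  structure(list(roads = roads, parcels_by_year = parcels_by_year,
                 residences = res, config = config),
            class = "lum_world")
}

#' @export
print.lum_world <- function(x, ...) {
  cat(sprintf(
    "<lum_world> %d road segments (%.0f%% closed), %d parcels x %d years, %d persons x %d waves\n",
    length(x$roads$segment_id), 100 * mean(!x$roads$accessible),
    length(x$parcels_by_year[[1]]$parcel_id), length(x$parcels_by_year),
    length(unique(x$residences$person_id)), x$config$waves))
  invisible(x)
}

# analytic exposure process on the lum_scaled (0..10) scale: baseline level
# plus wave-transition jumps matching the change-frequency/magnitude world
.analytic_exposures <- function(config, person_id, cohort_id) {
  n <- length(person_id)
  base <- pmin(10, pmax(0, stats::rnorm(n, 3.0, 0.65)))
  waves <- config$waves
  x <- matrix(0, n, waves)
  x[, 1] <- base
  p_change <- 0.664        # per-transition change probability (=> ~44%
  p_increase <- 0.6624     # of all person-observations changed)
  for (w in 2:waves) {
    ch <- stats::runif(n) < p_change
    up <- stats::runif(n) < p_increase
    delta <- ifelse(up, stats::rexp(n, 1 / 0.3), -stats::rexp(n, 1 / 0.5))
    x[, w] <- pmin(10, pmax(0, x[, w - 1L] + ifelse(ch, delta, 0)))
  }
  x
}

#' Generate the three-wave panel with known ground truth
#'
#' Outcomes follow the REWB equation: for each person i and wave t,
#' `PA_it = beta0 + beta1W (x_it - xbar_i) + beta2B xbar_i + covariate
#' effects + v_i + eps_it`, with `v_i ~ N(0, var_v)`,
#' `eps_it ~ N(0, var_eps)`, floored at zero (the truncated fraction is
#' recorded; defaults keep it below 1%). Exposure is either taken from
#' computed records or drawn from the analytic change process. Instrument
#' items (SQUASH for cohort A, LAPAQ for cohort B) are derived from the
#' outcome so harmonization can be exercised end-to-end; covariate
#' missingness is applied MCAR at the configured rates.
#'
#' @param config a [world_config()].
#' @param exposures optional data.frame (person_id, wave_id, lum_scaled)
#'   from the geometry pipeline; when NULL the analytic process is used.
#' @param residences optional person-wave residence table (from
#'   [generate_world()]); when NULL synthetic coordinates are attached.
#' @return panel data.frame with attribute `ground_truth`.
#' @export
generate_panel <- function(config, exposures = NULL, residences = NULL) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed + 1L)
  n_a <- config$n_persons_a; n_b <- config$n_persons_b
  n <- n_a + n_b
  waves <- config$waves
  person_id <- c(sprintf("A%05d", seq_len(n_a)), sprintf("B%05d", seq_len(n_b)))
  cohort_id <- rep(c("A", "B"), c(n_a, n_b))

  # time-invariant covariates
  sex <- factor(ifelse(stats::runif(n) < 0.46, "male", "female"),
                levels = c("female", "male"))
  edu_lv <- c("low", "lower_mid", "upper_mid", "high")
  education <- factor(edu_lv[sample.int(4, n, TRUE,
                                        prob = c(0.31, 0.18, 0.22, 0.29))],
                      levels = edu_lv, ordered = TRUE)
  age0 <- ifelse(cohort_id == "A",
                 stats::rnorm(n, 56, 12), stats::rnorm(n, 68, 8))
  age0 <- pmin(93, pmax(26, age0))
  v_i <- stats::rnorm(n, 0, sqrt(config$var_v))

  # exposure matrix on the lum_scaled scale
  if (is.null(exposures)) {
    x <- .analytic_exposures(config, person_id, cohort_id)
  } else {
    x <- matrix(NA_real_, n, waves)
    i <- match(paste(exposures$person_id, exposures$wave_id),
               paste(rep(person_id, waves), rep(seq_len(waves), each = n)))
    x[i] <- exposures$lum_scaled
    if (anyNA(x))
      stop("supplied exposures do not cover every person-wave")
  }
  xbar <- rowMeans(x)
  xdev <- x - xbar

  ce <- config$covariate_effects
  mar_lv <- names(ce$marital)
  inc_lv <- c("lt1200", "1200_1800", "1800_2600", "gt2600")
  srh_lv <- c("poor", "fair", "good", "very_good", "excellent")

  rows <- vector("list", waves)
  year_gap <- c(0, diff(config$fieldwork_years))
  marital <- factor(mar_lv[sample.int(4, n, TRUE,
                                      prob = c(0.75, 0.08, 0.06, 0.11))],
                    levels = mar_lv)
  income <- factor(inc_lv[sample.int(4, n, TRUE,
                                     prob = c(0.12, 0.27, 0.40, 0.21))],
                   levels = inc_lv, ordered = TRUE)
  smoking <- stats::runif(n) < 0.25
  bmi <- stats::rnorm(n, 26, 4)
  srh <- factor(srh_lv[sample.int(5, n, TRUE,
                                  prob = c(0.05, 0.15, 0.45, 0.25, 0.10))],
                levels = srh_lv, ordered = TRUE)
  age <- age0
  for (w in seq_len(waves)) {
    age <- age + year_gap[w]
    employment <- stats::runif(n) < stats::plogis(2.5 - 0.06 * (age - 40))
    if (w > 1L) { # sticky time-varying covariates
      flip <- stats::runif(n) < 0.08
      income[flip] <- factor(inc_lv[sample.int(4, sum(flip), TRUE)],
                             levels = inc_lv, ordered = TRUE)
      flip <- stats::runif(n) < 0.04
      marital[flip] <- factor(mar_lv[sample.int(4, sum(flip), TRUE)],
                              levels = mar_lv)
    }
    lin <- ce$sex_male * (sex == "male") +
      ce$education_per_level * (as.integer(education) - 1L) +
      ce$age_per_year * (age - 60) +
      ce$employment * employment +
      ce$income_per_level * (as.integer(income) - 1L) +
      ce$marital[as.integer(marital)] +
      ce$cohort_b * (cohort_id == "B")
    eps_w <- stats::rnorm(n, 0, sqrt(config$var_eps))
    eps_c <- stats::rnorm(n, 0, sqrt(config$var_eps))
    walk <- config$beta0[["walk"]] + config$beta1_within[["walk"]] * xdev[, w] +
      config$beta2_between[["walk"]] * xbar + lin + v_i + eps_w
    cycle <- config$beta0[["cycle"]] + config$beta1_within[["cycle"]] * xdev[, w] +
      config$beta2_between[["cycle"]] * xbar + lin + v_i + eps_c
    rows[[w]] <- data.frame(
      person_id = person_id, cohort_id = cohort_id, wave_id = w,
      fieldwork_year = config$fieldwork_years[w],
      sex = sex, education = education, age = age,
      marital_status = marital, income = income, employment = employment,
      self_rated_health = srh, smoking = smoking, bmi = bmi,
      walk_min_wk_true = walk, cycle_min_wk_true = cycle,
      lum_scaled_true = x[, w])
  }
  panel <- do.call(rbind, rows)
  trunc_frac <- mean(c(panel$walk_min_wk_true, panel$cycle_min_wk_true) < 0)
  panel$walk_min_wk <- pmax(0, panel$walk_min_wk_true)
  panel$cycle_min_wk <- pmax(0, panel$cycle_min_wk_true)
  panel$walk_min_wk_true <- NULL
  panel$cycle_min_wk_true <- NULL

  # instrument items derived from the harmonized outcome
  is_a <- panel$cohort_id == "A"
  for (act in c("walk", "cycle")) {
    y <- panel[[paste0(act, "_min_wk")]]
    days <- sample(1:7, nrow(panel), replace = TRUE)
    mins <- y / days
    sess <- sample(1:14, nrow(panel), replace = TRUE)
    mps <- 2 * y / sess
    panel[[paste0("squash_days_", act)]] <- ifelse(is_a, days, NA)
    panel[[paste0("squash_min_per_day_", act)]] <- ifelse(is_a, mins, NA)
    panel[[paste0("lapaq_sessions_", act)]] <- ifelse(is_a, NA, sess)
    panel[[paste0("lapaq_min_per_session_", act)]] <- ifelse(is_a, NA, mps)
  }
  # SQUASH item nonresponse exercising the scoring rules (cohort A only)
  for (act in c("walk", "cycle")) {
    dcol <- paste0("squash_days_", act)
    mcol <- paste0("squash_min_per_day_", act)
    drop_d <- is_a & stats::runif(nrow(panel)) < 0.05
    drop_m <- is_a & !drop_d & stats::runif(nrow(panel)) < 0.05
    panel[[dcol]][drop_d] <- NA
    panel[[mcol]][drop_m] <- NA
  }

  # residence coordinates and mover flags
  if (is.null(residences)) {
    ext <- config$grid_n * config$spacing_m
    bx <- stats::runif(n, 0, ext); by <- stats::runif(n, 0, ext)
    mover <- stats::runif(n) < config$mover_frac
    mwave <- ifelse(mover, sample(2:waves, n, TRUE), NA_integer_)
    nx <- stats::runif(n, 0, ext); ny <- stats::runif(n, 0, ext)
    i <- match(panel$person_id, person_id)
    use_new <- mover[i] & !is.na(mwave[i]) & panel$wave_id >= mwave[i]
    panel$res_x <- ifelse(use_new, nx[i], bx[i])
    panel$res_y <- ifelse(use_new, ny[i], by[i])
    panel$moved_since_previous_wave <-
      mover[i] & !is.na(mwave[i]) & panel$wave_id == mwave[i]
  } else {
    i <- match(paste(panel$person_id, panel$wave_id),
               paste(residences$person_id, residences$wave_id))
    panel$res_x <- residences$res_x[i]
    panel$res_y <- residences$res_y[i]
    panel$moved_since_previous_wave <- residences$moved_since_previous_wave[i]
  }

  # MCAR covariate missingness
  mr <- config$missing_rates
  for (v in names(mr)) {
    if (v %in% names(panel) && mr[[v]] > 0)
      panel[[v]][stats::runif(nrow(panel)) < mr[[v]]] <- NA
  }

  attr(panel, "ground_truth") <- list(
    beta0 = config$beta0, beta1_within = config$beta1_within,
    beta2_between = config$beta2_between,
    covariate_effects = ce, var_v = config$var_v, var_eps = config$var_eps,
    xbar = stats::setNames(xbar, person_id), x_dev = xdev, v_i = v_i,
    truncation_fraction = trunc_frac)
  if (trunc_frac > 0.01)
    warning(sprintf("%.1f%% of outcome draws were floored at 0; %s",
                    100 * trunc_frac,
                    "linear-recovery checks assume < 1%"))
  panel
}

#' Generate world and panel together (analytic exposures)
#'
#' @param config a [world_config()].
#' @return list with `world` and `panel`.
#' @export
simulate_study <- function(config) {
  world <- generate_world(config)
  panel <- generate_panel(config, residences = world$residences)
  list(world = world, panel = panel)
}

#' Entropy-change summary over linked exposure records
#'
#' For every person and buffer size, compares each wave's entropy with the
#' previous wave's. The changed fraction is reported over all
#' person-observations (first waves count as unchanged), the convention
#' under which roughly 44% of person-observations change.
#'
#' @param exposures data.frame with person_id, wave_id, buffer_size_m,
#'   lum_entropy.
#' @return data.frame per buffer size: n_obs, frac_changed, mean_decrease,
#'   mean_increase.
#' @export
exposure_change_stats <- function(exposures) {
  out <- lapply(split(exposures, exposures$buffer_size_m), function(d) {
    d <- d[order(d$person_id, d$wave_id), ]
    prev <- c(NA, d$lum_entropy[-nrow(d)])
    same <- c(FALSE, d$person_id[-nrow(d)] == d$person_id[-1])
    diffv <- ifelse(same, d$lum_entropy - prev, NA)
    changed <- !is.na(diffv) & abs(diffv) > 1e-12
    data.frame(buffer_size_m = d$buffer_size_m[1], n_obs = nrow(d),
               frac_changed = sum(changed) / nrow(d),
               mean_decrease = mean(diffv[changed & diffv < 0]),
               mean_increase = mean(diffv[changed & diffv > 0]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
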