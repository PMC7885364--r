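# Outcome harmonization to average minutes/week, non-mover restriction and
# cohort pooling.

#' SQUASH walking/cycling items to average minutes per week
#'
#' Scoring rules: a complete item contributes `days_per_week x
#' minutes_per_day`; respondents who reported a duration but omitted days
#' per week are assumed to have been active for at least 1 day (duration
#' counted once); respondents who reported days but no duration get the
#' cohort median minutes per day substituted; an all-missing item stays
#' missing. A directly reported weekly duration takes precedence.
#'
#' @param days_per_week integer 0..7, may be NA.
#' @param minutes_per_day nonnegative minutes, may be NA.
#' @param minutes_per_week_direct optional directly reported minutes/week.
#' @param median_min_per_day the substitution median, computed over
#'   respondents with complete items (see [squash_median()]); typically per
#'   wave and activity.
#' @return numeric minutes/week (NA where underivable).
#' @export
squash_minutes_per_week <- function(days_per_week, minutes_per_day,
                                    minutes_per_week_direct = NULL,
                                    median_min_per_day = NA_real_) {
  n <- max(length(days_per_week), length(minutes_per_day),
           length(minutes_per_week_direct))
  d <- rep_len(as.numeric(days_per_week), n)
  mi <- rep_len(as.numeric(minutes_per_day), n)
  dir <- if (is.null(minutes_per_week_direct)) rep(NA_real_, n)
         else rep_len(as.numeric(minutes_per_week_direct), n)
  med <- rep_len(as.numeric(median_min_per_day), n)
  if (any(d < 0 | d > 7, na.rm = TRUE))
    stop("days_per_week must be in 0..7")
  if (any(mi < 0, na.rm = TRUE) || any(dir < 0, na.rm = TRUE))
    stop("negative minutes are invalid")
  out <- rep(NA_real_, n)
  complete <- !is.na(d) & !is.na(mi)
  out[complete] <- d[complete] * mi[complete]
  only_dur <- is.na(d) & !is.na(mi)
  out[only_dur] <- mi[only_dur]               # assume active >= 1 day
  only_days <- !is.na(d) & is.na(mi)
  out[only_days] <- d[only_days] * med[only_days]
  use_dir <- !is.na(dir)
  out[use_dir] <- dir[use_dir]
  out
}

#' Cohort median minutes/day for SQUASH substitution
#'
#' Median over respondents with complete items, stratified by the given
#' grouping (default per wave and activity; set `strata = NULL` for the
#' unstratified reading).
#'
#' @param minutes_per_day,days_per_week item vectors.
#' @param strata optional list/data.frame of stratification variables.
#' @return numeric vector aligned with the input (the stratum median for
#'   every row), or a scalar when unstratified.
#' @export
squash_median <- function(minutes_per_day, days_per_week, strata = NULL) {
  complete <- !is.na(minutes_per_day) & !is.na(days_per_week)
  if (is.null(strata))
    return(stats::median(minutes_per_day[complete]))
  key <- interaction(as.data.frame(strata), drop = FALSE)
  med <- tapply(minutes_per_day[complete], key[complete], stats::median)
  as.numeric(med[as.character(key)])
}

#' LAPAQ walking/cycling items to average minutes per week
#'
#' The questionnaire asks frequency and duration over the last 2 weeks, so
#' minutes/week is `sessions x minutes_per_session / 2`.
#'
#' @param sessions_last_2wk nonnegative session count.
#' @param minutes_per_session nonnegative minutes.
#' @export
lapaq_minutes_per_week <- function(sessions_last_2wk, minutes_per_session) {
  s <- as.numeric(sessions_last_2wk)
  m <- as.numeric(minutes_per_session)
  if (any(s < 0, na.rm = TRUE) || any(m < 0, na.rm = TRUE))
    stop("negative LAPAQ items are invalid")
  s * m / 2
}

#' Restrict a panel to complete-case non-movers
#'
#' Keeps persons who (i) appear in all `n_waves` waves and (ii) whose
#' residence coordinates are identical across waves within `tol_m` meters
#' (absorbing geocoding jitter), so that within-person exposure changes
#' reflect environmental change rather than relocation.
#'
#' @param panel data.frame with person_id, wave_id, res_x, res_y.
#' @param n_waves required number of waves (default 3).
#' @param tol_m residence-identity tolerance in meters (default 1).
#' @return panel subset; attributes `n_excluded_incomplete` and
#'   `n_excluded_moved` count persons removed by each rule.
#' @export
filter_nonmovers <- function(panel, n_waves = 3L, tol_m = 1) {
  stopifnot(all(c("person_id", "wave_id", "res_x", "res_y") %in% names(panel)))
  sp <- split(seq_len(nrow(panel)), panel$person_id)
  complete <- vapply(sp, function(i)
    length(unique(panel$wave_id[i])) >= n_waves, logical(1))
  moved <- vapply(sp, function(i) {
    dx <- diff(range(panel$res_x[i]))
    dy <- diff(range(panel$res_y[i]))
    sqrt(dx^2 + dy^2) > tol_m
  }, logical(1))
  keep_person <- complete & !moved
  out <- panel[panel$person_id %in% names(sp)[keep_person], , drop = FALSE]
  attr(out, "n_excluded_incomplete") <- sum(!complete)
  attr(out, "n_excluded_moved") <- sum(complete & moved)
  message(sprintf(
    "filter_nonmovers: kept %d of %d persons (%d with < %d waves, %d moved)",
    sum(keep_person), length(sp), sum(!complete), n_waves,
    sum(complete & moved)))
  out
}

#' Pool two harmonized cohort panels
#'
#' Concatenates the panels, keeping `cohort_id` as a covariate (models are
#' adjusted for study). Both panels must already share the harmonized
#' schema, including identical level sets for the shared 4-level income
#' coding and other factors.
#'
#' @param panel_a,panel_b harmonized panels.
#' @return pooled data.frame.
#' @export
pool_cohorts <- function(panel_a, panel_b) {
  if (nrow(panel_b) == 0L) {
    warning("second panel is empty; pooled panel equals the first")
    return(panel_a)
  }
  miss_a <- setdiff(names(panel_b), names(panel_a))
  miss_b <- setdiff(names(panel_a), names(panel_b))
  if (length(miss_a) || length(miss_b))
    stop("schema mismatch between cohorts; missing in A: [",
         paste(miss_a, collapse = ", "), "], missing in B: [",
         paste(miss_b, collapse = ", "), "]")
  panel_b <- panel_b[names(panel_a)]
  for (v in names(panel_a)) {
    if (is.factor(panel_a[[v]]) || is.factor(panel_b[[v]])) {
      # compare declared level sets (not observed values): both cohorts must
      # already share the harmonized coding
      la <- if (is.factor(panel_a[[v]])) levels(panel_a[[v]])
            else unique(as.character(panel_a[[v]]))
      lb <- if (is.factor(panel_b[[v]])) levels(panel_b[[v]])
            else unique(as.character(panel_b[[v]]))
      if (length(setdiff(lb, la) ) > 0)
        stop(sprintf(
          "conflicting coding for '%s': levels [%s] vs [%s]; map both cohorts %s",
          v, paste(la, collapse = ","), paste(lb, collapse = ","),
          "onto the shared coding first"))
      ord <- is.ordered(panel_a[[v]]) || is.ordered(panel_b[[v]])
      panel_a[[v]] <- factor(panel_a[[v]], levels = la, ordered = ord)
      panel_b[[v]] <- factor(panel_b[[v]], levels = la, ordered = ord)
    }
  }
  if (anyDuplicated(c(unique(panel_a$person_id), unique(panel_b$person_id))))
    stop("person_id values collide across cohorts; prefix them per cohort")
  rbind(panel_a, panel_b)
}
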