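# Random-effects within-between (REWB / hybrid / Mundlak) model:
# decomposition of a time-varying exposure into person means and
# deviations, random-intercept REML fit, Wald inference, Rubin pooling
# across imputations, and the full results grid.

#' Decompose a time-varying exposure into person means and deviations
#'
#' Adds `<prefix>_bar` (the arithmetic mean of the exposure over the
#' person's observed waves: the between component) and `<prefix>_dev`
#' (the deviation from that mean: the within component) to the data.
#' By construction deviations sum to zero within person and
#' `dev + bar` reconstructs the exposure exactly.
#'
#' @param data data.frame.
#' @param exposure name of the exposure column (e.g. `"lum_scaled_1000"`).
#' @param id name of the person identifier column.
#' @param prefix prefix for the new columns (default `"x"`).
#' @export
decompose_within_between <- function(data, exposure, id = "person_id",
                                     prefix = "x") {
  stopifnot(exposure %in% names(data), id %in% names(data))
  x <- data[[exposure]]
  if (anyNA(x)) stop("exposure contains missing values; link/exclude first")
  xbar <- stats::ave(x, data[[id]], FUN = mean)
  data[[paste0(prefix, "_bar")]] <- xbar
  data[[paste0(prefix, "_dev")]] <- x - xbar
  data
}

#' Fit a random-effects within-between model
#'
#' Fits the random-intercept linear mixed model
#' `y_it = b0 + b1W (x_it - xbar_i) + b2B xbar_i + b3 Z_i + b4 g_it +
#' (v_i + e_it)` by REML (default), where the time-varying exposure enters
#' through its person-mean (`b2B`, the between effect) and the deviation
#' from it (`b1W`, the within effect). A random person intercept accounts
#' for the dependence of repeated measurements. Confidence intervals and
#' p-values are Wald normal approximations, matching symmetric 95% CIs.
#'
#' @param formula model formula of outcome on covariates, e.g.
#'   `walk_min_wk ~ sex + education + age + marital_status + income +
#'   employment + cohort_id`; the exposure terms are added automatically.
#' @param data data.frame (one row per person-wave).
#' @param exposure name of the time-varying exposure column, on the scale
#'   coefficients should be reported in (use `lum_scaled_*` so effects read
#'   as minutes/week per 10% change in land-use mix).
#' @param id person identifier column (default `"person_id"`).
#' @param estimator `"REML"` (default) or `"ML"`.
#' @param wave_effect add a wave fixed effect (off by default: the model
#'   equation carries none; time-varying age absorbs secular trend).
#' @return object of class `rewb`.
#' @export
rewb <- function(formula, data, exposure, id = "person_id",
                 estimator = c("REML", "ML"), wave_effect = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(formula, "formula"))
  data <- decompose_within_between(data, exposure, id)
  data$.id <- factor(data[[id]])

  waves_per_person <- table(data$.id)
  if (sum(waves_per_person >= 2L) < 2L)
    stop("need at least 2 persons with at least 2 waves to separate ",
         "within from between variation")
  if (all(abs(data$x_dev) < 1e-12))
    stop("within-person exposure variance is exactly zero for all persons; ",
         "the within coefficient is inestimable")

  rhs <- attr(stats::terms(formula), "term.labels")
  lhs <- all.vars(formula[[2]])
  rhs_full <- c("x_dev", "x_bar", rhs, if (wave_effect) "factor(wave_id)")
  fml_fixed <- stats::reformulate(rhs_full, response = lhs)

  mm <- stats::model.matrix(fml_fixed, data = data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("rank-deficient fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }

  fml <- stats::update(fml_fixed, . ~ . + (1 | .id))
  fit <- lme4::lmer(fml, data = data, REML = (estimator == "REML"))

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_v <- vc$vcov[vc$grp == ".id"]
  var_eps <- vc$vcov[vc$grp == "Residual"]
  boundary <- var_v < 1e-8 * var_eps
  if (boundary)
    warning("random-intercept variance estimated at the boundary (~0); ",
            "estimates reported as-is")
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- cbind(beta - stats::qnorm(0.975) * se, beta + stats::qnorm(0.975) * se)
  colnames(ci) <- c("2.5 %", "97.5 %")

  structure(list(
    coefficients = beta, se = se, ci = ci, p = p,
    var_v = var_v, var_eps = var_eps,
    n_persons = nlevels(data$.id), n_obs = nrow(data),
    estimator = estimator, exposure = exposure, outcome = lhs,
    boundary = boundary, formula = fml, fit = fit,
    call = match.call()), class = "rewb")
}

#' Backwards-compatible alias used in pipeline code
#' @inheritParams rewb
#' @export
fit_rewb <- function(formula, data, exposure, id = "person_id",
                     estimator = c("REML", "ML"), wave_effect = FALSE) {
  rewb(formula, data, exposure, id, estimator, wave_effect)
}

#' @export
print.rewb <- function(x, digits = 3, ...) {
  cat(sprintf("REWB random-intercept model (%s), outcome: %s\n",
              x$estimator, x$outcome))
  cat(sprintf("  %d persons, %d person-observations; exposure: %s\n",
              x$n_persons, x$n_obs, x$exposure))
  cat(sprintf("  within  (x_dev): %8.*f  [%.*f; %.*f]\n", digits,
              x$coefficients[["x_dev"]], digits, x$ci["x_dev", 1],
              digits, x$ci["x_dev", 2]))
  cat(sprintf("  between (x_bar): %8.*f  [%.*f; %.*f]\n", digits,
              x$coefficients[["x_bar"]], digits, x$ci["x_bar", 1],
              digits, x$ci["x_bar", 2]))
  cat(sprintf("  var(v_i) = %.*f, var(eps) = %.*f%s\n", digits, x$var_v,
              digits, x$var_eps,
              if (x$boundary) "  [boundary fit]" else ""))
  invisible(x)
}

#' @export
summary.rewb <- function(object, ...) {
  tab <- data.frame(beta = object$coefficients, se = object$se,
                    ci_low = object$ci[, 1], ci_high = object$ci[, 2],
                    p = object$p)
  structure(list(table = tab, var_v = object$var_v,
                 var_eps = object$var_eps, n_persons = object$n_persons,
                 n_obs = object$n_obs, outcome = object$outcome,
                 exposure = object$exposure, estimator = object$estimator,
                 boundary = object$boundary),
            class = "summary.rewb")
}

#' @export
print.summary.rewb <- function(x, digits = 3, ...) {
  cat(sprintf("REWB model (%s) of %s on %s\n", x$estimator, x$outcome,
              x$exposure))
  print(round(x$table, digits))
  cat(sprintf("Variance components: var(v_i) = %.3f, var(eps) = %.3f\n",
              x$var_v, x$var_eps))
  cat(sprintf("%d persons, %d person-observations\n", x$n_persons, x$n_obs))
  invisible(x)
}

#' @export
coef.rewb <- function(object, ...) object$coefficients

#' @export
vcov.rewb <- function(object, ...) as.matrix(stats::vcov(object$fit))

#' @export
confint.rewb <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.rewb <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.rewb <- function(object, ...) stats::residuals(object$fit, ...)

#' Pool REWB fits across multiply imputed datasets (Rubin's rules)
#'
#' Pooled estimate = mean of the m estimates; total variance = mean
#' within-imputation variance + (1 + 1/m) x between-imputation variance.
#' Intervals use the normal approximation by default; Barnard-Rubin
#' small-sample degrees of freedom are available behind a flag.
#'
#' @param results list of [rewb()] fits from identical specifications on
#'   the m completed datasets.
#' @param small_sample_df use Barnard-Rubin adjusted t df instead of the
#'   normal approximation.
#' @return object of class `rewb_pooled`.
#' @export
rubin_pool <- function(results, small_sample_df = FALSE) {
  if (inherits(results, "rewb")) results <- list(results)
  m <- length(results)
  stopifnot(m >= 1L)
  nm <- names(results[[1]]$coefficients)
  for (r in results) {
    if (!identical(names(r$coefficients), nm) ||
        !identical(r$outcome, results[[1]]$outcome) ||
        !identical(r$exposure, results[[1]]$exposure))
      stop("mismatched model specifications across imputations")
  }
  if (m == 1L)
    warning("pooling a single result; between-imputation variance is zero")
  est <- do.call(rbind, lapply(results, `[[`, "coefficients"))
  wi <- do.call(rbind, lapply(results, function(r) r$se^2))
  qbar <- colMeans(est)
  ubar <- colMeans(wi)
  b <- if (m > 1L) apply(est, 2L, stats::var) else 0 * qbar
  tvar <- ubar + (1 + 1 / m) * b
  se <- sqrt(tvar)
  if (small_sample_df && m > 1L) {
    # Barnard-Rubin: combine old-style df with complete-data df
    r <- (1 + 1 / m) * b / ubar
    df_old <- (m - 1) * (1 + 1 / r)^2
    df_com <- results[[1]]$n_obs - length(qbar)
    lam <- (1 + 1 / m) * b / tvar
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lam)
    df <- df_old * df_obs / (df_old + df_obs)
    df[!is.finite(df)] <- df_com
    q <- stats::qt(0.975, df)
    p <- 2 * stats::pt(-abs(qbar / se), df)
  } else {
    df <- rep(Inf, length(qbar))
    q <- stats::qnorm(0.975)
    p <- 2 * stats::pnorm(-abs(qbar / se))
  }
  ci <- cbind(qbar - q * se, qbar + q * se)
  colnames(ci) <- c("2.5 %", "97.5 %")
  structure(list(
    coefficients = qbar, se = se, ci = ci, p = p, m = m,
    within_var = ubar, between_var = b, total_var = tvar, df = df,
    var_v = mean(vapply(results, `[[`, numeric(1), "var_v")),
    var_eps = mean(vapply(results, `[[`, numeric(1), "var_eps")),
    n_persons = results[[1]]$n_persons, n_obs = results[[1]]$n_obs,
    outcome = results[[1]]$outcome, exposure = results[[1]]$exposure),
    class = "rewb_pooled")
}

#' @export
print.rewb_pooled <- function(x, digits = 3, ...) {
  cat(sprintf("Rubin-pooled REWB model (m = %d), outcome: %s\n", x$m,
              x$outcome))
  tab <- data.frame(beta = x$coefficients, se = x$se,
                    ci_low = x$ci[, 1], ci_high = x$ci[, 2], p = x$p)
  print(round(tab[c("x_dev", "x_bar"), ], digits))
  invisible(x)
}

#' @export
coef.rewb_pooled <- function(object, ...) object$coefficients

#' @export
confint.rewb_pooled <- function(object, parm, level = 0.95, ...) {
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Fit the full results grid: outcomes x buffer sizes, pooled over
#' imputations
#'
#' @param panels an `imputed_panels` object (or a single data.frame,
#'   treated as m = 1) whose datasets carry `lum_scaled_<size>` columns.
#' @param outcomes outcome columns to model.
#' @param buffer_sizes buffer sizes (meters) to model.
#' @param covariates character vector of adjustment covariates.
#' @param id person identifier column.
#' @param ... passed to [rewb()].
#' @return tidy data.frame with one row per outcome x buffer size x effect
#'   type (within/between): beta, se, ci_low, ci_high, p, status. Failed
#'   cells are marked `status = "failed: <reason>"` and the run continues.
#' @export
run_all_models <- function(panels,
                           outcomes = c("walk_min_wk", "cycle_min_wk"),
                           buffer_sizes = c(500, 1000, 1600),
                           covariates = c("sex", "education", "age",
                                          "marital_status", "income",
                                          "employment", "cohort_id"),
                           id = "person_id", ...) {
  if (is.data.frame(panels)) panels <- list(panels)
  covariates <- intersect(covariates, names(panels[[1]]))
  rows <- list()
  for (oc in outcomes) {
    for (sz in buffer_sizes) {
      expo <- sprintf("lum_scaled_%g", sz)
      cell <- tryCatch({
        if (!expo %in% names(panels[[1]]))
          stop("no exposure column ", expo)
        fml <- stats::reformulate(if (length(covariates)) covariates else "1",
                                  response = oc)
        fits <- lapply(panels, function(d)
          rewb(fml, data = d, exposure = expo, id = id, ...))
        pooled <- if (length(fits) > 1L) rubin_pool(fits)
                  else suppressWarnings(rubin_pool(fits))
        lapply(c(within = "x_dev", between = "x_bar"), function(term) {
          data.frame(outcome = oc, buffer_size = sz,
                     effect_type = if (term == "x_dev") "within" else "between",
                     beta = unname(pooled$coefficients[term]),
                     se = unname(pooled$se[term]),
                     ci_low = unname(pooled$ci[term, 1]),
                     ci_high = unname(pooled$ci[term, 2]),
                     p = unname(pooled$p[term]), status = "ok")
        })
      }, error = function(e) {
        lapply(c("within", "between"), function(et)
          data.frame(outcome = oc, buffer_size = sz, effect_type = et,
                     beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, p = NA_real_,
                     status = paste0("failed: ", conditionMessage(e))))
      })
      rows <- c(rows, cell)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
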