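# Multiple imputation of covariates by chained equations (no external
# imputation engine is assumed): predictive mean matching for continuous
# variables, binomial draws for binary, proportional-odds draws for
# ordered factors and one-vs-rest logit draws for nominal factors.

.default_impute_vars <- c("education", "income", "employment",
                          "marital_status", "self_rated_health", "smoking",
                          "bmi")
.default_predictors <- c("sex", "education", "age", "marital_status",
                         "income", "employment", "self_rated_health",
                         "smoking", "bmi")

.draw_pmm <- function(y_obs, pred_obs, pred_mis, k = 5L) {
  vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    donors <- order(d)[seq_len(min(k, length(d)))]
    y_obs[sample(donors, 1L)]
  }, y_obs[1])
}

# drop predictors that are constant or aliased on the observed rows, so
# small cohorts do not break polr/glm with rank-deficient designs
.prune_predictors <- function(data_obs, predictors) {
  keep <- predictors[vapply(predictors, function(v) {
    x <- data_obs[[v]]
    length(unique(x[!is.na(x)])) >= 2L
  }, logical(1))]
  if (length(keep) < 2L) return(keep)
  mm <- stats::model.matrix(stats::reformulate(keep), data = data_obs)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased_cols <- q$pivot[(q$rank + 1L):ncol(mm)]
    aliased_vars <- unique(attr(mm, "assign")[aliased_cols])
    aliased_vars <- aliased_vars[aliased_vars > 0]
    keep <- keep[-aliased_vars]
  }
  keep
}

.impute_one <- function(data, target, predictors) {
  mis <- is.na(data[[target]])
  obs <- !mis
  predictors <- .prune_predictors(data[obs, , drop = FALSE], predictors)
  if (length(predictors) == 0L) predictors <- "1"
  rhs <- paste(predictors, collapse = " + ")
  fml <- stats::as.formula(paste(target, "~", rhs))
  y <- data[[target]]
  draw <- NULL
  if (is.numeric(y)) {
    draw <- try(suppressWarnings({
      fit <- stats::lm(fml, data = data[obs, , drop = FALSE])
      pred_obs <- stats::predict(fit, newdata = data[obs, , drop = FALSE])
      pred_mis <- stats::predict(fit, newdata = data[mis, , drop = FALSE])
      .draw_pmm(y[obs], pred_obs, pred_mis)
    }), silent = TRUE)
  } else if (is.logical(y) || nlevels(factor(y)) == 2L) {
    draw <- try(suppressWarnings({
      fit <- stats::glm(fml, data = data[obs, , drop = FALSE],
                        family = stats::binomial())
      p <- stats::predict(fit, newdata = data[mis, , drop = FALSE],
                          type = "response")
      b <- stats::rbinom(length(p), 1L, pmin(pmax(p, 0), 1))
      if (is.logical(y)) as.logical(b)
      else factor(levels(y)[b + 1L], levels = levels(y),
                  ordered = is.ordered(y))
    }), silent = TRUE)
  } else if (is.ordered(y)) {
    draw <- try(suppressWarnings({
      fit <- MASS::polr(fml, data = data[obs, , drop = FALSE], Hess = FALSE)
      pr <- stats::predict(fit, newdata = data[mis, , drop = FALSE],
                           type = "probs")
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
      idx <- apply(pr, 1L, function(p)
        sample.int(length(p), 1L, prob = pmax(p, 1e-12)))
      factor(levels(y)[idx], levels = levels(y), ordered = TRUE)
    }), silent = TRUE)
  } else if (is.factor(y)) {
    # nominal: one-vs-rest logits, normalized
    draw <- try(suppressWarnings({
      lv <- levels(y)
      pr <- matrix(NA_real_, sum(mis), length(lv))
      for (j in seq_along(lv)) {
        data$.ovr <- as.integer(data[[target]] == lv[j])
        f2 <- stats::as.formula(paste(".ovr ~", rhs))
        fit <- stats::glm(f2, data = data[obs, , drop = FALSE],
                          family = stats::binomial())
        pr[, j] <- stats::predict(fit, newdata = data[mis, , drop = FALSE],
                                  type = "response")
      }
      data$.ovr <- NULL
      idx <- apply(pr, 1L, function(p)
        sample.int(length(p), 1L, prob = pmax(p, 1e-12)))
      factor(lv[idx], levels = lv)
    }), silent = TRUE)
  }
  if (is.null(draw) || inherits(draw, "try-error")) {
    # fallback: draw from the observed marginal
    draw <- sample(y[obs], sum(mis), replace = TRUE)
  }
  data$.ovr <- NULL
  data[[target]][mis] <- draw
  data
}

#' Multiple imputation of covariates by chained equations
#'
#' Imputes missing covariate values (outcomes and exposures are assumed
#' complete for included rows and are never imputed) using the model
#' covariates plus the auxiliary variables self-rated health, smoking and
#' BMI as predictors. Categorical variables are imputed as categorical.
#'
#' @param panel data.frame.
#' @param m number of completed datasets (default 5).
#' @param seed RNG seed making the run reproducible.
#' @param maxit chained-equation sweeps per dataset (default 5).
#' @param impute_vars variables eligible for imputation (intersected with
#'   columns that actually have missing values).
#' @param predictors predictor set (intersected with available columns).
#' @return object of class `imputed_panels`: a list of `m` completed
#'   data.frames, with per-variable missingness and chain means stored in
#'   attributes `missingness` and `chain_means`.
#' @export
impute_missing <- function(panel, m = 5L, seed = NULL, maxit = 5L,
                           impute_vars = .default_impute_vars,
                           predictors = .default_predictors) {
  if (!is.null(seed)) set.seed(seed)
  impute_vars <- intersect(impute_vars, names(panel))
  predictors <- intersect(predictors, names(panel))
  frac <- vapply(panel[impute_vars], function(v) mean(is.na(v)), numeric(1))
  targets <- impute_vars[frac > 0]
  if (any(frac >= 1))
    stop("variable(s) entirely missing: ",
         paste(impute_vars[frac >= 1], collapse = ", "))
  if (any(frac > 0.5))
    warning("variable(s) with > 50% missing: ",
            paste(impute_vars[frac > 0.5], collapse = ", "))
  outcome_like <- grep("_min_wk$|^lum_", names(panel), value = TRUE)
  bad <- outcome_like[vapply(panel[outcome_like],
                             function(v) anyNA(v), logical(1))]
  if (length(bad))
    stop("outcomes/exposures must be complete for included rows; missing in: ",
         paste(bad, collapse = ", "))
  if (length(targets) == 0L) {
    out <- replicate(m, panel, simplify = FALSE)
    attr(out, "missingness") <- frac
    attr(out, "chain_means") <- NULL
    class(out) <- "imputed_panels"
    return(out)
  }
  chain <- vector("list", m)
  out <- vector("list", m)
  for (im in seq_len(m)) {
    d <- panel
    for (v in targets) { # initialize from the observed marginal
      mis <- is.na(d[[v]])
      d[[v]][mis] <- sample(d[[v]][!mis], sum(mis), replace = TRUE)
    }
    tr <- matrix(NA_real_, maxit, length(targets),
                 dimnames = list(NULL, targets))
    for (it in seq_len(maxit)) {
      for (v in targets) {
        d[[v]][is.na(panel[[v]])] <- NA
        preds <- setdiff(predictors, v)
        d <- .impute_one(d, v, preds)
        tr[it, v] <- if (is.numeric(d[[v]])) mean(d[[v]][is.na(panel[[v]])])
                     else mean(as.integer(factor(d[[v]][is.na(panel[[v]])])))
      }
    }
    chain[[im]] <- tr
    out[[im]] <- d
  }
  attr(out, "missingness") <- frac
  attr(out, "chain_means") <- chain
  class(out) <- "imputed_panels"
  out
}

#' @export
print.imputed_panels <- function(x, ...) {
  frac <- attr(x, "missingness")
  cat(sprintf("<imputed_panels> m = %d completed datasets, %d rows\n",
              length(x), nrow(x[[1]])))
  if (length(frac)) {
    shown <- frac[frac > 0]
    if (length(shown))
      cat("  imputed:", paste(sprintf("%s (%.1f%%)", names(shown),
                                      100 * shown), collapse = ", "), "\n")
    else cat("  no missing values; copies of the input\n")
  }
  invisible(x)
}
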