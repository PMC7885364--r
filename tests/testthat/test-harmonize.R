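# Outcome harmonization, non-mover restriction, pooling, imputation.

test_that("SQUASH scoring follows the substitution rules", {
  # complete item: days x minutes/day
  expect_equal(squash_minutes_per_week(3, 30), 90)
  # duration without days: assume at least 1 active day
  expect_equal(squash_minutes_per_week(NA, 45), 45)
  # days without duration: substitute the cohort median
  expect_equal(squash_minutes_per_week(4, NA, median_min_per_day = 30), 120)
  # all missing stays missing; direct weekly minutes take precedence
  expect_true(is.na(squash_minutes_per_week(NA, NA)))
  expect_equal(squash_minutes_per_week(3, 30, minutes_per_week_direct = 75), 75)
  expect_error(squash_minutes_per_week(8, 30), "0..7")
  expect_error(squash_minutes_per_week(3, -5), "negative")
})

test_that("LAPAQ scoring averages the 2-week recall", {
  expect_equal(lapaq_minutes_per_week(4, 30), 60)
  expect_equal(lapaq_minutes_per_week(0, 30), 0)
  expect_equal(lapaq_minutes_per_week(7, 20), 70)
  expect_error(lapaq_minutes_per_week(-1, 20), "negative")
})

test_that("harmonized outcomes are scale-consistent", {
  d <- c(2, 5, 7); m <- c(10, 40, 25)
  expect_equal(squash_minutes_per_week(d, 2 * m), 2 * squash_minutes_per_week(d, m))
  s <- c(1, 6, 10); ms <- c(15, 30, 45)
  expect_equal(lapaq_minutes_per_week(s, 2 * ms), 2 * lapaq_minutes_per_week(s, ms))
})

test_that("squash_median stratifies and uses complete items only", {
  mins <- c(10, 20, 30, NA, 100, 200)
  days <- c(1, 2, 3, 4, 1, NA)
  waves <- c(1, 1, 1, 1, 2, 2)
  med <- squash_median(mins, days, strata = list(wave = waves))
  expect_equal(med[1:4], rep(20, 4))  # wave 1: median(10, 20, 30)
  expect_equal(med[5], 100)           # wave 2: only one complete item
  expect_equal(squash_median(mins, days), 25)
})

test_that("filter_nonmovers keeps complete three-wave stayers, idempotently", {
  panel <- data.frame(
    person_id = rep(c("stay", "move", "twowave"), times = c(3, 3, 2)),
    wave_id = c(1:3, 1:3, 1:2),
    res_x = c(10, 10, 10.5, 0, 0, 800, 5, 5),
    res_y = c(20, 20, 20, 0, 0, 800, 5, 5))
  out <- suppressMessages(filter_nonmovers(panel))
  expect_equal(unique(out$person_id), "stay")
  expect_equal(attr(out, "n_excluded_incomplete"), 1L)
  expect_equal(attr(out, "n_excluded_moved"), 1L)
  # idempotent
  out2 <- suppressMessages(filter_nonmovers(out))
  expect_equal(out2$person_id, out$person_id)
  expect_equal(attr(out2, "n_excluded_moved"), 0L)
})

test_that("pool_cohorts concatenates, checks schema and codings", {
  a <- data.frame(person_id = c("A1", "A2"), walk_min_wk = c(10, 20),
                  cohort_id = "A",
                  income = factor(c("low", "high"), levels = c("low", "high")))
  b <- data.frame(person_id = c("B1", "B2"), walk_min_wk = c(30, 40),
                  cohort_id = "B",
                  income = factor(c("low", "high"), levels = c("low", "high")))
  pooled <- pool_cohorts(a, b)
  expect_equal(nrow(pooled), 4L)
  expect_equal(table(pooled$cohort_id)[["A"]], 2L)
  # per-cohort marginals preserved
  expect_equal(pooled$walk_min_wk[pooled$cohort_id == "A"], a$walk_min_wk)

  b_bad <- b
  b_bad$income <- factor(c("quintile1", "quintile5"))
  expect_error(pool_cohorts(a, b_bad), "conflicting coding")
  b_col <- b["person_id"]
  expect_error(pool_cohorts(a, b_col), "schema mismatch")
  expect_warning(pool_cohorts(a, b[0, ]), "empty")
})

test_that("impute_missing returns m complete panels; copies when complete", {
  cfg <- tiny_config(missing_rates = c(income = 0, employment = 0,
                                       education = 0, bmi = 0))
  p <- generate_panel(cfg)
  imp <- impute_missing(p, m = 3, seed = 1)
  expect_length(imp, 3L)
  expect_identical(imp[[1]], p)
  expect_identical(imp[[2]], p)

  cfg2 <- tiny_config(seed = 9)
  p2 <- generate_panel(cfg2)
  expect_true(anyNA(p2$income))
  imp2 <- impute_missing(p2, m = 5, seed = 2)
  expect_length(imp2, 5L)
  for (d in imp2) {
    expect_false(anyNA(d$income))
    expect_false(anyNA(d$employment))
    expect_false(anyNA(d$education))
    expect_s3_class(d$income, "factor")  # categorical imputed as categorical
  }
  # imputations differ across datasets (not single imputation repeated)
  mis <- is.na(p2$income)
  expect_false(identical(imp2[[1]]$income[mis], imp2[[2]]$income[mis]))
})

test_that("MCAR imputation reproduces category frequencies within MC error", {
  set.seed(11)
  n <- 1200
  lv <- c("lt1200", "1200_1800", "1800_2600", "gt2600")
  truth_p <- c(0.15, 0.30, 0.35, 0.20)
  d <- data.frame(
    sex = factor(sample(c("m", "f"), n, TRUE)),
    age = rnorm(n, 60, 10),
    income = factor(sample(lv, n, TRUE, prob = truth_p), levels = lv,
                    ordered = TRUE))
  d$income_full <- d$income
  drop <- runif(n) < 0.25 # MCAR
  d$income[drop] <- NA
  imp <- impute_missing(d, m = 5, seed = 3, impute_vars = "income",
                        predictors = c("sex", "age"))
  freq_imp <- rowMeans(sapply(imp, function(x)
    prop.table(table(x$income[drop]))))
  freq_true <- prop.table(table(d$income_full[drop]))
  # binomial MC error on ~300 imputed values, 3.5 sigma margin
  expect_true(all(abs(freq_imp - freq_true) <
                    3.5 * sqrt(freq_true * (1 - freq_true) / sum(drop)) + 0.02))
})

test_that("impute_missing validates pathological missingness", {
  p <- generate_panel(tiny_config(seed = 5))
  p$income[] <- NA
  expect_error(impute_missing(p, m = 2, seed = 1), "entirely missing")
  p2 <- generate_panel(tiny_config(seed = 6))
  p2$employment[runif(nrow(p2)) < 0.7] <- NA
  expect_warning(impute_missing(p2, m = 2, seed = 1), "50%")
  p3 <- generate_panel(tiny_config(seed = 7))
  p3$walk_min_wk[1] <- NA
  expect_error(impute_missing(p3, m = 2, seed = 1), "outcomes/exposures")
})
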