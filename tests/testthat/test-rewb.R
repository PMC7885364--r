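# Within-between decomposition, REWB fit, Rubin pooling, results grid.

test_that("decomposition is exact and sums to zero within person", {
  d <- data.frame(person_id = rep("p1", 3), x = c(1, 2, 3))
  out <- decompose_within_between(d, "x")
  expect_equal(out$x_bar, rep(2, 3))
  expect_equal(out$x_dev, c(-1, 0, 1))

  d2 <- data.frame(person_id = rep("p2", 3), x = rep(7, 3))
  out2 <- decompose_within_between(d2, "x")
  expect_equal(out2$x_dev, rep(0, 3))

  set.seed(3)
  d3 <- data.frame(person_id = rep(sprintf("q%02d", 1:30), each = 3),
                   x = rnorm(90))
  out3 <- decompose_within_between(d3, "x")
  expect_equal(out3$x_dev + out3$x_bar, d3$x)
  sums <- tapply(out3$x_dev, d3$person_id, sum)
  expect_true(all(abs(sums) < 1e-9))
})

test_that("REWB equals the FE-within and between-means OLS oracles", {
  d <- balanced_panel(n_persons = 60, seed = 4)
  fit <- rewb(y ~ 1, data = d, exposure = "x")

  # independent within oracle: OLS of demeaned y on demeaned x
  ybar <- ave(d$y, d$person_id)
  xbar <- ave(d$x, d$person_id)
  bw_fe <- coef(lm(I(d$y - ybar) ~ 0 + I(d$x - xbar)))[[1]]
  # independent between oracle: OLS of person means on person means
  pm <- aggregate(cbind(y, x) ~ person_id, d, mean)
  bb_ols <- coef(lm(y ~ x, pm))[["x"]]

  expect_equal(unname(fit$coefficients["x_dev"]), bw_fe, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x_bar"]), bb_ols, tolerance = 1e-6)
})

test_that("a person-level constant shift moves only the between side", {
  d <- balanced_panel(n_persons = 40, seed = 9)
  f1 <- rewb(y ~ 1, data = d, exposure = "x")
  d2 <- d
  d2$x <- d2$x + 5 # constant within person
  f2 <- rewb(y ~ 1, data = d2, exposure = "x")
  expect_equal(unname(f1$coefficients["x_dev"]),
               unname(f2$coefficients["x_dev"]), tolerance = 1e-8)
  expect_equal(unname(f1$coefficients["x_bar"]),
               unname(f2$coefficients["x_bar"]), tolerance = 1e-8)
})

test_that("noiseless generator limit is recovered to machine precision", {
  cfg <- tiny_config(seed = 21, var_v = 0, var_eps = 0,
                     covariate_effects = list(
                       sex_male = 0, education_per_level = 0,
                       age_per_year = 0, employment = 0,
                       income_per_level = 0,
                       marital = c(married = 0, never_married = 0,
                                   divorced = 0, widowed = 0),
                       cohort_b = 0),
                     missing_rates = c(income = 0, employment = 0,
                                       education = 0, bmi = 0))
  p <- generate_panel(cfg)
  p$lum_scaled_1000 <- p$lum_scaled_true
  fit <- suppressWarnings(rewb(walk_min_wk ~ 1, data = p,
                               exposure = "lum_scaled_1000"))
  expect_equal(unname(fit$coefficients["x_dev"]), -5, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x_bar"]), 10, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 280, tolerance = 1e-5)
})

test_that("degenerate designs raise informative errors", {
  d <- balanced_panel(n_persons = 20, seed = 5)
  d$x <- ave(d$x, d$person_id) # kill all within variation
  expect_error(rewb(y ~ 1, data = d, exposure = "x"),
               "within-person exposure variance")

  d2 <- balanced_panel(n_persons = 20, seed = 6)
  d2$z1 <- rnorm(nrow(d2))
  d2$z2 <- 2 * d2$z1 # aliased
  expect_error(rewb(y ~ z1 + z2, data = d2, exposure = "x"),
               "aliased term")

  d3 <- balanced_panel(n_persons = 1, seed = 7)
  expect_error(rewb(y ~ 1, data = d3, exposure = "x"), "at least 2 persons")
})

test_that("boundary random-intercept variance is reported with a warning", {
  d <- balanced_panel(n_persons = 60, sd_v = 0, sd_e = 10, seed = 8)
  expect_warning(fit <- rewb(y ~ 1, data = d, exposure = "x"), "boundary")
  expect_true(fit$boundary)
  expect_gte(fit$var_v, 0)
})

test_that("rewb methods behave like standard model accessors", {
  d <- balanced_panel(n_persons = 40, seed = 10)
  fit <- rewb(y ~ 1, data = d, exposure = "x")
  expect_s3_class(fit, "rewb")
  expect_named(coef(fit)[1:3], c("(Intercept)", "x_dev", "x_bar"))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_length(residuals(fit), nrow(d))
  expect_length(predict(fit), nrow(d))
  s <- summary(fit)
  expect_s3_class(s, "summary.rewb")
  expect_output(print(fit), "within")
  expect_output(print(s), "Variance components")
})

test_that("Rubin pooling reproduces the closed-form two-imputation case", {
  d <- balanced_panel(n_persons = 30, seed = 11)
  base <- rewb(y ~ 1, data = d, exposure = "x")
  # forge two results with estimates {1, 3} and within-variances {1, 1}
  r1 <- base; r2 <- base
  r1$coefficients[] <- 1; r1$se[] <- 1
  r2$coefficients[] <- 3; r2$se[] <- 1
  pooled <- rubin_pool(list(r1, r2))
  expect_equal(unname(pooled$coefficients["x_dev"]), 2)
  expect_equal(unname(pooled$total_var["x_dev"]), 1 + 1.5 * 2)
  expect_equal(unname(pooled$se["x_dev"]), 2)

  # m identical results collapse to zero between-imputation variance
  pid <- rubin_pool(list(base, base, base))
  expect_equal(pid$coefficients, base$coefficients)
  expect_equal(unname(pid$between_var), rep(0, length(base$coefficients)))
  expect_equal(pid$se, base$se)

  # m = 1 pools to itself with a warning
  expect_warning(p1 <- rubin_pool(list(base)), "single result")
  expect_equal(p1$coefficients, base$coefficients)

  # mismatched specifications are refused
  other <- rewb(y ~ 1, data = d, exposure = "x")
  other$outcome <- "cycle_min_wk"
  expect_error(rubin_pool(list(base, other)), "mismatched")
})

test_that("run_all_models emits the full outcome x buffer grid", {
  cfg <- tiny_config(seed = 31)
  p <- generate_panel(cfg)
  for (sz in c(500, 1000, 1600)) {
    p[[sprintf("lum_scaled_%g", sz)]] <-
      pmin(10, pmax(0, p$lum_scaled_true + rnorm(nrow(p), 0, 0.1)))
  }
  imp <- impute_missing(p, m = 2, seed = 1)
  res <- run_all_models(imp, covariates = c("sex", "age", "cohort_id"))
  expect_equal(nrow(res), 12L) # 2 outcomes x 3 sizes x within/between
  expect_setequal(unique(res$effect_type), c("within", "between"))
  expect_true(all(res$status == "ok"))
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))

  # a buffer size without exposure data yields marked-failed rows
  res2 <- run_all_models(imp, buffer_sizes = c(1000, 2400),
                         covariates = c("sex", "age"))
  bad <- res2[res2$buffer_size == 2400, ]
  expect_true(all(grepl("failed", bad$status)))
  expect_true(all(is.na(bad$beta)))
  expect_true(all(res2$status[res2$buffer_size == 1000] == "ok"))
})
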