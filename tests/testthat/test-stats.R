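test_that("charge-density limit converts to the expected safe amplitude", {
  ## 1.0 mC/cm^2 on a 200 um disc at 0.45 ms -> ~698 uA
  expect_equal(max_safe_amplitude(1.0, 0.45, 200), 698, tolerance = 0.001)
  ## doubling the pulse width halves the allowed current
  expect_equal(max_safe_amplitude(1.0, 0.9, 200),
               max_safe_amplitude(1.0, 0.45, 200) / 2)
  ## the clinical 677 uA cutoff stays within the limit
  cd <- charge_density(677, 0.45, 200)
  expect_equal(cd, 0.97, tolerance = 0.005)
  expect_lte(cd, 1.0)
})

test_that("inclusion filter applies visibility and the strict threshold cap", {
  m <- data.frame(label = c("A1", "A2", "A3", "A4"),
                  threshold_uA = c(600, 677, 700, 100),
                  visible = c(TRUE, TRUE, TRUE, FALSE))
  kept <- inclusion_filter(m)
  expect_equal(kept$label, "A1")            # 677 is excluded: strict <
  cnt <- attr(kept, "excluded_counts")
  expect_equal(unname(cnt["over_cap"]), 2)
  expect_equal(unname(cnt["not_visible"]), 1)
  empty <- inclusion_filter(m[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(attr(empty, "excluded_counts")), 0)
})

test_that("ols matches the closed-form normal equations on small data", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8, 12.2)
  fit <- ols(x, y)
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(fit$coefficients$estimate, beta, tolerance = 1e-12)
  expect_equal(fit$intercept, alpha, tolerance = 1e-12)
  r2 <- cor(x, y)^2
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  ## exactly linear data
  exact <- ols(x, 3 + 2 * x)
  expect_equal(exact$r_squared, 1)
  expect_lt(exact$p_value, 1e-10)
})

test_that("ols recovers the generating slope within 3 standard errors", {
  lay <- default_layout()
  slope <- 0.4 / (9 * 0.525)
  geo <- make_synthetic_retina(
    retina_config(standoff_um = 30, tilt = c(slope, 0.02)), lay, seed = 4)
  m <- measure_electrodes(geo, lay)
  m <- synth_thresholds(m, list(intercept = 60, distance_mm = 500),
                        noise_sd = 10, seed = 11)
  fit <- ols(m$distance_mm, m$threshold_uA)
  expect_equal(fit$n, 60L)
  se <- fit$coefficients$std_error
  expect_lt(abs(fit$coefficients$estimate - 500), 3 * se)
  expect_true(fit$significant)
})

test_that("multiple regression R^2 dominates the single-covariate fits", {
  lay <- default_layout()
  slope <- 0.4 / (9 * 0.525)
  geo <- make_synthetic_retina(
    retina_config(standoff_um = 30, tilt = c(slope, 0),
                  thickness_roughness_um = 25), lay, seed = 5)
  m <- synth_thresholds(measure_electrodes(geo, lay),
                        list(intercept = 60, distance_mm = 400,
                             thickness_mm = -250),
                        noise_sd = 15, seed = 6)
  covs <- c("distance_mm", "thickness_mm", "impedance_kohm")
  singles <- vapply(covs, function(v)
    ols(m[[v]], m$threshold_uA)$r_squared, numeric(1))
  multi <- ols(m[, covs], m$threshold_uA)
  expect_gte(multi$r_squared, max(singles))
  tab <- regression_table(m, covariates = covs)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$r_squared[tab$model == "multiple"], multi$r_squared)
})

test_that("ols rejects degenerate designs", {
  y <- rnorm(10)
  expect_error(ols(data.frame(a = 1:10, b = rep(2, 10)), y), "constant")
  expect_error(ols(data.frame(a = 1:10, b = 2 * (1:10)), y),
               "collinear")
  expect_error(ols(1:2, c(1, 2)))   # too few observations
})

test_that("type-I error rate is calibrated near the nominal 5%", {
  n <- 60
  reps <- 1000
  set.seed(99)
  x <- rnorm(n)
  hits <- 0L
  for (i in seq_len(reps)) {
    y <- rnorm(n)                     # independent of x
    if (ols(x, y)$p_value < 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  ## binomial sd at p = 0.05, n = 1000 is ~0.7%; accept within ~3 sd
  expect_gt(rate, 0.028)
  expect_lt(rate, 0.075)
})

test_that("mixed model detects a shared thickness effect across participants", {
  set.seed(7)
  dat <- do.call(rbind, lapply(1:6, function(p) {
    n <- 40
    thick <- runif(n, 0.1, 0.35)
    slope <- -900 + rnorm(1, 0, 100)
    data.frame(participant = paste0("P", p), thickness_mm = thick,
               threshold_uA = 400 + slope * thick + rnorm(n, 0, 30))
  }))
  fit <- lmm_threshold(dat, "thickness_mm")
  expect_lt(fit$fixed_p, 0.05)
  expect_lt(abs(fit$fixed_effect - (-900)), 300)
})
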