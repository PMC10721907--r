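test_that("constant flat geometry yields constant electrode measurements", {
  m <- measure_electrodes(flat_geometry(), default_layout())
  expect_true(all(m$visible))
  expect_equal(m$distance_mm, rep(0.1, 60))
  expect_equal(m$thickness_mm, rep(0.2, 60))
  expect_equal(m$fibrosis_mm, rep(0, 60))
})

test_that("tilted array produces distances on the configured plane", {
  lay <- default_layout()
  ## 0.5 mm drop across the 10 columns (9 pitches)
  slope <- 0.5 / (9 * 0.525)
  geo <- make_synthetic_retina(
    retina_config(standoff_um = 50, tilt = c(slope, 0)), lay, seed = 3)
  m <- measure_electrodes(geo, lay)
  plane <- geo$array_plane
  expected <- plane$z0 + plane$ax * m$x_mm + plane$ay * m$y_mm
  expect_equal(m$distance_mm, expected, tolerance = 1e-10)
  ## the configured drop is realised across the 10 columns
  expect_equal(max(m$distance_mm) - min(m$distance_mm), 0.5,
               tolerance = 1e-6)
  ## the standoff is the minimum gap over the substrate footprint, so every
  ## electrode sits at or above it
  expect_true(all(m$distance_mm >= 0.05 - 1e-9))
  expect_lt(min(m$distance_mm), 0.05 * 2 + slope * 0.6)
})

test_that("geometry generation is deterministic in the seed", {
  cfg <- retina_config(thickness_roughness_um = 30,
                       surface_amplitude_um = 20)
  g1 <- make_synthetic_retina(cfg, default_layout(), seed = 7)
  g2 <- make_synthetic_retina(cfg, default_layout(), seed = 7)
  g3 <- make_synthetic_retina(cfg, default_layout(), seed = 8)
  expect_identical(g1$thickness_um, g2$thickness_um)
  expect_identical(g1$inner_z_mm, g2$inner_z_mm)
  expect_false(identical(g1$thickness_um, g3$thickness_um))
})

test_that("array plane intersecting the retina is rejected", {
  expect_error(
    make_synthetic_retina(
      retina_config(standoff_um = -20), default_layout(), seed = 1),
    "intersects")
})

test_that("apposed electrode over fibrosis reports distance equal to fibrosis", {
  lay <- default_layout()
  e <- lay$electrodes[lay$electrodes$label == "C5", ]
  geo <- make_synthetic_retina(
    retina_config(standoff_um = 80,
                  fibrosis = list(list(center_xy = c(e$x_mm, e$y_mm),
                                       radius_mm = 0.3, thickness_um = 80,
                                       edge_mm = 0.1))),
    lay, seed = 1)
  m <- measure_electrodes(geo, lay)
  row <- m[m$label == "C5", ]
  expect_equal(row$fibrosis_mm, 0.08, tolerance = 1e-9)
  expect_equal(row$distance_mm, row$fibrosis_mm)
  ## fibrosis never exceeds the electrode-retina gap anywhere
  expect_true(all(m$fibrosis_mm <= m$distance_mm + 1e-12))
})

test_that("electrode outside the lateral grid is flagged not visible", {
  lay <- default_layout()
  geo <- make_synthetic_retina(
    retina_config(extent_mm = c(4, 2.4), grid_spacing_mm = 0.1), lay,
    seed = 1)
  m <- measure_electrodes(geo, lay)
  outside <- abs(lay$electrodes$x_mm) > 2 | abs(lay$electrodes$y_mm) > 1.2
  expect_equal(m$visible, !outside)
  expect_true(all(is.na(m$distance_mm[!m$visible])))
  expect_true(any(!m$visible) && any(m$visible))
})

test_that("zero-noise synthetic thresholds are exactly linear in covariates", {
  lay <- default_layout()
  slope <- 0.4 / (9 * 0.525)
  geo <- make_synthetic_retina(
    retina_config(standoff_um = 30, tilt = c(slope, 0),
                  thickness_roughness_um = 25), lay, seed = 2)
  m <- measure_electrodes(geo, lay)
  co <- list(intercept = 40, distance_mm = 500, thickness_mm = -300)
  m1 <- synth_thresholds(m, co, noise_sd = 0, seed = 1, floor_uA = 1e-9)
  expected <- 40 + 500 * m1$distance_mm - 300 * m1$thickness_mm
  expect_equal(m1$threshold_uA, expected, tolerance = 1e-12)
  ## exactly invertible by OLS
  fit <- ols(m1[, c("distance_mm", "thickness_mm")], m1$threshold_uA)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$coefficients$estimate, c(500, -300), tolerance = 1e-6)
})

test_that("threshold noise differs across seeds, systematic part does not", {
  m <- measure_electrodes(flat_geometry(), default_layout())
  a <- synth_thresholds(m, noise_sd = 5, seed = 1)
  b <- synth_thresholds(m, noise_sd = 5, seed = 2)
  expect_false(identical(a$threshold_uA, b$threshold_uA))
  expect_equal(mean(a$threshold_uA), mean(b$threshold_uA), tolerance = 0.2)
  expect_identical(synth_thresholds(m, noise_sd = 5, seed = 1)$threshold_uA,
                   a$threshold_uA)
})

test_that("measurement tables round-trip through TSV", {
  m <- synth_thresholds(measure_electrodes(flat_geometry(),
                                           default_layout()))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(m, path)
  back <- read_measurements(path)
  expect_equal(back$label, m$label)
  expect_equal(back$threshold_uA, m$threshold_uA, tolerance = 1e-9)
  expect_equal(back$visible, m$visible)
})
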