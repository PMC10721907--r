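make_thr_table <- function(thr, x = NULL, y = NULL, electrode = "C5") {
  n <- length(thr)
  data.frame(electrode = electrode, neuron_id = seq_len(n),
             x_mm = if (is.null(x)) seq(0, 1, length.out = n) else x,
             y_mm = if (is.null(y)) rep(0, n) else y,
             threshold_uA = thr, stringsAsFactors = FALSE)
}

test_that("threshold map takes the minimum over retained neurons", {
  tab <- make_thr_table(c(12.3, 45.6, 7.8))
  map <- electrode_threshold_map(tab)
  expect_equal(map$electrodes$min_threshold_uA, 7.8)
  ## excluding the argmin neuron re-computes the minimum
  tab$excluded <- c(FALSE, FALSE, TRUE)
  map2 <- electrode_threshold_map(tab)
  expect_equal(map2$electrodes$min_threshold_uA, 12.3)
  ## permutation invariance
  perm <- tab[c(3, 1, 2), ]
  expect_equal(electrode_threshold_map(perm)$electrodes$min_threshold_uA,
               map2$electrodes$min_threshold_uA)
  ## fully excluded electrodes are flagged, not zeroed
  tab$excluded <- TRUE
  map3 <- electrode_threshold_map(tab)
  expect_true(map3$electrodes$flagged)
  expect_true(is.na(map3$electrodes$min_threshold_uA))
})

test_that("activation set and hull area behave with amplitude multiples", {
  thr <- c(10, 12, 15, 20, 30, 61)
  tab <- make_thr_table(thr, x = c(0, 1, 0, 0.5, 0.2, 0.9),
                        y = c(0, 0, 1, 0.5, 0.8, 0.1))
  map <- electrode_threshold_map(tab)
  ## k = 1: exactly the argmin neuron(s)
  p1 <- activation_pattern(map, "C5", 1)
  expect_equal(p1$activated$neuron_id, 1L)
  expect_equal(p1$hull_area_mm2, 0)
  ## triangle (0,0), (1,0), (0,1): area 0.5 mm^2 = 6.028 deg^2
  p2 <- activation_pattern(map, "C5", 1.5)
  expect_equal(sort(p2$activated$neuron_id), 1:3)
  expect_equal(p2$hull_area_mm2, 0.5)
  expect_equal(p2$hull_area_deg2, 0.5 / 0.288^2, tolerance = 1e-12)
  expect_equal(p2$hull_area_deg2, 6.028, tolerance = 1e-3)
  ## activated count is non-decreasing over the amplitude grid; 6x misses
  ## only the 61 uA neuron
  counts <- vapply(c(1.2, 2, 3, 4, 5, 6), function(k)
    activation_pattern(map, "C5", k)$n_activated, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], 5)
  expect_error(activation_pattern(map, "C5", 0.5))
})

test_that("hull area is invariant to rigid rotation of soma coordinates", {
  thr <- c(5, 6, 7, 8, 9)
  x <- c(0, 0.7, 0.3, 0.9, 0.1); y <- c(0, 0.2, 0.8, 0.9, 0.4)
  a1 <- activation_pattern(electrode_threshold_map(make_thr_table(thr, x, y)),
                           "C5", 2)$hull_area_mm2
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y
  yr <- sin(th) * x + cos(th) * y
  a2 <- activation_pattern(electrode_threshold_map(make_thr_table(thr, xr, yr)),
                           "C5", 2)$hull_area_mm2
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("size-amplitude slope recovers a constructed linear growth", {
  ## thresholds engineered so hull area grows exactly linearly in k:
  ## squares of side s(k) = sqrt(1.17 * 0.288^2 * k) activated at multiple k
  ks <- c(1.2, 2, 3, 4, 5, 6)
  min_thr <- 10
  xs <- ys <- thr <- numeric(0)
  for (k in ks) {
    s <- sqrt(1.17 * 0.288^2 * k)
    xs <- c(xs, c(0, s, s, 0)); ys <- c(ys, c(0, 0, s, s))
    thr <- c(thr, rep(min_thr * k, 4))
  }
  thr[1] <- min_thr
  tab <- make_thr_table(thr, xs, ys)
  fit <- size_amplitude_slope(electrode_threshold_map(tab), "C5",
                              k_grid = ks)
  expect_equal(fit$slope_deg2_per_k, 1.17, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("degenerate sweeps are handled", {
  ## constant areas -> slope 0; all-zero areas -> NA sentinel
  tab <- make_thr_table(c(1, 1, 1, 1), x = c(0, 1, 0, 1),
                        y = c(0, 0, 1, 1))
  fit <- size_amplitude_slope(electrode_threshold_map(tab), "C5")
  expect_equal(fit$slope_deg2_per_k, 0, tolerance = 1e-12)
  two <- make_thr_table(c(1, 2), x = c(0, 0.1), y = c(0, 0))
  fit0 <- size_amplitude_slope(electrode_threshold_map(two), "C5")
  expect_true(is.na(fit0$slope_deg2_per_k))
})

test_that("with a half-excluded population the minimum comes from the retained side", {
  lay <- default_layout()
  pop <- place_somas(lay, "C5", n = 60, seed = 2)
  x0 <- layout_xy(lay, "C5")[1]
  geo <- flat_geometry()
  geo$thickness_um <- outer(ifelse(geo$x > x0, 50, 200),
                            rep(1, length(geo$y)))
  kept <- apply_thickness_exclusion(pop, geo, floor_um = 100)
  ## mimic a distance-dominated threshold: nearer the electrode = lower
  e <- layout_xy(lay, "C5")
  thr <- 10 + 100 * sqrt((kept$x_mm - e[1])^2 + (kept$y_mm - e[2])^2)
  tab <- data.frame(electrode = "C5", neuron_id = kept$neuron_id,
                    x_mm = kept$x_mm, y_mm = kept$y_mm, threshold_uA = thr)
  map <- electrode_threshold_map(tab)
  best <- tab[which.min(tab$threshold_uA), ]
  ## argmin neuron sits on the retained side (up to the one-cell
  ## interpolation band at the degeneration boundary)
  expect_lte(best$x_mm, x0 + geo$grid_spacing_mm)
  expect_equal(map$electrodes$min_threshold_uA, min(thr))
})
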