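test_that("pulse trains are cathodic-first, charge-balanced, right length", {
  wf <- make_pulse_train(n_pulses = 5)
  expect_equal(wf$duration_ms, 250)
  s <- retfield:::waveform_samples(wf, 0.01, 250)
  expect_equal(sum(s) * 0.01, 0)                 # charge balance
  expect_equal(s[which(s != 0)[1]], -1)          # cathodic first
  expect_equal(sum(s == -1) * 0.01, 5 * 0.45, tolerance = 1e-6)
  wf1 <- make_pulse_train(n_pulses = 1, interphase_gap_ms = 0.2)
  s1 <- retfield:::waveform_samples(wf1, 0.01, 2)
  expect_equal(sum(s1) * 0.01, 0)
  expect_error(make_pulse_train(pulse_width_ms = 30, frequency_hz = 20),
               "overlap")
})

test_that("resting neuron is stable and zero amplitude never spikes", {
  mod <- demo_cable()$model
  r <- simulate_rgc(mod, rep(0, mod$n_comp), make_pulse_train(n_pulses = 1),
                    amplitude_uA = 0, duration_ms = 200, record_v = TRUE,
                    stop_at_spike = FALSE)
  expect_false(r$spiked)
  expect_lt(max(abs(r$v - mod$v_rest)), 1)
})

test_that("suprathreshold amplitudes spike; spikes start in the sodium band", {
  fix <- demo_cable()
  ve <- point_source_ve(fix$neuron, 0.1)
  thr <- find_threshold(fix$model, ve)
  s <- simulate_rgc(fix$model, ve, make_pulse_train(n_pulses = 1),
                    amplitude_uA = 10 * thr)
  expect_true(s$spiked)
  sub <- simulate_rgc(fix$model, ve, make_pulse_train(n_pulses = 1),
                      amplitude_uA = 0.8 * thr, duration_ms = 4)
  expect_false(sub$spiked)
  at <- simulate_rgc(fix$model, ve, make_pulse_train(n_pulses = 1),
                     amplitude_uA = 1.05 * thr)
  expect_true(fix$neuron$section[at$spike_comp] %in%
                c("sodium_band", "hillock", "axon"))
})

test_that("bisection matches a brute-force amplitude scan within tolerance", {
  ## synthetic indicator: spikes iff amplitude >= 123.45 uA
  thr <- bisect_threshold(function(a) a >= 123.45, lo_uA = 0, hi_uA = 1000,
                          tol_uA = 0.1)
  scan <- seq(0, 1000, by = 0.01)
  brute <- scan[which(scan >= 123.45)[1]]
  expect_lt(abs(thr - brute), 0.1)
  expect_lte(diff(attr(thr, "bracket_uA")), 0.1)

  ## on the actual neuron: brute-force scan at 0.05 uA agrees with bisection
  fix <- demo_cable()
  ve <- point_source_ve(fix$neuron, 0.1)
  wf <- make_pulse_train(n_pulses = 1)
  b <- find_threshold(fix$model, ve)
  spikes <- function(a) simulate_rgc(fix$model, ve, wf, amplitude_uA = a,
                                     duration_ms = 4)$spiked
  grid <- seq(b - 0.5, b + 0.5, by = 0.05)
  hit <- grid[which(vapply(grid, spikes, logical(1)))[1]]
  expect_lt(abs(b - hit), 0.1)
})

test_that("bisection uses the expected number of spike evaluations", {
  calls <- 0L
  bisect_threshold(function(a) {
    calls <<- calls + 1L
    a >= 400
  }, lo_uA = 0, hi_uA = 1000, tol_uA = 0.1)
  ## ceil(log2(1000/0.1)) = 14 halvings plus the two bracket checks
  expect_equal(calls, 14L + 2L)
})

test_that("inexcitable neurons return the NA sentinel", {
  out <- bisect_threshold(function(a) FALSE, lo_uA = 0, hi_uA = 10,
                          tol_uA = 0.1, expand_cap = 40)
  expect_true(is.na(out))
  expect_true(attr(out, "inexcitable"))
})

test_that("threshold rises monotonically with electrode distance", {
  fix <- demo_cable()
  heights <- c(0.05, 0.1, 0.2, 0.3)
  thr <- vapply(heights, function(h)
    as.numeric(find_threshold(fix$model,
                              point_source_ve(fix$neuron, h - 0.055))),
    numeric(1))
  expect_true(all(diff(thr) > 0))
})

test_that("strength-duration: threshold non-increasing in pulse width", {
  fix <- demo_cable()
  ve <- point_source_ve(fix$neuron, 0.1)
  widths <- c(0.1, 0.25, 0.45, 1.0)
  thr <- vapply(widths, function(pw)
    as.numeric(find_threshold(fix$model, ve,
                              waveform = make_pulse_train(
                                pulse_width_ms = pw, n_pulses = 1))),
    numeric(1))
  expect_true(all(diff(thr) < 0))
})

test_that("field scaling and amplitude scaling are equivalent", {
  fix <- demo_cable()
  ve <- point_source_ve(fix$neuron, 0.12)
  t1 <- find_threshold(fix$model, ve)
  t2 <- find_threshold(fix$model, 2 * ve)
  expect_equal(as.numeric(t1), 2 * as.numeric(t2), tolerance = 0.02)
})

test_that("halving the time step changes thresholds by less than 2%", {
  fix <- demo_cable()
  ve <- point_source_ve(fix$neuron, 0.1)
  t1 <- find_threshold(fix$model, ve, dt_ms = 0.01)
  t2 <- find_threshold(fix$model, ve, dt_ms = 0.005)
  expect_lt(abs(t1 - t2) / t1, 0.02)
})
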