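#' Biphasic charge-balanced pulse train
#'
#' Builds the clinical stimulus waveform: cathodic-first, charge-balanced,
#' biphasic rectangular current pulses (0.45 ms per phase at 20 Hz by
#' default; five pulses make the standard 250 ms trial).  The waveform is a
#' dimensionless scale factor (-1 cathodic, +1 anodic, 0 off) multiplying
#' the stimulus amplitude.
#'
#' @param amplitude_uA stimulus amplitude (uA); may be overridden at
#'   simulation time.
#' @param pulse_width_ms phase duration (ms).
#' @param frequency_hz pulse rate (Hz).
#' @param n_pulses number of pulses in the train.
#' @param interphase_gap_ms gap between the two phases (ms).
#' @return object of class `stimulus_waveform` with the pulse parameters,
#'   total `duration_ms`, and a segment table (`t0_ms`, `t1_ms`, `scale`).
#' @export
make_pulse_train <- function(amplitude_uA = NA_real_, pulse_width_ms = 0.45,
                             frequency_hz = 20, n_pulses = 5,
                             interphase_gap_ms = 0) {
  stopifnot(pulse_width_ms > 0, frequency_hz > 0, n_pulses >= 1,
            interphase_gap_ms >= 0)
  period_ms <- 1000 / frequency_hz
  if (2 * pulse_width_ms + interphase_gap_ms > period_ms)
    stop("pulse phases overlap the next pulse at this frequency")
  t0 <- (seq_len(n_pulses) - 1) * period_ms
  segments <- data.frame(
    t0_ms = c(t0, t0 + pulse_width_ms + interphase_gap_ms),
    t1_ms = c(t0 + pulse_width_ms,
              t0 + 2 * pulse_width_ms + interphase_gap_ms),
    scale = rep(c(-1, 1), each = n_pulses)
  )
  segments <- segments[order(segments$t0_ms), ]
  rownames(segments) <- NULL
  structure(list(amplitude_uA = amplitude_uA,
                 pulse_width_ms = pulse_width_ms,
                 frequency_hz = frequency_hz, n_pulses = n_pulses,
                 interphase_gap_ms = interphase_gap_ms,
                 duration_ms = n_pulses * period_ms,
                 segments = segments),
            class = "stimulus_waveform")
}

#' @export
print.stimulus_waveform <- function(x, ...) {
  cat(sprintf(
    "<stimulus_waveform> %d biphasic cathodic-first pulse(s), %.2f ms/phase at %g Hz (%g ms)\n",
    x$n_pulses, x$pulse_width_ms, x$frequency_hz, x$duration_ms))
  invisible(x)
}

## Sample the waveform scale factor at time-step midpoints.
waveform_samples <- function(waveform, dt_ms, duration_ms) {
  nsteps <- ceiling(duration_ms / dt_ms)
  tm <- (seq_len(nsteps) - 0.5) * dt_ms
  scale <- numeric(nsteps)
  for (i in seq_len(nrow(waveform$segments))) {
    seg <- waveform$segments[i, ]
    scale[tm >= seg$t0_ms & tm < seg$t1_ms] <- seg$scale
  }
  scale
}

#' Simulate the membrane response of an RGC to extracellular stimulation
#'
#' Advances the multi-compartment cable equation under the extracellular
#' potential field `amplitude * waveform(t) * unit_potential`, where
#' `unit_potential` is the per-compartment potential of the unit-current
#' field solution (the linearity of the volume conductor is what allows one
#' field solve per electrode to serve all amplitudes).  Integration is
#' semi-implicit (exponential gating update + backward-Euler voltage step);
#' a spike is an upward crossing of `spike_mv` in any compartment.
#'
#' @param model a [cable_model()].
#' @param unit_potentials_V per-compartment extracellular potential for a
#'   1 A electrode current (V/A), e.g. from [interpolate_potential()] at the
#'   compartment centres.
#' @param waveform a [make_pulse_train()].
#' @param amplitude_uA stimulus amplitude (uA); defaults to the waveform's.
#' @param dt_ms time step (ms); must be <= 0.025.
#' @param duration_ms simulated time; defaults to the waveform duration plus
#'   a 3 ms spike-detection window.
#' @param spike_mv spike detection level (mV, upward crossing).
#' @param vmax_mv integration guard: membrane excursions beyond this in a
#'   run that never spikes raise an instability error.  Strong extracellular
#'   fields legitimately swing compartments near the electrode by hundreds
#'   of mV, so the guard is generous.
#' @param record_v record membrane voltage traces.
#' @param stop_at_spike stop integrating once a spike is detected.
#' @return list of class `sim_result`: `spiked`, `spike_time_ms`,
#'   `spike_comp`, final state, and optionally `vtrace` (compartments x
#'   samples) with `t_ms`.
#' @export
simulate_rgc <- function(model, unit_potentials_V, waveform,
                         amplitude_uA = waveform$amplitude_uA,
                         dt_ms = 0.01, duration_ms = NULL,
                         spike_mv = 0, vmax_mv = 1000, record_v = FALSE,
                         stop_at_spike = !record_v) {
  stopifnot(inherits(model, "cable_model"),
            length(unit_potentials_V) == model$n_comp,
            dt_ms > 0, dt_ms <= 0.025, !is.na(amplitude_uA))
  if (is.null(duration_ms)) duration_ms <- waveform$duration_ms + 3
  wave <- waveform_samples(waveform, dt_ms, duration_ms)
  ve_unit <- unit_potentials_V * 1e-3      # mV per uA of electrode current
  res <- .cable_run(model, resting_state(model), ve_unit, wave,
                    amplitude_uA, dt_ms, spike_mv, vmax_mv, stop_at_spike,
                    record_v, max(1L, as.integer(round(0.05 / dt_ms))))
  if (isTRUE(res$unstable) && !isTRUE(res$spiked))
    stop(sprintf(
      "cable integration unstable (|Vm| > %g mV); reduce dt_ms", vmax_mv))
  res$amplitude_uA <- amplitude_uA
  res$dt_ms <- dt_ms
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  if (isTRUE(x$spiked))
    cat(sprintf("<sim_result> spiked at %.3f ms (compartment %d), %g uA\n",
                x$spike_time_ms, x$spike_comp, x$amplitude_uA))
  else cat(sprintf("<sim_result> no spike at %g uA\n", x$amplitude_uA))
  invisible(x)
}

#' Bisection search for an activation threshold
#'
#' Generic bisection over stimulus amplitude against a boolean spike
#' predicate.  The upper bracket is expanded geometrically (up to
#' `expand_cap`) if it does not yet spike; the search then halves the
#' bracket until its width is at most `tol_uA` and returns the midpoint.
#' Under the monotone-activation assumption the result is within `tol_uA`
#' of the true threshold.
#'
#' @param spike_fun function(amplitude_uA) -> logical.
#' @param lo_uA,hi_uA initial bracket (uA).
#' @param tol_uA convergence tolerance on the bracket width (uA).
#' @param expand_cap maximum amplitude tried when expanding the upper
#'   bracket (default 4 * hi_uA).
#' @return threshold estimate (uA), with the final bracket as attribute
#'   `bracket_uA`; `NA` with attribute `inexcitable = TRUE` if no spike
#'   occurs at `expand_cap`.
#' @export
bisect_threshold <- function(spike_fun, lo_uA = 0, hi_uA = 1000,
                             tol_uA = 0.1, expand_cap = 4 * hi_uA) {
  stopifnot(lo_uA >= 0, hi_uA > lo_uA, tol_uA > 0)
  if (spike_fun(lo_uA)) {
    out <- lo_uA
    attr(out, "bracket_uA") <- c(lo_uA, lo_uA)
    return(out)
  }
  while (!spike_fun(hi_uA)) {
    if (hi_uA >= expand_cap) {
      out <- NA_real_
      attr(out, "inexcitable") <- TRUE
      return(out)
    }
    lo_uA <- hi_uA
    hi_uA <- min(2 * hi_uA, expand_cap)
  }
  while (hi_uA - lo_uA > tol_uA) {
    mid <- (lo_uA + hi_uA) / 2
    if (spike_fun(mid)) hi_uA <- mid else lo_uA <- mid
  }
  out <- (lo_uA + hi_uA) / 2
  attr(out, "bracket_uA") <- c(lo_uA, hi_uA)
  out
}

#' Activation threshold of a neuron under a stimulus waveform
#'
#' Runs [bisect_threshold()] with [simulate_rgc()] as the spike predicate.
#' By default the search stimulus is a single biphasic pulse: for this
#' deterministic membrane model the first pulse of a train determines the
#' threshold, and a single pulse is five times cheaper than the 250 ms
#' clinical train (set `waveform` explicitly to search with a full train).
#'
#' @param model a [cable_model()].
#' @param unit_potentials_V per-compartment unit-field potentials (V/A).
#' @param waveform search waveform; default single biphasic pulse.
#' @param lo_uA,hi_uA,tol_uA,expand_cap bisection parameters (see
#'   [bisect_threshold()]); convergence defaults to 0.1 uA.
#' @param dt_ms integration step (ms).
#' @param post_window_ms spike-detection window after the last stimulus
#'   phase (ms); each search simulation runs only this long past the pulse.
#' @return threshold in uA (NA with attribute `inexcitable` if the neuron
#'   cannot be driven to spike at `expand_cap`).
#' @export
find_threshold <- function(model, unit_potentials_V,
                           waveform = make_pulse_train(n_pulses = 1),
                           lo_uA = 0, hi_uA = 1000, tol_uA = 0.1,
                           expand_cap = 4 * hi_uA, dt_ms = 0.01,
                           post_window_ms = 3) {
  t_stop <- max(waveform$segments$t1_ms) + post_window_ms
  bisect_threshold(function(amp) {
    simulate_rgc(model, unit_potentials_V, waveform,
                 amplitude_uA = amp, dt_ms = dt_ms,
                 duration_ms = t_stop)$spiked
  }, lo_uA = lo_uA, hi_uA = hi_uA, tol_uA = tol_uA, expand_cap = expand_cap)
}
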