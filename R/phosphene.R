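#' Per-electrode threshold map
#'
#' Aggregates per-neuron activation thresholds into an electrode-level map:
#' for each electrode, the retained neurons (after any thickness exclusion
#' and dropping inexcitable neurons) and the absolute minimum threshold over
#' them.  Electrodes whose population is entirely excluded are flagged, not
#' given a threshold.
#'
#' @param thresholds data.frame with columns `electrode`, `neuron_id`,
#'   `threshold_uA`, `x_mm`, `y_mm` and optionally logical `excluded`.
#' @return object of class `threshold_map`: the per-neuron table plus a
#'   per-electrode summary (`electrode`, `min_threshold_uA`, `n_retained`,
#'   `flagged`).
#' @export
electrode_threshold_map <- function(thresholds) {
  stopifnot(all(c("electrode", "neuron_id", "threshold_uA") %in%
                  names(thresholds)))
  if (is.null(thresholds$excluded)) thresholds$excluded <- FALSE
  thresholds$excluded <- thresholds$excluded | is.na(thresholds$threshold_uA)
  summary <- do.call(rbind, lapply(split(thresholds, thresholds$electrode),
    function(d) {
      kept <- d[!d$excluded, ]
      data.frame(electrode = d$electrode[1],
                 min_threshold_uA = if (nrow(kept)) min(kept$threshold_uA)
                                    else NA_real_,
                 n_retained = nrow(kept),
                 flagged = nrow(kept) == 0,
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  structure(list(neurons = thresholds, electrodes = summary),
            class = "threshold_map")
}

#' @export
print.threshold_map <- function(x, ...) {
  cat(sprintf("<threshold_map> %d electrode(s), %d neuron(s)\n",
              nrow(x$electrodes), nrow(x$neurons)))
  print(x$electrodes)
  invisible(x)
}

## Shoelace polygon area of the convex hull of a point set; 0 for
## degenerate sets (< 3 non-collinear points).
hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3) return(0)
  h <- chull(xy)
  if (length(h) < 3) return(0)
  px <- xy[h, 1]; py <- xy[h, 2]
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

#' Activation pattern at an amplitude multiple of threshold
#'
#' The set of neurons activated at amplitude `k` times the electrode's
#' minimum threshold is, under monotone activation, exactly the set whose
#' individual threshold is at most `k * min`; no re-simulation is needed.
#' The retinal area activated is the convex hull of the activated soma
#' positions, reported in mm^2 and in squared degrees of visual angle
#' (288 um/degree).
#'
#' @param map a [electrode_threshold_map()].
#' @param electrode electrode label.
#' @param k amplitude as a multiple of the electrode threshold (>= 1).
#' @param mm_per_deg visual-angle conversion factor.
#' @return list of class `activation_pattern`: `k`, `activated` (soma
#'   data.frame), `hull_area_mm2`, `hull_area_deg2`.
#' @export
activation_pattern <- function(map, electrode, k, mm_per_deg = 0.288) {
  stopifnot(k >= 1)
  s <- map$electrodes[map$electrodes$electrode == electrode, ]
  if (nrow(s) != 1) stop("unknown electrode: ", electrode)
  if (s$flagged) stop("electrode ", electrode, " has no retained neurons")
  d <- map$neurons
  d <- d[d$electrode == electrode & !d$excluded, ]
  act <- d[d$threshold_uA <= k * s$min_threshold_uA + 1e-12, ]
  area_mm2 <- hull_area(cbind(act$x_mm, act$y_mm))
  structure(list(electrode = electrode, k = k, activated = act,
                 n_activated = nrow(act),
                 hull_area_mm2 = area_mm2,
                 hull_area_deg2 = area_mm2 / mm_per_deg^2),
            class = "activation_pattern")
}

#' Phosphene size versus amplitude slope
#'
#' Sweeps the amplitude multiple over `k_grid` (default 1.2x-6x threshold),
#' computes the activated convex-hull area at each multiple, and fits an
#' ordinary least-squares line of hull area (deg^2) against the multiple.
#' The slope, in deg^2 per multiple of threshold, is the model's analogue of
#' the psychophysical growth of phosphene size with stimulus amplitude.
#'
#' @param map a [electrode_threshold_map()].
#' @param electrode electrode label.
#' @param k_grid amplitude multiples (>= 3 values for a fit).
#' @param mm_per_deg visual-angle conversion factor.
#' @return list of class `size_amplitude_fit`: `k`, `area_deg2`,
#'   `slope_deg2_per_k`, `intercept_deg2`, `r_squared` (slope is NA when
#'   every area is zero).
#' @export
size_amplitude_slope <- function(map, electrode,
                                 k_grid = c(1.2, 2, 3, 4, 5, 6),
                                 mm_per_deg = 0.288) {
  stopifnot(length(k_grid) >= 3)
  areas <- vapply(k_grid, function(k)
    activation_pattern(map, electrode, k, mm_per_deg)$hull_area_deg2,
    numeric(1))
  if (all(areas == 0))
    return(structure(list(electrode = electrode, k = k_grid,
                          area_deg2 = areas, slope_deg2_per_k = NA_real_,
                          intercept_deg2 = NA_real_, r_squared = NA_real_),
                     class = "size_amplitude_fit"))
  fit <- lm(areas ~ k_grid)
  ## suppressWarnings: summary.lm warns on constructed exact-linear sweeps
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(electrode = electrode, k = k_grid, area_deg2 = areas,
                 slope_deg2_per_k = unname(coef(fit)[2]),
                 intercept_deg2 = unname(coef(fit)[1]),
                 r_squared = r2),
            class = "size_amplitude_fit")
}

#' @export
print.size_amplitude_fit <- function(x, ...) {
  cat(sprintf(
    "<size_amplitude_fit> electrode %s: slope %.2f deg^2/x threshold (R^2 = %.3f)\n",
    x$electrode, x$slope_deg2_per_k, x$r_squared))
  invisible(x)
}
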