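#' Centroidal-Voronoi point placement in a disc (Lloyd's algorithm)
#'
#' Distributes `n` points quasi-uniformly inside a disc by Lloyd relaxation:
#' starting from a uniform random draw, each iteration assigns a dense fixed
#' sample of the disc to its nearest point (a discretised Voronoi partition)
#' and moves every point to the centroid of its cell.  Centroids of subsets
#' of the disc stay inside the disc, so points never leave it.
#'
#' @param n number of points.
#' @param radius disc radius (any length unit; output in the same unit).
#' @param iterations maximum Lloyd iterations.
#' @param seed integer seed (reproducible placement).
#' @param sample_density number of disc sample points per placed point.
#' @return n x 2 matrix of point coordinates centred on the origin.
#' @export
lloyd_disc <- function(n, radius, iterations = 50, seed = 1L,
                       sample_density = 40) {
  stopifnot(n >= 1, radius > 0)
  withr::with_seed(as.integer(seed), {
    m <- max(2000L, as.integer(sample_density * n))
    rr <- radius * sqrt(runif(m))
    th <- runif(m, 0, 2 * pi)
    px <- rr * cos(th); py <- rr * sin(th)
    rs <- radius * sqrt(runif(n))
    ts <- runif(n, 0, 2 * pi)
    cx <- rs * cos(ts); cy <- rs * sin(ts)
    for (it in seq_len(iterations)) {
      d2 <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
      nearest <- max.col(-d2, ties.method = "first")
      nx <- tapply(px, factor(nearest, levels = seq_len(n)), mean)
      ny <- tapply(py, factor(nearest, levels = seq_len(n)), mean)
      keep <- !is.na(nx)
      move <- sqrt((nx[keep] - cx[keep])^2 + (ny[keep] - cy[keep])^2)
      cx[keep] <- nx[keep]; cy[keep] <- ny[keep]
      if (max(move) < 1e-4 * radius) break
    }
    cbind(x = cx, y = cy)
  })
}

#' Place a target RGC population beneath an electrode
#'
#' Lloyd-distributes `n` somata within `radius_um` of the electrode centre
#' (the target population paradigm: 250 somata in a 700 um disc) and records
#' their lateral positions in retinal mm.
#'
#' @param layout an [make_argus2_layout()] layout.
#' @param electrode electrode label.
#' @param n number of somata.
#' @param radius_um placement radius (um).
#' @param seed integer seed.
#' @param iterations Lloyd iterations.
#' @return data.frame of class `soma_population`: `neuron_id`, `x_mm`,
#'   `y_mm`, with the electrode label and parameters as attributes.
#' @export
place_somas <- function(layout, electrode, n = 250, radius_um = 700,
                        seed = 1L, iterations = 50) {
  e <- layout_electrode(layout, electrode)
  xy <- lloyd_disc(n, radius_um / 1000, iterations = iterations, seed = seed)
  out <- data.frame(neuron_id = seq_len(n),
                    x_mm = e$x_mm + xy[, 1], y_mm = e$y_mm + xy[, 2])
  attr(out, "electrode") <- electrode
  attr(out, "radius_um") <- radius_um
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("soma_population", class(out))
  out
}

#' Compartment parameters for neuron construction
#'
#' Morphology defaults for the simplified multi-compartment RGC: a single
#' equivalent-cylinder dendrite (a run-time stand-in for a full dendritic
#' arbor), a spherical soma, an axon hillock, a short high-sodium-density
#' band (the axon initial segment), and an axon that follows the
#' nerve-fiber-layer trajectory to the optic disc.  The soma sits 55 um and
#' the axon 15 um below the inner retinal surface.
#'
#' @param soma_diameter_um,dendrite_length_um,dendrite_diameter_um,
#'   hillock_length_um,hillock_diameter_um,band_length_um,band_diameter_um,
#'   axon_diameter_um section geometry (um).
#' @param proximal_step_um compartment length near the soma (um).
#' @param axon_step_um compartment length along the distal axon (um).
#' @param soma_depth_um,axon_depth_um depths below the inner surface (um).
#' @return list of class `neuron_params`.
#' @export
neuron_params <- function(soma_diameter_um = 20,
                          dendrite_length_um = 200,
                          dendrite_diameter_um = 2,
                          hillock_length_um = 40,
                          hillock_diameter_um = 2,
                          band_length_um = 40,
                          band_diameter_um = 1.5,
                          axon_diameter_um = 1,
                          proximal_step_um = 10,
                          axon_step_um = 25,
                          soma_depth_um = 55,
                          axon_depth_um = 15) {
  structure(as.list(environment()), class = "neuron_params")
}

## Interpolate a resampled trajectory at arc-length positions (mm).
path_at <- function(traj, s_mm) {
  s_grid <- (seq_len(nrow(traj$xy_mm)) - 1) * traj$step_mm
  s_grid[length(s_grid)] <- traj$arc_length_mm
  s_mm <- pmin(s_mm, traj$arc_length_mm)
  cbind(approx(s_grid, traj$xy_mm[, 1], s_mm)$y,
        approx(s_grid, traj$xy_mm[, 2], s_mm)$y)
}

#' Build the compartment geometry of one RGC
#'
#' Chains dendrite - soma - hillock - sodium band - axon.  The axon follows
#' the nerve-fiber trajectory through the soma toward the optic disc; its
#' depth tracks the inner retinal surface at 15 um, while the soma sits at
#' 55 um; the hillock and sodium band ramp between the two depths.  The
#' dendrite extends from the soma away from the axon at soma depth.
#'
#' @param soma_xy_mm soma lateral position (mm).
#' @param geometry a [make_synthetic_retina()] geometry (supplies the inner
#'   surface height).
#' @param params a [neuron_params()].
#' @param traj_params a [trajectory_params()].
#' @return data.frame of class `neuron_geometry`: one row per compartment
#'   with `x_mm`, `y_mm`, `z_mm`, `length_um`, `diameter_um`, `section`
#'   (dendrite/soma/hillock/sodium_band/axon), ordered from dendrite tip to
#'   axon end.
#' @export
build_neuron <- function(soma_xy_mm, geometry,
                         params = neuron_params(),
                         traj_params = trajectory_params()) {
  traj <- soma_to_path(soma_xy_mm, traj_params,
                       step_mm = params$axon_step_um / 2000)
  p <- params

  surface_z <- function(x, y) {
    xc <- pmin(pmax(x, min(geometry$x)), max(geometry$x))
    yc <- pmin(pmax(y, min(geometry$y)), max(geometry$y))
    interp_field(geometry, "inner_z_mm", xc, yc)
  }
  soma_z <- surface_z(soma_xy_mm[1], soma_xy_mm[2]) - p$soma_depth_um / 1000

  ## axon-side sections: arc-length centre positions from the soma edge
  prox_len <- p$hillock_length_um + p$band_length_um
  n_h <- ceiling(p$hillock_length_um / p$proximal_step_um)
  n_b <- ceiling(p$band_length_um / p$proximal_step_um)
  s_h <- p$soma_diameter_um / 2 +
    (seq_len(n_h) - 0.5) * p$hillock_length_um / n_h
  s_b <- p$soma_diameter_um / 2 + p$hillock_length_um +
    (seq_len(n_b) - 0.5) * p$band_length_um / n_b
  ax_start <- p$soma_diameter_um / 2 + prox_len
  ax_total <- traj$arc_length_mm * 1000 - ax_start
  if (ax_total <= 0) stop("axon trajectory shorter than the proximal sections")
  n_a <- max(1L, ceiling(ax_total / p$axon_step_um))
  s_a <- ax_start + (seq_len(n_a) - 0.5) * ax_total / n_a

  mk <- function(s_um, L_um, d_um, section, depth_um) {
    xy <- path_at(traj, s_um / 1000)
    data.frame(x_mm = xy[, 1], y_mm = xy[, 2],
               z_mm = surface_z(xy[, 1], xy[, 2]) - depth_um / 1000,
               length_um = L_um, diameter_um = d_um, section = section,
               stringsAsFactors = FALSE)
  }
  ## depth ramps linearly from soma depth to axon depth across hillock+band
  ramp <- function(s_um) {
    f <- pmin(pmax((s_um - p$soma_diameter_um / 2) / prox_len, 0), 1)
    p$soma_depth_um + f * (p$axon_depth_um - p$soma_depth_um)
  }
  hill <- mk(s_h, p$hillock_length_um / n_h, p$hillock_diameter_um,
             "hillock", ramp(s_h))
  band <- mk(s_b, p$band_length_um / n_b, p$band_diameter_um,
             "sodium_band", ramp(s_b))
  axon <- mk(s_a, ax_total / n_a, p$axon_diameter_um, "axon", p$axon_depth_um)

  soma <- data.frame(x_mm = soma_xy_mm[1], y_mm = soma_xy_mm[2],
                     z_mm = soma_z, length_um = p$soma_diameter_um,
                     diameter_um = p$soma_diameter_um, section = "soma",
                     stringsAsFactors = FALSE)

  ## dendrite: straight, opposite the axon's initial direction, soma depth
  dir0 <- path_at(traj, c(0, 0.05))
  u <- dir0[2, ] - dir0[1, ]
  u <- u / sqrt(sum(u^2))
  n_d <- ceiling(p$dendrite_length_um / (2 * p$proximal_step_um))
  s_d <- p$soma_diameter_um / 2 +
    (seq_len(n_d) - 0.5) * p$dendrite_length_um / n_d
  dx <- soma_xy_mm[1] - u[1] * s_d / 1000
  dy <- soma_xy_mm[2] - u[2] * s_d / 1000
  dend <- data.frame(x_mm = dx, y_mm = dy,
                     z_mm = surface_z(dx, dy) - p$soma_depth_um / 1000,
                     length_um = p$dendrite_length_um / n_d,
                     diameter_um = p$dendrite_diameter_um,
                     section = "dendrite", stringsAsFactors = FALSE)

  out <- rbind(dend[rev(seq_len(n_d)), ], soma, hill, band, axon)
  rownames(out) <- NULL
  attr(out, "phi0") <- traj$phi0
  attr(out, "arc_length_mm") <- traj$arc_length_mm
  class(out) <- c("neuron_geometry", class(out))
  out
}

#' Export neuron geometries as a TSV polyline table
#'
#' Writes one row per compartment centre with the header
#' `neuron_id  point_idx  x_mm  y_mm  z_mm`, a format shared by axon
#' trajectories and full neuron chains.
#'
#' @param neurons a single [build_neuron()] table or a list of them (list
#'   names become neuron ids).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_neuron_tsv <- function(neurons, path) {
  if (inherits(neurons, "neuron_geometry")) neurons <- list(`1` = neurons)
  if (is.null(names(neurons))) names(neurons) <- seq_along(neurons)
  rows <- lapply(names(neurons), function(id) {
    n <- neurons[[id]]
    data.frame(neuron_id = id, point_idx = seq_len(nrow(n)),
               x_mm = n$x_mm, y_mm = n$y_mm, z_mm = n$z_mm)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Remove neurons over degenerated retina
#'
#' Applies the thin-retina exclusion rule: neurons whose soma lies where the
#' retina has degenerated below `floor_um` are removed from the population
#' (the model's proxy for the loss of viable ganglion cells in thinned
#' retina).
#'
#' @param population a [place_somas()] data.frame.
#' @param geometry a [make_synthetic_retina()] geometry.
#' @param floor_um thickness floor (um).
#' @return the retained population; the logical removal mask (TRUE =
#'   removed) is attached as attribute `removed`.
#' @export
apply_thickness_exclusion <- function(population, geometry, floor_um = 100) {
  th <- interp_field(geometry, "thickness_um",
                     population$x_mm, population$y_mm)
  removed <- th < floor_um
  out <- population[!removed, , drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "electrode") <- attr(population, "electrode")
  out
}
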