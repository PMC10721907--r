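#' Configuration for the synthetic virtual-patient retina
#'
#' Assembles the parameter list consumed by [make_synthetic_retina()].  The
#' defaults describe the model domain used throughout: a 25 x 17 mm lateral
#' extent with an 18 mm vitreous column above the inner retinal surface, a
#' 200 um thick retina, and an epiretinal array whose substrate plane floats
#' `standoff_um` above the closest point of the retina.
#'
#' Degeneration patches lower the retinal thickness toward a floor inside a
#' disc (with a smooth cosine edge); fibrosis patches put fibrotic tissue on
#' the array surface, filling the electrode-retina gap from above.  `tilt`
#' expresses the array plane slope in mm of height per mm of lateral
#' distance, which is how a range of electrode-retina distances arises across
#' one array.
#'
#' @param extent_mm lateral domain size c(x, y) in mm.
#' @param grid_spacing_mm lateral grid spacing of the height fields (mm).
#' @param vitreous_height_mm vitreous column height above the retina (mm).
#' @param choroid_thickness_mm choroid layer thickness (mm).
#' @param thickness_mean_um mean retinal thickness (um).
#' @param thickness_roughness_um s.d. of the smooth random thickness
#'   perturbation (um); 0 gives a deterministic field.
#' @param surface_amplitude_um s.d. of the smooth inner-surface height
#'   variation (um).
#' @param roughness_scale_mm correlation length of the random fields (mm).
#' @param standoff_um minimum electrode-face-to-retina gap over the array
#'   footprint (um).
#' @param tilt c(dz/dx, dz/dy) slope of the array substrate plane (mm/mm).
#' @param degeneration list of patches, each
#'   `list(center_xy = c(x, y) mm, radius_mm, thickness_um, edge_mm)`.
#' @param fibrosis list of patches on the array surface, each
#'   `list(center_xy, radius_mm, thickness_um, edge_mm)`.
#' @return A list of class `retina_config`.
#' @export
retina_config <- function(extent_mm = c(25, 17),
                          grid_spacing_mm = 0.1,
                          vitreous_height_mm = 18,
                          choroid_thickness_mm = 0.25,
                          thickness_mean_um = 200,
                          thickness_roughness_um = 0,
                          surface_amplitude_um = 0,
                          roughness_scale_mm = 1,
                          standoff_um = 100,
                          tilt = c(0, 0),
                          degeneration = list(),
                          fibrosis = list()) {
  cfg <- as.list(environment())
  class(cfg) <- "retina_config"
  cfg
}

## Smooth unit-variance Gaussian random field on an nx x ny grid: white noise
## convolved with a separable Gaussian kernel of the given correlation length.
smooth_random_field <- function(nx, ny, spacing_mm, scale_mm) {
  z <- matrix(rnorm(nx * ny), nx, ny)
  if (scale_mm <= 0) return(z)
  s <- scale_mm / spacing_mm
  half <- max(1L, ceiling(3 * s))
  k <- exp(-0.5 * (seq(-half, half) / s)^2)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[n - seq_len(half) + 1]))
    stats::filter(vp, k, sides = 2)[half + seq_len(n)]
  }
  z <- apply(z, 2, conv1)
  z <- t(apply(z, 1, conv1))
  sdz <- stats::sd(as.vector(z))
  if (sdz > 0) z <- z / sdz
  z
}

## Radial patch weight: 1 inside radius, cosine taper over edge_mm.
patch_weight <- function(xg, yg, patch) {
  d <- sqrt(outer(xg - patch$center_xy[1], yg - patch$center_xy[2],
                  function(a, b) a^2 + b^2))
  edge <- if (is.null(patch$edge_mm)) 0.2 else patch$edge_mm
  w <- matrix(0, length(xg), length(yg))
  w[d <= patch$radius_mm] <- 1
  tap <- d > patch$radius_mm & d < patch$radius_mm + edge
  w[tap] <- 0.5 * (1 + cos(pi * (d[tap] - patch$radius_mm) / edge))
  w
}

#' Generate a synthetic virtual-patient retinal geometry
#'
#' Produces the gridded inner-surface height, retinal thickness, and fibrosis
#' thickness fields plus the array substrate pose that downstream stages
#' consume, emulating what would otherwise be measured from OCT B-scans.  The
#' array plane is `z = z0 + tilt[1] x + tilt[2] y` with `z0` chosen so the
#' minimum gap to the inner retinal surface over the array footprint equals
#' `standoff_um`; a configuration whose plane would intersect the retina is
#' rejected.  Fibrosis hangs from the substrate plane and is clipped to the
#' local gap, so an apposed electrode reports a distance equal to its
#' fibrosis thickness.
#'
#' @param config a [retina_config()] list.
#' @param layout an [make_argus2_layout()] layout (defines the array
#'   footprint used to anchor the substrate plane).
#' @param seed integer seed; the same seed reproduces the same fields.
#' @return An object of class `retina_geometry`: lateral grid vectors `x`,
#'   `y` (mm), matrices `inner_z_mm`, `thickness_um`, `fibrosis_um`
#'   (nx x ny), the `array_plane` (`z0`, `ax`, `ay`), and the domain sizes.
#' @export
make_synthetic_retina <- function(config = retina_config(),
                                  layout = make_argus2_layout(),
                                  seed = 1L) {
  cfg <- config
  nx <- round(cfg$extent_mm[1] / cfg$grid_spacing_mm) + 1L
  ny <- round(cfg$extent_mm[2] / cfg$grid_spacing_mm) + 1L
  xg <- seq(-cfg$extent_mm[1] / 2, cfg$extent_mm[1] / 2, length.out = nx)
  yg <- seq(-cfg$extent_mm[2] / 2, cfg$extent_mm[2] / 2, length.out = ny)

  fields <- withr::with_seed(as.integer(seed), {
    inner <- matrix(0, nx, ny)
    if (cfg$surface_amplitude_um > 0)
      inner <- inner + cfg$surface_amplitude_um / 1000 *
        smooth_random_field(nx, ny, cfg$grid_spacing_mm, cfg$roughness_scale_mm)
    thick <- matrix(cfg$thickness_mean_um, nx, ny)
    if (cfg$thickness_roughness_um > 0)
      thick <- thick + cfg$thickness_roughness_um *
        smooth_random_field(nx, ny, cfg$grid_spacing_mm, cfg$roughness_scale_mm)
    list(inner = inner, thick = thick)
  })
  inner <- fields$inner
  thick <- fields$thick

  for (p in cfg$degeneration) {
    w <- patch_weight(xg, yg, p)
    thick <- thick * (1 - w) + p$thickness_um * w
  }
  thick[thick < 0] <- 0

  ## Anchor the substrate plane over the array footprint.
  ol <- layout$substrate_outline
  in_fp_x <- xg >= min(ol[, 1]) & xg <= max(ol[, 1])
  in_fp_y <- yg >= min(ol[, 2]) & yg <= max(ol[, 2])
  if (!any(in_fp_x) || !any(in_fp_y))
    stop("array footprint lies outside the geometry grid")
  plane_rel <- outer(xg * cfg$tilt[1], yg * cfg$tilt[2], "+")
  gap_rel <- plane_rel - inner                 # plane with z0 = 0
  z0 <- cfg$standoff_um / 1000 - min(gap_rel[in_fp_x, in_fp_y])
  gap <- gap_rel + z0
  if (any(gap[in_fp_x, in_fp_y] < -1e-9))
    stop("array plane intersects the retina; increase standoff_um or reduce tilt")

  fib <- matrix(0, nx, ny)
  for (p in cfg$fibrosis) {
    w <- patch_weight(xg, yg, p)
    fib <- pmax(fib, p$thickness_um * w)
  }
  fib <- pmin(fib, pmax(gap, 0) * 1000)        # fibrosis cannot exceed the gap

  structure(
    list(x = xg, y = yg,
         inner_z_mm = inner, thickness_um = thick, fibrosis_um = fib,
         array_plane = list(z0 = z0, ax = cfg$tilt[1], ay = cfg$tilt[2]),
         extent_mm = cfg$extent_mm,
         grid_spacing_mm = cfg$grid_spacing_mm,
         vitreous_height_mm = cfg$vitreous_height_mm,
         choroid_thickness_mm = cfg$choroid_thickness_mm,
         config = cfg, seed = as.integer(seed)),
    class = "retina_geometry"
  )
}

#' @export
print.retina_geometry <- function(x, ...) {
  cat(sprintf(
    "<retina_geometry> %g x %g mm at %g mm spacing; thickness %.0f-%.0f um\n",
    x$extent_mm[1], x$extent_mm[2], x$grid_spacing_mm,
    min(x$thickness_um), max(x$thickness_um)))
  invisible(x)
}

## Bilinear interpolation of a gridded field at arbitrary lateral points.
interp_field <- function(geometry, field, x, y) {
  xg <- geometry$x; yg <- geometry$y
  f <- geometry[[field]]
  ix <- findInterval(x, xg, rightmost.closed = TRUE)
  iy <- findInterval(y, yg, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(xg) - 1L)
  iy <- pmin(pmax(iy, 1L), length(yg) - 1L)
  tx <- (x - xg[ix]) / (xg[ix + 1] - xg[ix])
  ty <- (y - yg[iy]) / (yg[iy + 1] - yg[iy])
  f[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    f[cbind(ix + 1, iy)] * tx * (1 - ty) +
    f[cbind(ix, iy + 1)] * (1 - tx) * ty +
    f[cbind(ix + 1, iy + 1)] * tx * ty
}

array_plane_z <- function(geometry, x, y) {
  p <- geometry$array_plane
  p$z0 + p$ax * x + p$ay * y
}

#' Per-electrode geometric measurements
#'
#' Samples the geometry fields at each electrode centre, reproducing the
#' B-scan measurements a clinician would make: the electrode-retina distance
#' (vertical gap from the electrode face to the inner retinal surface),
#' retinal thickness, and fibrotic tissue thickness at the same lateral
#' point.  An electrode whose centre falls outside the lateral grid is
#' flagged not visible and is excluded downstream.  For an apposed electrode
#' the gap is fully occupied by fibrosis, so distance equals fibrosis
#' thickness.
#'
#' @param geometry a [make_synthetic_retina()] geometry.
#' @param layout an [make_argus2_layout()] layout.
#' @return data.frame with one row per electrode: `label`, `x_mm`, `y_mm`,
#'   `distance_mm`, `thickness_mm`, `fibrosis_mm`, `impedance_kohm` (NA until
#'   synthesised), `threshold_uA` (NA until synthesised or supplied),
#'   `visible`.
#' @export
measure_electrodes <- function(geometry, layout) {
  el <- layout$electrodes
  visible <- el$x_mm >= min(geometry$x) & el$x_mm <= max(geometry$x) &
    el$y_mm >= min(geometry$y) & el$y_mm <= max(geometry$y)
  out <- data.frame(
    label = el$label, x_mm = el$x_mm, y_mm = el$y_mm,
    distance_mm = NA_real_, thickness_mm = NA_real_, fibrosis_mm = NA_real_,
    impedance_kohm = NA_real_, threshold_uA = NA_real_,
    visible = visible, stringsAsFactors = FALSE
  )
  if (any(visible)) {
    xv <- el$x_mm[visible]; yv <- el$y_mm[visible]
    inner <- interp_field(geometry, "inner_z_mm", xv, yv)
    gap <- array_plane_z(geometry, xv, yv) - inner
    fib <- interp_field(geometry, "fibrosis_um", xv, yv) / 1000
    out$distance_mm[visible] <- pmax(gap, fib)
    out$thickness_mm[visible] <-
      interp_field(geometry, "thickness_um", xv, yv) / 1000
    out$fibrosis_mm[visible] <- fib
  }
  out
}

#' Synthesise perceptual thresholds (and impedances) for an electrode table
#'
#' Fills the `threshold_uA` column with a linear model of the geometric
#' covariates plus Gaussian noise, emulating the structure assumed by
#' electrode-level regression analyses (threshold rising with
#' electrode-retina distance, falling with retinal thickness):
#' `threshold = intercept + sum(coefficients[v] * v) + N(0, noise_sd)`,
#' clipped below at `floor_uA`.  If `impedance_kohm` is missing it is drawn
#' first as `impedance = impedance_mean + impedance_slope * distance + noise`
#' so it can itself act as a covariate.
#'
#' @param measurements data.frame from [measure_electrodes()].
#' @param coefficients named list/vector of regression coefficients in uA per
#'   unit covariate; names among `intercept`, `distance_mm`, `thickness_mm`,
#'   `fibrosis_mm`, `impedance_kohm`.
#' @param noise_sd s.d. of the additive Gaussian threshold noise (uA).
#' @param seed integer seed (reproducible noise realisation).
#' @param floor_uA lower clip for generated thresholds (uA).
#' @param impedance list with `mean` (kohm), `slope` (kohm/mm of distance)
#'   and `sd` used only when impedance is absent.
#' @return the measurement data.frame with `threshold_uA` (and possibly
#'   `impedance_kohm`) filled for visible electrodes.
#' @export
synth_thresholds <- function(measurements,
                             coefficients = list(intercept = 50,
                                                 distance_mm = 500,
                                                 thickness_mm = -300),
                             noise_sd = 10, seed = 1L, floor_uA = 1,
                             impedance = list(mean = 20, slope = -15, sd = 2)) {
  stopifnot(noise_sd >= 0, floor_uA > 0)
  m <- measurements
  vis <- which(m$visible & !is.na(m$distance_mm))
  withr::with_seed(as.integer(seed), {
    if (all(is.na(m$impedance_kohm[vis]))) {
      m$impedance_kohm[vis] <- pmax(
        impedance$mean + impedance$slope * m$distance_mm[vis] +
          rnorm(length(vis), 0, impedance$sd), 0.1)
    }
    co <- as.list(coefficients)
    thr <- rep(if (is.null(co$intercept)) 0 else co$intercept, length(vis))
    for (v in setdiff(names(co), "intercept"))
      thr <- thr + co[[v]] * m[[v]][vis]
    m$threshold_uA[vis] <- pmax(thr + rnorm(length(vis), 0, noise_sd), floor_uA)
  })
  m
}

#' Write / read an electrode measurement table as TSV
#'
#' @param measurements data.frame as produced by [measure_electrodes()] /
#'   [synth_thresholds()].
#' @param path file path.
#' @return `read_measurements` returns the data.frame; `write_measurements`
#'   returns `path` invisibly.
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("label", "distance_mm", "thickness_mm", "fibrosis_mm",
            "impedance_kohm", "threshold_uA", "visible")
  write.table(measurements[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
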