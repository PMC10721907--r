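#' Parameters of the nerve-fiber-layer trajectory model
#'
#' Retinal ganglion cell axons run from the soma to the optic disc along
#' stereotyped arcuate paths.  This package uses the Jansonius et al. (2009)
#' nerve-fiber bundle description: in modified polar coordinates
#' \eqn{(r, \phi)} centred on the optic disc (angle measured from the
#' disc-to-nasal direction, positive superior), a bundle launched at angle
#' \eqn{\phi_0} from the disc circle \eqn{r_0} follows
#' \deqn{\phi(r) = \phi_0 + b(\phi_0)\,(r - r_0)^{c(\phi_0)},}
#' with hemisphere-specific coefficient functions
#' \eqn{b = \exp(\beta_s + 3.9\tanh(-(\phi_0-121)/14))},
#' \eqn{c = 1.9 + 1.4\tanh((\phi_0-121)/14)} for the superior retina
#' (\eqn{\phi_0 > 0}) and
#' \eqn{b = -\exp(\beta_i + 1.5\tanh(-(-\phi_0-90)/25))},
#' \eqn{c = 1.0 + 0.5\tanh((-\phi_0-90)/25)} for the inferior retina.
#' The defaults (`beta_sup = -1.9`, `beta_inf = 0.5`, `r0 = 4` deg, disc
#' centre 15 deg nasal / 2 deg superior of the fovea) are the coefficients
#' used by common phosphene-modelling software; every constant can be
#' overridden here.  Visual angle converts to retinal distance at
#' 288 um/degree.
#'
#' @param optic_disc_deg c(nasal, superior) position of the optic disc
#'   centre relative to the fovea, degrees.
#' @param r0_deg launch radius at the disc (deg).
#' @param beta_sup,beta_inf hemisphere curvature offsets.
#' @param mm_per_deg retinal mm per degree of visual angle.
#' @param max_eccentricity_deg sampling limit for trajectories (distance
#'   from the disc, deg).
#' @return list of class `trajectory_params`.
#' @export
trajectory_params <- function(optic_disc_deg = c(15, 2), r0_deg = 4,
                              beta_sup = -1.9, beta_inf = 0.5,
                              mm_per_deg = 0.288,
                              max_eccentricity_deg = 45) {
  stopifnot(r0_deg > 0, mm_per_deg > 0)
  structure(as.list(environment()), class = "trajectory_params")
}

## Coefficients b, c for a launch angle phi0 (deg).  phi0 == 0 (the temporal
## raphe ambiguity) is assigned to the inferior hemisphere.
jansonius_coefs <- function(phi0, params) {
  if (phi0 > 0) {
    list(b = exp(params$beta_sup + 3.9 * tanh(-(phi0 - 121) / 14)),
         c = 1.9 + 1.4 * tanh((phi0 - 121) / 14))
  } else {
    list(b = -exp(params$beta_inf + 1.5 * tanh(-(-phi0 - 90) / 25)),
         c = 1.0 + 0.5 * tanh((-phi0 - 90) / 25))
  }
}

## Disc-centred polar <-> fovea-centred Cartesian (degrees).  The polar
## x'-axis points nasally from the disc, so the temporal raphe sits at
## phi = +/-180; the global frame has +x temporal, +y superior.
polar_to_deg <- function(r, phi, params) {
  od <- params$optic_disc_deg
  cbind(x = -od[1] - r * cos(phi * pi / 180),
        y = od[2] + r * sin(phi * pi / 180))
}

deg_to_polar <- function(x, y, params) {
  od <- params$optic_disc_deg
  xp <- -(x + od[1])
  yp <- y - od[2]
  list(r = sqrt(xp^2 + yp^2), phi = atan2(yp, xp) * 180 / pi)
}

#' Nerve-fiber trajectory for a launch angle
#'
#' Integrates the bundle equation \eqn{\phi(r)} outward from the disc circle
#' and returns the path in fovea-centred visual-field degrees.  Trajectories
#' are truncated where they would cross the temporal raphe
#' (\eqn{|\phi| > 180}), which the underlying fits do not constrain at
#' extreme eccentricity.
#'
#' @param phi0 launch angle at the disc, degrees in (-180, 180];
#'   positive = superior retina.
#' @param params a [trajectory_params()].
#' @param r_max maximum eccentricity from the disc (deg).
#' @param dr radial sampling step (deg).
#' @return matrix with columns `x`, `y` (deg), plus attributes `r`, `phi`
#'   (the polar samples) and `phi0`.
#' @export
jansonius_path <- function(phi0, params = trajectory_params(),
                           r_max = params$max_eccentricity_deg, dr = 0.05) {
  if (phi0 <= -180 || phi0 > 180)
    stop("phi0 must lie in (-180, 180] degrees")
  r <- seq(params$r0_deg, r_max, by = dr)
  co <- jansonius_coefs(phi0, params)
  phi <- phi0 + co$b * (r - params$r0_deg)^co$c
  keep <- abs(phi) <= 180
  r <- r[keep]; phi <- phi[keep]
  out <- polar_to_deg(r, phi, params)
  attr(out, "r") <- r
  attr(out, "phi") <- phi
  attr(out, "phi0") <- phi0
  out
}

#' Axon trajectory through a soma position
#'
#' Finds the launch angle whose nerve-fiber bundle passes through the given
#' soma (a scalar root-find over \eqn{\phi_0} in the soma's hemisphere;
#' somata exactly on the raphe are assigned to the inferior hemisphere) and
#' returns the soma-to-disc portion of the path resampled at a fixed arc
#' step in retinal mm.
#'
#' @param soma_xy_mm soma position c(x, y) in retinal mm (fovea origin,
#'   +x temporal, +y superior).
#' @param params a [trajectory_params()].
#' @param step_mm arc-length resampling step (mm).
#' @return object of class `axon_trajectory`: list with `xy_mm` (matrix,
#'   soma first, optic-disc end last), `phi0`, `arc_length_mm`.
#' @export
soma_to_path <- function(soma_xy_mm, params = trajectory_params(),
                         step_mm = 0.025) {
  soma_deg <- soma_xy_mm / params$mm_per_deg
  pol <- deg_to_polar(soma_deg[1], soma_deg[2], params)
  if (pol$r <= params$r0_deg)
    stop("soma lies inside the peripapillary launch circle (r0)")
  if (pol$r > params$max_eccentricity_deg)
    stop("soma lies beyond the modelled eccentricity range")
  target <- pol$phi
  dist_pow <- function(phi0) {
    co <- jansonius_coefs(phi0, params)
    phi0 + co$b * (pol$r - params$r0_deg)^co$c - target
  }
  eps <- 1e-9
  if (target > 0) {
    lo <- eps; hi <- target              # superior: b > 0, so phi0 < phi
  } else {
    lo <- target; hi <- -eps             # inferior: b < 0, so phi0 > phi
    if (target == 0) { lo <- -30; hi <- -eps }
  }
  flo <- dist_pow(lo); fhi <- dist_pow(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop(sprintf("no nerve-fiber bundle through soma at (%.3f, %.3f) mm",
                 soma_xy_mm[1], soma_xy_mm[2]))
  phi0 <- uniroot(dist_pow, c(lo, hi), tol = 1e-9)$root

  ## dense path from soma to the disc, then resample by arc length
  co <- jansonius_coefs(phi0, params)
  r <- seq(pol$r, params$r0_deg, by = -0.02)
  if (r[length(r)] != params$r0_deg) r <- c(r, params$r0_deg)
  phi <- phi0 + co$b * (r - params$r0_deg)^co$c
  xy <- polar_to_deg(r, phi, params) * params$mm_per_deg
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  s_new <- seq(0, total, by = step_mm)
  if (s_new[length(s_new)] < total) s_new <- c(s_new, total)
  xy_mm <- cbind(x = approx(s, xy[, 1], s_new)$y,
                 y = approx(s, xy[, 2], s_new)$y)
  structure(list(xy_mm = xy_mm, phi0 = phi0, arc_length_mm = total,
                 step_mm = step_mm),
            class = "axon_trajectory")
}

#' Visual-angle / retinal-distance conversion
#'
#' Scalar scaling about the foveal origin at 288 um per degree (overridable
#' through `mm_per_deg`).
#'
#' @param points_deg,points_mm numeric vector/matrix of coordinates.
#' @param mm_per_deg conversion factor (mm/deg).
#' @return converted coordinates with the same shape.
#' @export
degrees_to_mm <- function(points_deg, mm_per_deg = 0.288) {
  points_deg * mm_per_deg
}

#' @rdname degrees_to_mm
#' @export
mm_to_degrees <- function(points_mm, mm_per_deg = 0.288) {
  points_mm / mm_per_deg
}
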