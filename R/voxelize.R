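#' Tissue conductivity table
#'
#' Conductivities (S/m) assigned to each model domain, and the retinal
#' pigment epithelium (RPE) contact-impedance parameters.  The RPE is not
#' resolved as a voxel layer; it enters as a thin-sheet interface conductance
#' `g = sigma_rpe / thickness_rpe` (default 0.001 S/m over 10 um, i.e.
#' 100 S/m^2) on every retina/choroid voxel face.  The array substrate is a
#' perfect insulator (sigma = 0).
#'
#' @param vitreous,retina,fibrosis,choroid,platinum,substrate conductivities
#'   in S/m.
#' @param rpe_sigma RPE conductivity (S/m).
#' @param rpe_thickness_um RPE thickness (um).
#' @return named list with the domain conductivities and
#'   `rpe_conductance_S_m2`.
#' @export
conductivity_table <- function(vitreous = 1.5, retina = 0.100,
                               fibrosis = 0.15, choroid = 0.503,
                               platinum = 9.43e6, substrate = 0,
                               rpe_sigma = 0.001, rpe_thickness_um = 10) {
  list(vitreous = vitreous, retina = retina, fibrosis = fibrosis,
       choroid = choroid, platinum = platinum, substrate = substrate,
       rpe_sigma = rpe_sigma, rpe_thickness_um = rpe_thickness_um,
       rpe_conductance_S_m2 = rpe_sigma / (rpe_thickness_um * 1e-6))
}

DOMAIN_LEVELS <- c("vitreous", "retina", "fibrosis", "choroid",
                   "platinum", "substrate")

#' Voxelize a retinal geometry into a conductivity grid
#'
#' Rasterises the layered geometry onto a regular cubic voxel grid over a
#' lateral subdomain (by default centred on the active electrode of
#' interest), assigning a domain label and conductivity to every voxel.
#' Layers per lateral column, bottom to top: choroid (down to the domain
#' floor), retina, the electrode-retina gap (vitreous, topped by fibrosis
#' hanging from the substrate where present), the substrate slab with
#' platinum voxels in its bottom layer under each electrode face, and
#' vitreous above.  Retina/choroid interface faces carry the RPE contact
#' conductance.
#'
#' @param geometry a [make_synthetic_retina()] geometry.
#' @param layout an [make_argus2_layout()] layout.
#' @param resolution_um voxel edge length (um).  Must resolve the electrode
#'   diameter with at least 4 voxels.
#' @param conductivity a [conductivity_table()].
#' @param center_xy lateral centre of the subdomain (mm); default the centre
#'   of `electrode` if given, else c(0, 0).
#' @param electrode optional electrode label used to centre the subdomain.
#' @param lateral_extent_mm subdomain lateral size c(x, y) in mm.
#' @param z_above_mm vitreous height retained above the substrate (mm).
#' @param substrate_thickness_um substrate slab thickness (um; at least one
#'   voxel is used).
#' @return An object of class `conductivity_grid`: voxel-centre coordinate
#'   vectors `x`, `y`, `z` (mm), 3-D arrays `sigma` (S/m) and `label`
#'   (integer, levels `vitreous`, `retina`, `fibrosis`, `choroid`,
#'   `platinum`, `substrate`), per-electrode platinum voxel indices, and the
#'   RPE interface conductance.
#' @export
voxelize <- function(geometry, layout, resolution_um = 25,
                     conductivity = conductivity_table(),
                     center_xy = NULL, electrode = NULL,
                     lateral_extent_mm = c(3, 3), z_above_mm = 1,
                     substrate_thickness_um = 100) {
  if (resolution_um > layout$diameter_um / 4)
    stop(sprintf(
      "resolution %g um too coarse: fewer than 4 voxels across a %g um electrode",
      resolution_um, layout$diameter_um))
  if (is.null(center_xy)) {
    center_xy <- if (is.null(electrode)) c(0, 0) else {
      e <- layout_electrode(layout, electrode)
      c(e$x_mm, e$y_mm)
    }
  }
  h <- resolution_um / 1000                      # voxel edge, mm
  nx <- max(8L, round(lateral_extent_mm[1] / h))
  ny <- max(8L, round(lateral_extent_mm[2] / h))
  xg <- center_xy[1] + (seq_len(nx) - (nx + 1) / 2) * h
  yg <- center_xy[2] + (seq_len(ny) - (ny + 1) / 2) * h

  ## Column-wise layer boundaries at voxel centres.  The substrate paddle
  ## exists only inside the layout's substrate outline; elsewhere the gap
  ## region continues as vitreous all the way up.
  XY <- expand.grid(x = xg, y = yg)
  inner <- interp_field(geometry, "inner_z_mm", XY$x, XY$y)
  thick <- interp_field(geometry, "thickness_um", XY$x, XY$y) / 1000
  fib <- interp_field(geometry, "fibrosis_um", XY$x, XY$y) / 1000
  plane <- array_plane_z(geometry, XY$x, XY$y)
  ol <- layout$substrate_outline
  in_paddle <- XY$x >= min(ol[, 1]) & XY$x <= max(ol[, 1]) &
    XY$y >= min(ol[, 2]) & XY$y <= max(ol[, 2])
  if (any(plane[in_paddle] < inner[in_paddle] - 1e-9))
    stop("substrate plane intersects the retina inside the subdomain")
  slab_mm <- max(substrate_thickness_um / 1000, h)
  plane[!in_paddle] <- Inf                        # no array outside paddle
  fib[!in_paddle] <- 0

  z_lo <- min(inner - thick) - geometry$choroid_thickness_mm
  z_top_paddle <- if (any(in_paddle)) max(plane[in_paddle]) + slab_mm else
    max(inner)
  z_hi <- z_top_paddle + z_above_mm
  nz <- ceiling((z_hi - z_lo) / h)
  zg <- z_lo + (seq_len(nz) - 0.5) * h

  lab <- array(4L, dim = c(nx, ny, nz))          # default: choroid
  zi <- rep(zg, each = nx * ny)
  innerv <- rep(inner, nz)
  thickv <- rep(thick, nz)
  fibv <- rep(fib, nz)
  planev <- rep(plane, nz)
  sub_top <- planev + slab_mm

  lab[zi >= innerv - thickv & zi < innerv] <- 2L           # retina
  lab[zi >= innerv & zi < planev] <- 1L                    # gap: vitreous
  lab[zi >= planev - fibv & zi < planev & zi >= innerv] <- 3L  # fibrosis
  lab[zi >= planev & zi < sub_top] <- 6L                   # substrate slab
  lab[zi >= sub_top & is.finite(sub_top)] <- 1L            # vitreous above

  ## Platinum discs: bottom voxel layer of the slab under each electrode face.
  el <- layout$electrodes
  rad_mm <- layout$diameter_um / 2000
  keep <- el$x_mm > min(xg) - rad_mm & el$x_mm < max(xg) + rad_mm &
    el$y_mm > min(yg) - rad_mm & el$y_mm < max(yg) + rad_mm
  electrode_voxels <- list()
  if (any(keep) && any(in_paddle)) {
    ## face layer per column: first voxel centre at or above the plane
    kf <- floor((plane - z_lo) / h - 0.5) + 1L
    adj <- is.finite(plane) & (z_lo + (kf - 0.5) * h < plane - 1e-12)
    kf[adj] <- kf[adj] + 1L
    ok <- is.finite(plane) & kf >= 1L & kf <= nz
    face <- (seq_len(nx * ny) + (kf - 1L) * nx * ny)[ok]
    fx <- XY$x[ok]; fy <- XY$y[ok]
    for (j in which(keep)) {
      inside <- (fx - el$x_mm[j])^2 + (fy - el$y_mm[j])^2 <= rad_mm^2
      if (any(inside)) {
        lab[face[inside]] <- 5L
        electrode_voxels[[el$label[j]]] <- face[inside]
      }
    }
  }

  sig_by_label <- c(conductivity$vitreous, conductivity$retina,
                    conductivity$fibrosis, conductivity$choroid,
                    conductivity$platinum, conductivity$substrate)
  sigma <- array(sig_by_label[lab], dim = dim(lab))

  structure(
    list(x = xg, y = yg, z = zg, resolution_um = resolution_um,
         sigma = sigma, label = lab, label_levels = DOMAIN_LEVELS,
         electrode_voxels = electrode_voxels,
         rpe_conductance_S_m2 = conductivity$rpe_conductance_S_m2,
         conductivity = conductivity),
    class = "conductivity_grid"
  )
}

#' @export
print.conductivity_grid <- function(x, ...) {
  cat(sprintf("<conductivity_grid> %d x %d x %d voxels at %g um (%d electrodes)\n",
              length(x$x), length(x$y), length(x$z), x$resolution_um,
              length(x$electrode_voxels)))
  invisible(x)
}
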