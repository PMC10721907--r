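#' Solver configuration for the volume-conductor problem
#'
#' @param active_electrode label of the electrode injecting current.
#' @param tolerance relative-residual stopping criterion for the conjugate
#'   gradient solve; must lie in (0, 1e-3].
#' @param max_iterations iteration cap for the linear solve.
#' @param injected_current injected current in amperes (default 1, i.e. the
#'   solution is the unit field; by linearity other amplitudes are scalings).
#' @param inactive_treatment `"floating"` keeps inactive platinum discs in
#'   the system as equipotential zero-net-current supernodes (a floating
#'   potential condition); `"remove"` deletes them (treats them as
#'   substrate).
#' @param boundary `"choroid"` (the patient-model condition: Dirichlet 0 V
#'   on the outer choroid face at the bottom of the grid, insulating
#'   elsewhere) or `"open"` (a ballistic far-field truncation: every bottom
#'   and side boundary face is tied to 0 V through the conductance
#'   `sigma * A / r` of the analytic `1/r` far field, `r` being the distance
#'   to the active electrode).  The open boundary emulates an unbounded
#'   medium on a compact grid and is what the homogeneous-medium validation
#'   against [analytic_disc_potential()] uses.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(active_electrode, tolerance = 1e-6,
                          max_iterations = 20000L, injected_current = 1,
                          inactive_treatment = c("floating", "remove"),
                          boundary = c("choroid", "open")) {
  stopifnot(is.character(active_electrode), length(active_electrode) == 1,
            tolerance > 0, tolerance <= 1e-3, max_iterations >= 1)
  structure(list(active_electrode = active_electrode, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 injected_current = injected_current,
                 inactive_treatment = match.arg(inactive_treatment),
                 boundary = match.arg(boundary)),
            class = "solver_config")
}

## Jacobi-preconditioned conjugate gradient for a sparse SPD system.
cg_solve <- function(A, b, tol, maxit) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, residual = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) return(list(x = x, iterations = it, residual = res))
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf(
    "field solve did not converge in %d iterations (relative residual %.3g)",
    maxit, res))
}

## Face list of the voxel grid for one axis: linear index pairs (lo, hi).
axis_faces <- function(dims, axis) {
  idx <- array(seq_len(prod(dims)), dim = dims)
  switch(axis,
         x = list(lo = as.vector(idx[-dims[1], , , drop = FALSE]),
                  hi = as.vector(idx[-1, , , drop = FALSE])),
         y = list(lo = as.vector(idx[, -dims[2], , drop = FALSE]),
                  hi = as.vector(idx[, -1, , drop = FALSE])),
         z = list(lo = as.vector(idx[, , -dims[3], drop = FALSE]),
                  hi = as.vector(idx[, , -1, drop = FALSE])))
}

#' Solve the quasi-static field for a unit-current electrode
#'
#' Finite-volume discretisation of \eqn{\nabla\cdot(\sigma\nabla V)=0} on the
#' voxel grid.  Face conductances are harmonic means of the adjacent voxel
#' conductivities; retina/choroid faces add the RPE thin-sheet conductance in
#' series.  Each electrode's platinum voxels are merged into one supernode,
#' so the active electrode is an equipotential terminal injecting the
#' configured current and every inactive electrode satisfies a floating
#' potential condition (single potential, zero net current).  The outer
#' choroid face (bottom of the grid) is the Dirichlet 0 V ground; all other
#' outer boundaries are insulating.  The symmetric positive-definite system
#' is solved by Jacobi-preconditioned conjugate gradients on the
#' ground-connected component of the grid.
#'
#' @param grid a [voxelize()] conductivity grid.
#' @param config a [solver_config()].
#' @return An object of class `field_solution`: voxel-centre coordinates,
#'   3-D array `potential` (V for the configured current; V/A when the
#'   current is 1), the active electrode, the achieved residual and
#'   iteration count, and `ground_flux_A` (discrete current through the
#'   ground face, for conservation audits).
#' @export
solve_unit_field <- function(grid, config) {
  lab <- grid$label
  dims <- dim(lab)
  nvox <- prod(dims)
  h_m <- grid$resolution_um * 1e-6

  if (!config$active_electrode %in% names(grid$electrode_voxels))
    stop("active electrode ", config$active_electrode,
         " has no platinum voxels in this grid")

  sigma <- grid$sigma
  if (config$inactive_treatment == "remove") {
    for (lbl in setdiff(names(grid$electrode_voxels), config$active_electrode))
      sigma[grid$electrode_voxels[[lbl]]] <- 0
  }
  conductive <- sigma > 0

  ## Faces between two conductive voxels, with conductances in siemens.
  inv_sig <- ifelse(conductive, 1 / sigma, Inf)
  face_lo <- integer(0); face_hi <- integer(0); face_G <- numeric(0)
  g_rpe <- grid$rpe_conductance_S_m2
  for (ax in c("x", "y", "z")) {
    f <- axis_faces(dims, ax)
    ok <- conductive[f$lo] & conductive[f$hi]
    lo <- f$lo[ok]; hi <- f$hi[ok]
    G <- 2 * h_m / (inv_sig[lo] + inv_sig[hi])
    rpe <- (lab[lo] == 2L & lab[hi] == 4L) | (lab[lo] == 4L & lab[hi] == 2L)
    if (any(rpe) && is.finite(g_rpe))
      G[rpe] <- 1 / (1 / G[rpe] + 1 / (g_rpe * h_m^2))
    face_lo <- c(face_lo, lo); face_hi <- c(face_hi, hi)
    face_G <- c(face_G, G)
  }

  ## Ground attachments.  "choroid": bottom z-layer (outer choroid face),
  ## Dirichlet through the half-voxel conductance.  "open": bottom and side
  ## boundary voxels tied to 0 V through the 1/r far-field conductance.
  if (is.null(config$boundary) || config$boundary == "choroid") {
    bottom <- which(slice.index(lab, 3) == 1 & conductive)
    G_ground <- 2 * sigma[bottom] * h_m
  } else {
    on_boundary <- slice.index(lab, 3) == 1 |
      slice.index(lab, 1) %in% c(1L, dims[1]) |
      slice.index(lab, 2) %in% c(1L, dims[2])
    bottom <- which(on_boundary & conductive)
    act0 <- grid$electrode_voxels[[config$active_electrode]]
    ai <- arrayInd(act0, dims)
    center <- c(mean(grid$x[ai[, 1]]), mean(grid$y[ai[, 2]]),
                mean(grid$z[ai[, 3]]))
    bi <- arrayInd(bottom, dims)
    r_m <- pmax(h_m, 1e-3 * sqrt((grid$x[bi[, 1]] - center[1])^2 +
                                   (grid$y[bi[, 2]] - center[2])^2 +
                                   (grid$z[bi[, 3]] - center[3])^2))
    G_ground <- sigma[bottom] * h_m^2 / r_m
  }

  ## Ground-connected component of the conductive voxel graph.
  comp <- .uf_components(face_lo, face_hi, nvox)
  reach <- logical(nvox)
  reach[conductive] <- comp[conductive] %in% unique(comp[bottom])
  act_vox <- grid$electrode_voxels[[config$active_electrode]]
  if (!any(reach[act_vox]))
    stop("no conductive path from electrode ", config$active_electrode,
         " to ground")

  ## Node numbering on the reachable set, with per-electrode merging.
  node_of <- integer(nvox)
  solve_vox <- which(reach)
  node_of[solve_vox] <- seq_along(solve_vox)
  merged <- names(grid$electrode_voxels)
  if (config$inactive_treatment == "remove")
    merged <- config$active_electrode
  for (lbl in merged) {
    vox <- grid$electrode_voxels[[lbl]]
    vox <- vox[reach[vox]]
    if (length(vox) > 1) node_of[vox] <- node_of[vox[1]]
  }
  keep_nodes <- sort(unique(node_of[solve_vox]))
  renum <- integer(length(solve_vox))
  renum[keep_nodes] <- seq_along(keep_nodes)
  node_of[solve_vox] <- renum[node_of[solve_vox]]
  nn <- length(keep_nodes)

  keep_face <- reach[face_lo]              # faces within the component
  i <- node_of[face_lo[keep_face]]
  j <- node_of[face_hi[keep_face]]
  G <- face_G[keep_face]
  internal <- i != j                       # drop intra-supernode faces
  i <- i[internal]; j <- j[internal]; G <- G[internal]

  A <- Matrix::sparseMatrix(
    i = c(i, j, i, j, node_of[bottom]),
    j = c(j, i, i, j, node_of[bottom]),
    x = c(-G, -G, G, G, G_ground),
    dims = c(nn, nn)
  )
  b <- numeric(nn)
  b[node_of[act_vox[1]]] <- config$injected_current

  sol <- cg_solve(A, b, config$tolerance, config$max_iterations)

  pot <- array(NA_real_, dim = dims)
  pot[solve_vox] <- sol$x[node_of[solve_vox]]
  ground_flux <- sum(G_ground * pot[bottom])

  ## Fill unsolved voxels (substrate, disconnected pockets) from the voxel
  ## below so trilinear interpolation near the array face stays defined.
  for (k in 2:dims[3]) {
    sl <- pot[, , k]
    na <- is.na(sl)
    if (any(na)) {
      below <- pot[, , k - 1]
      sl[na] <- below[na]
      pot[, , k] <- sl
    }
  }
  for (k in (dims[3] - 1):1) {             # any NA left in bottom-up pass
    sl <- pot[, , k]
    na <- is.na(sl)
    if (any(na)) {
      above <- pot[, , k + 1]
      sl[na] <- above[na]
      pot[, , k] <- sl
    }
  }

  structure(
    list(x = grid$x, y = grid$y, z = grid$z, potential = pot,
         active_electrode = config$active_electrode,
         injected_current = config$injected_current,
         resolution_um = grid$resolution_um,
         residual = sol$residual, iterations = sol$iterations,
         ground_flux_A = ground_flux),
    class = "field_solution"
  )
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "<field_solution> electrode %s, %d x %d x %d voxels, residual %.2g (%d CG iters)\n",
    x$active_electrode, length(x$x), length(x$y), length(x$z),
    x$residual, x$iterations))
  invisible(x)
}

#' On-axis potential of an equipotential disc electrode (analytic oracle)
#'
#' Closed-form potential on the axis of a conducting disc of radius `a`
#' carrying current `I` into a homogeneous half-space of conductivity
#' `sigma`, mounted flush in an insulating plane:
#' \deqn{V(z) = \frac{I}{2\pi\sigma a}\arctan(a/z),\qquad V(0)=\frac{I}{4\sigma a}.}
#' Used as the independent validation oracle for [solve_unit_field()] in
#' homogeneous configurations.
#'
#' @param radius_um disc radius (um).
#' @param sigma_S_m half-space conductivity (S/m).
#' @param current_A injected current (A).
#' @param z_um on-axis depth(s) below the disc (um, >= 0); vectorised.
#' @return potential(s) in volts.
#' @export
analytic_disc_potential <- function(radius_um, sigma_S_m, current_A = 1,
                                    z_um) {
  stopifnot(radius_um > 0, sigma_S_m > 0, all(z_um >= 0))
  a <- radius_um * 1e-6
  z <- z_um * 1e-6
  current_A / (2 * pi * sigma_S_m * a) * atan2(a, z)
}

#' Trilinear interpolation of a field solution at arbitrary points
#'
#' @param solution a [solve_unit_field()] result.
#' @param points numeric matrix (n x 3) or length-3 vector of xyz
#'   coordinates in mm.
#' @return numeric vector of potentials (same units as the solution).
#' @export
interpolate_potential <- function(solution, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  gx <- solution$x; gy <- solution$y; gz <- solution$z
  out_of <- points[, 1] < gx[1] | points[, 1] > gx[length(gx)] |
    points[, 2] < gy[1] | points[, 2] > gy[length(gy)] |
    points[, 3] < gz[1] | points[, 3] > gz[length(gz)]
  if (any(out_of)) {
    p <- points[which(out_of)[1], ]
    stop(sprintf("point (%.4f, %.4f, %.4f) mm lies outside the solved domain",
                 p[1], p[2], p[3]))
  }
  f <- solution$potential
  ix <- pmin(pmax(findInterval(points[, 1], gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(points[, 2], gy), 1L), length(gy) - 1L)
  iz <- pmin(pmax(findInterval(points[, 3], gz), 1L), length(gz) - 1L)
  tx <- (points[, 1] - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (points[, 2] - gy[iy]) / (gy[iy + 1] - gy[iy])
  tz <- (points[, 3] - gz[iz]) / (gz[iz + 1] - gz[iz])
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
      (if (dz) tz else 1 - tz)
    v <- v + w * f[cbind(ix + dx, iy + dy, iz + dz)]
  }
  v
}
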