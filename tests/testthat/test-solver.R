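test_that("analytic disc potential has the textbook limits", {
  a <- 100; sig <- 0.1; I <- 1
  expect_equal(analytic_disc_potential(a, sig, I, 0),
               I / (4 * sig * a * 1e-6))
  ## V(a) is exactly half of V(0): arctan(1) = pi/4
  expect_equal(analytic_disc_potential(a, sig, I, a),
               analytic_disc_potential(a, sig, I, 0) / 2)
  ## far field approaches the point source I / (2 pi sigma z)
  z <- c(25 * a, 40 * a)
  ps <- I / (2 * pi * sig * z * 1e-6)
  expect_equal(analytic_disc_potential(a, sig, I, z) / ps,
               c(1, 1), tolerance = 0.01)
})

test_that("homogeneous solve matches the disc oracle within 5% beyond 2 voxels", {
  fix <- disc_solution()
  zs <- seq(50, 300, by = 25)           # 2 voxels = 50 um and beyond
  van <- analytic_disc_potential(100, 0.1, 1, zs)
  vnum <- interpolate_potential(fix$solution,
                                cbind(fix$electrode[1], fix$electrode[2],
                                      -zs / 1000))
  expect_true(all(abs(vnum - van) / van < 0.05))
})

test_that("discrete current conservation holds within 0.5%", {
  fix <- disc_solution()
  expect_lt(abs(fix$solution$ground_flux_A - 1), 0.005)
})

test_that("solution scales linearly with injected current", {
  fix <- disc_solution()
  s2 <- solve_unit_field(fix$grid, solver_config(
    "C5", tolerance = 1e-8, boundary = "open",
    inactive_treatment = "remove", injected_current = 2))
  p1 <- fix$solution$potential
  ok <- !is.na(p1) & abs(p1) > 1
  expect_equal(s2$potential[ok] / p1[ok], rep(2, sum(ok)),
               tolerance = 1e-5)
})

test_that("electrode access resistance converges under grid refinement", {
  lay <- make_argus2_layout(pitch_um = 1000, diameter_um = 400)
  geo <- make_synthetic_retina(
    retina_config(standoff_um = 0, choroid_thickness_mm = 1.2), lay,
    seed = 1)
  v_exact <- 1 / (4 * 0.1 * 200e-6)     # I / (4 sigma a)
  errs <- vapply(c(100, 50, 25), function(res) {
    grid <- voxelize(geo, lay, resolution_um = res,
                     conductivity = homogeneous_table(),
                     electrode = "C5", lateral_extent_mm = c(2, 2),
                     z_above_mm = 0.2)
    sol <- solve_unit_field(grid, solver_config(
      "C5", tolerance = 1e-8, boundary = "open",
      inactive_treatment = "remove"))
    v0 <- sol$potential[grid$electrode_voxels[["C5"]][1]]
    abs(v0 - v_exact) / v_exact
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("layered solution attenuates monotonically below the electrode", {
  lay <- default_layout()
  grid <- voxelize(flat_geometry(), lay, resolution_um = 50,
                   electrode = "C5", lateral_extent_mm = c(2.5, 2.5))
  sol <- solve_unit_field(grid, solver_config("C5", tolerance = 1e-8))
  e <- layout_xy(lay, "C5")
  zs <- seq(0.08, 0.3, by = 0.02)       # electrode face at z = 0.1
  v <- interpolate_potential(sol, cbind(e[1], e[2], 0.1 - zs))
  expect_true(all(diff(abs(v)) < 0))
  ## raising the retinal conductivity lowers intraretinal potentials
  grid2 <- voxelize(flat_geometry(), lay, resolution_um = 50,
                    conductivity = conductivity_table(retina = 0.2),
                    electrode = "C5", lateral_extent_mm = c(2.5, 2.5))
  sol2 <- solve_unit_field(grid2, solver_config("C5", tolerance = 1e-8))
  v2 <- interpolate_potential(sol2, cbind(e[1], e[2], 0.1 - c(0.12, 0.2)))
  expect_true(all(abs(v2) < abs(v[c(3, 7)])))
})

test_that("trilinear interpolation is exact at nodes and linear between them", {
  fix <- disc_solution()
  sol <- fix$solution
  i <- c(20L, 30L, 25L)
  node <- c(sol$x[i[1]], sol$y[i[2]], sol$z[i[3]])
  expect_equal(interpolate_potential(sol, node),
               sol$potential[i[1], i[2], i[3]])
  mid <- node + c((sol$x[2] - sol$x[1]) / 2, 0, 0)
  expect_equal(interpolate_potential(sol, mid),
               mean(c(sol$potential[i[1], i[2], i[3]],
                      sol$potential[i[1] + 1L, i[2], i[3]])))
  expect_error(interpolate_potential(sol, c(99, 0, 0)), "outside")
})

test_that("solver failure modes are reported", {
  fix <- disc_solution()
  expect_error(solve_unit_field(fix$grid, solver_config(
    "C5", tolerance = 1e-8, max_iterations = 3, boundary = "open")),
    "did not converge")
  expect_error(solve_unit_field(fix$grid, solver_config("A1")),
               "no platinum voxels")
  expect_error(solver_config("C5", tolerance = 0.5))
})
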