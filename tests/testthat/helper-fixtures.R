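# Shared fixtures, built lazily and memoised across test files.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Flat retina: 200 um thickness, 100 um standoff, no tilt.
flat_geometry <- function() memo("flat_geometry", {
  make_synthetic_retina(retina_config(standoff_um = 100),
                        make_argus2_layout(), seed = 42)
})

default_layout <- function() memo("layout", make_argus2_layout())

# Homogeneous half-space conductivity (all tissue 0.1 S/m, transparent RPE).
homogeneous_table <- function(sigma = 0.1)
  conductivity_table(vitreous = sigma, retina = sigma, fibrosis = sigma,
                     choroid = sigma, rpe_sigma = 1e6)

# Unit-field solution for a lone 200 um disc over a homogeneous half-space
# (open far-field boundary, inactive discs removed), 25 um voxels.
disc_solution <- function() memo("disc_solution", {
  lay <- default_layout()
  geo <- make_synthetic_retina(
    retina_config(standoff_um = 0, choroid_thickness_mm = 1.2), lay,
    seed = 1)
  grid <- voxelize(geo, lay, resolution_um = 25,
                   conductivity = homogeneous_table(),
                   electrode = "C5", lateral_extent_mm = c(1.8, 1.8),
                   z_above_mm = 0.2)
  list(grid = grid,
       solution = solve_unit_field(
         grid, solver_config("C5", tolerance = 1e-8, boundary = "open",
                             inactive_treatment = "remove")),
       electrode = layout_xy(lay, "C5"))
})

layout_xy <- function(layout, label) {
  e <- layout$electrodes[layout$electrodes$label == label, ]
  c(e$x_mm, e$y_mm)
}

# A cable model for a soma near the array centre over the flat geometry,
# plus an analytic point-source unit field at a given electrode height (mm
# above the inner surface).
demo_cable <- function() memo("demo_cable", {
  neu <- build_neuron(c(0.5, 0.3), flat_geometry())
  list(neuron = neu, model = cable_model(neu))
})

point_source_ve <- function(neuron, height_mm, sigma = 0.1,
                            center = c(0.5, 0.3)) {
  r <- sqrt((neuron$x_mm - center[1])^2 + (neuron$y_mm - center[2])^2 +
              (neuron$z_mm - height_mm)^2)
  1 / (2 * pi * sigma * (r / 1000))   # V per A at r mm
}
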