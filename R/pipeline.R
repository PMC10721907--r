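#' Pipeline run configuration
#'
#' Bundles every parameter of the end-to-end workflow (geometry -> field ->
#' neurons -> thresholds -> phosphenes -> stats) with the standard defaults:
#' 0.45 ms cathodic-first pulses, 0.1 uA bisection convergence, 55/15 um
#' soma/axon depths (inside [neuron_params()]), a 100 um thickness exclusion
#' floor, and a 677 uA electrode inclusion cutoff.  The default demo scale
#' (4 electrodes x 100 neurons on a 50 um grid) is sized to run on a desktop
#' in minutes; production-scale runs raise `n_neurons` to 250 and tighten
#' `resolution_um`.
#'
#' @param electrodes electrode labels to process.
#' @param n_neurons somata per electrode population.
#' @param placement_radius_um population radius (um).
#' @param exclusion_floor_um retinal thickness floor (um).
#' @param geometry a [retina_config()].
#' @param resolution_um field-solver voxel size (um).
#' @param lateral_extent_mm field subdomain lateral size (mm).
#' @param solver_tolerance CG relative-residual tolerance.
#' @param pulse_width_ms,frequency_hz,n_pulses stimulus waveform; the
#'   threshold search uses `n_pulses` pulses (1 by default).
#' @param dt_ms cable integration step (ms).
#' @param bisection list with `lo_uA`, `hi_uA`, `tol_uA`.
#' @param k_grid amplitude multiples for the phosphene sweep.
#' @param threshold_cap_uA electrode inclusion cutoff (uA).
#' @param synth_coefficients,synth_noise_sd synthetic perceptual-threshold
#'   generator settings (see [synth_thresholds()]).
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(electrodes = c("C5", "C6", "D5", "D6"),
                       n_neurons = 100,
                       placement_radius_um = 700,
                       exclusion_floor_um = 100,
                       geometry = retina_config(),
                       resolution_um = 50,
                       lateral_extent_mm = c(3, 3),
                       solver_tolerance = 1e-6,
                       pulse_width_ms = 0.45, frequency_hz = 20,
                       n_pulses = 1,
                       dt_ms = 0.01,
                       bisection = list(lo_uA = 0, hi_uA = 1000,
                                        tol_uA = 0.1),
                       k_grid = c(1.2, 2, 3, 4, 5, 6),
                       threshold_cap_uA = 677,
                       synth_coefficients = list(intercept = 50,
                                                 distance_mm = 500,
                                                 thickness_mm = -300),
                       synth_noise_sd = 10,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Save / load a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[names(cfg) %in% names(formals(run_config))])
}

#' Unit-field potentials at a neuron's compartment centres
#'
#' Interpolates the unit-current field solution at every compartment of a
#' [build_neuron()] geometry.  Compartments outside the solved subdomain
#' (the distal axon, typically millimetres from the electrode) are clamped
#' to the nearest boundary value: only potential *differences* drive the
#' cable equation, so a constant extracellular tail is inert, whereas
#' zeroing it would fabricate a potential step at the domain edge and
#' spurious activation there.
#'
#' @param solution a [solve_unit_field()] result.
#' @param neuron a [build_neuron()] compartment table.
#' @return numeric vector, V/A per compartment.
#' @export
unit_potentials_for_neuron <- function(solution, neuron) {
  pts <- cbind(pmin(pmax(neuron$x_mm, min(solution$x)), max(solution$x)),
               pmin(pmax(neuron$y_mm, min(solution$y)), max(solution$y)),
               pmin(pmax(neuron$z_mm, min(solution$z)), max(solution$z)))
  interpolate_potential(solution, pts)
}

#' Per-neuron activation thresholds for one electrode
#'
#' Runs the field-cable chain for a single electrode: voxelize a subdomain
#' centred on it, solve the unit field, place the soma population, build
#' each neuron along its nerve-fiber trajectory, interpolate the unit
#' potentials at every compartment, and bisect each neuron's activation
#' threshold.
#'
#' @param geometry,layout geometry and layout objects.
#' @param electrode electrode label.
#' @param config a [run_config()].
#' @param mem a [rgc_membrane_params()].
#' @param nparams a [neuron_params()].
#' @param tparams a [trajectory_params()].
#' @param solution optional precomputed [solve_unit_field()] result.
#' @param progress emit progress messages.
#' @return data.frame: `electrode`, `neuron_id`, `x_mm`, `y_mm`,
#'   `threshold_uA`, `excluded` (thin retina or inexcitable).
#' @export
electrode_thresholds <- function(geometry, layout, electrode, config,
                                 mem = rgc_membrane_params(),
                                 nparams = neuron_params(),
                                 tparams = trajectory_params(),
                                 solution = NULL, progress = FALSE) {
  if (is.null(solution)) {
    grid <- voxelize(geometry, layout, resolution_um = config$resolution_um,
                     electrode = electrode,
                     lateral_extent_mm = config$lateral_extent_mm)
    solution <- solve_unit_field(
      grid, solver_config(electrode, tolerance = config$solver_tolerance))
  }
  pop <- place_somas(layout, electrode, n = config$n_neurons,
                     radius_um = config$placement_radius_um,
                     seed = config$seed + match(electrode,
                                                layout$electrodes$label))
  kept <- apply_thickness_exclusion(pop, geometry,
                                    floor_um = config$exclusion_floor_um)
  removed <- attr(kept, "removed")
  wf <- make_pulse_train(pulse_width_ms = config$pulse_width_ms,
                         frequency_hz = config$frequency_hz,
                         n_pulses = config$n_pulses)
  thr <- rep(NA_real_, nrow(pop))
  for (i in seq_len(nrow(kept))) {
    neuron <- build_neuron(c(kept$x_mm[i], kept$y_mm[i]), geometry,
                           params = nparams, traj_params = tparams)
    model <- cable_model(neuron, mem)
    ve <- unit_potentials_for_neuron(solution, neuron)
    thr[kept$neuron_id[i]] <- find_threshold(
      model, ve, waveform = wf,
      lo_uA = config$bisection$lo_uA, hi_uA = config$bisection$hi_uA,
      tol_uA = config$bisection$tol_uA, dt_ms = config$dt_ms)
    if (progress && i %% 25 == 0)
      message(sprintf("  electrode %s: %d/%d neurons", electrode, i,
                      nrow(kept)))
  }
  data.frame(electrode = electrode, neuron_id = pop$neuron_id,
             x_mm = pop$x_mm, y_mm = pop$y_mm, threshold_uA = thr,
             excluded = removed | is.na(thr), stringsAsFactors = FALSE)
}

#' Phosphene size-amplitude sweep across electrode-retina standoffs
#'
#' The in-silico counterpart of the phosphene-size experiment: for a set of
#' electrode-retina standoffs, run the field-cable chain for one electrode
#' over a flat retina at that standoff (100 neurons per electrode by
#' default), then sweep the amplitude multiple over `k_grid` and fit hull
#' area against multiple for each electrode.
#'
#' @param standoffs_um electrode-retina distances to simulate (um).
#' @param n_neurons somata per electrode.
#' @param seed master seed.
#' @param k_grid amplitude multiples (default 1.2x-6x threshold).
#' @param electrode electrode label used for every run.
#' @param resolution_um,lateral_extent_mm,solver_tolerance field-solver
#'   settings.
#' @param progress emit progress messages.
#' @return list with `fits` (one [size_amplitude_slope()] per standoff,
#'   named `s<standoff>`), `map` (combined [electrode_threshold_map()]),
#'   and `summary` data.frame (`standoff_um`, `min_threshold_uA`,
#'   `slope_deg2_per_k`, `r_squared`).
#' @export
phosphene_standoff_batch <- function(standoffs_um = c(50, 100, 150, 200,
                                                      250, 300),
                                     n_neurons = 100, seed = 1L,
                                     k_grid = c(1.2, 2, 3, 4, 5, 6),
                                     electrode = "C5",
                                     resolution_um = 50,
                                     lateral_extent_mm = c(2.5, 2.5),
                                     solver_tolerance = 1e-6,
                                     progress = TRUE) {
  layout <- make_argus2_layout()
  tabs <- list()
  for (s in standoffs_um) {
    if (progress) message(sprintf("standoff %g um ...", s))
    cfg <- run_config(electrodes = electrode, n_neurons = n_neurons,
                      geometry = retina_config(standoff_um = s),
                      resolution_um = resolution_um,
                      lateral_extent_mm = lateral_extent_mm,
                      solver_tolerance = solver_tolerance,
                      k_grid = k_grid, seed = seed)
    geometry <- make_synthetic_retina(cfg$geometry, layout, seed = seed)
    tab <- electrode_thresholds(geometry, layout, electrode, cfg,
                                progress = FALSE)
    tab$electrode <- sprintf("s%g", s)
    tabs[[tab$electrode[1]]] <- tab
  }
  all_thr <- do.call(rbind, tabs)
  rownames(all_thr) <- NULL
  map <- electrode_threshold_map(all_thr)
  fits <- lapply(setNames(nm = names(tabs)), function(el)
    size_amplitude_slope(map, el, k_grid = k_grid))
  summary <- data.frame(
    standoff_um = standoffs_um,
    min_threshold_uA = map$electrodes$min_threshold_uA[
      match(names(tabs), map$electrodes$electrode)],
    slope_deg2_per_k = vapply(fits, `[[`, numeric(1), "slope_deg2_per_k"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    row.names = NULL
  )
  list(fits = fits, map = map, summary = summary)
}

#' Run the end-to-end field-cable pipeline
#'
#' Executes every stage in order -- synthetic geometry, electrode
#' measurements with synthetic perceptual thresholds, one unit-field solve
#' per electrode (cached and reused across all amplitudes and neurons),
#' population placement, per-neuron bisection thresholds (cached), the
#' electrode threshold map, the phosphene size-amplitude sweep, and the
#' electrode-level regression table -- writing TSV/JSON outputs, a log, and
#' a manifest with the configuration hash into `out_dir`.
#'
#' Stage caches are keyed on the parameters that affect the stage, so
#' re-running with only `k_grid` changed re-uses both the field solutions
#' and the neuron thresholds.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param use_cache reuse cached field solutions / thresholds when present.
#' @param progress emit progress messages.
#' @return list with the threshold map, phosphene fits, measurement table,
#'   regression table, and output paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("retfield_run_"),
                         use_cache = TRUE, progress = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (progress) message(msg)
    log <<- c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say("stage %-12s %6.1f s", name, timings[[name]])
    out
  }

  layout <- make_argus2_layout()
  geometry <- stage("geometry", make_synthetic_retina(
    config$geometry, layout, seed = config$seed))

  measurements <- stage("measure", {
    m <- measure_electrodes(geometry, layout)
    synth_thresholds(m, coefficients = config$synth_coefficients,
                     noise_sd = config$synth_noise_sd,
                     seed = config$seed + 1000L)
  })
  meas_path <- file.path(out_dir, "electrodes.tsv")
  write_measurements(measurements, meas_path)

  geom_key <- config_hash(list(config$geometry, config$seed,
                               config$resolution_um,
                               config$lateral_extent_mm,
                               config$solver_tolerance))
  thr_key <- config_hash(list(geom_key, config$n_neurons,
                              config$placement_radius_um,
                              config$exclusion_floor_um,
                              config$pulse_width_ms, config$frequency_hz,
                              config$n_pulses, config$dt_ms,
                              config$bisection))

  visible <- measurements$label[measurements$visible]
  run_electrodes <- intersect(config$electrodes, visible)
  if (!length(run_electrodes))
    stop("none of the configured electrodes are visible in the geometry")

  thr_tables <- list()
  for (el in run_electrodes) {
    cache_file <- file.path(cache_dir,
                            sprintf("thresholds_%s_%s.rds", el, thr_key))
    if (use_cache && file.exists(cache_file)) {
      say("electrode %s: thresholds from cache", el)
      thr_tables[[el]] <- readRDS(cache_file)
      next
    }
    field_file <- file.path(cache_dir,
                            sprintf("field_%s_%s.rds", el, geom_key))
    solution <- if (use_cache && file.exists(field_file)) {
      say("electrode %s: field from cache", el)
      readRDS(field_file)
    } else {
      sol <- stage(paste0("field_", el), {
        grid <- voxelize(geometry, layout,
                         resolution_um = config$resolution_um,
                         electrode = el,
                         lateral_extent_mm = config$lateral_extent_mm)
        solve_unit_field(grid, solver_config(
          el, tolerance = config$solver_tolerance))
      })
      saveRDS(sol, field_file)
      sol
    }
    thr_tables[[el]] <- stage(paste0("thresholds_", el),
      electrode_thresholds(geometry, layout, el, config,
                           solution = solution, progress = progress))
    saveRDS(thr_tables[[el]], cache_file)
  }
  thresholds <- do.call(rbind, thr_tables)
  rownames(thresholds) <- NULL
  thr_path <- file.path(out_dir, "neuron_thresholds.tsv")
  write.table(thresholds, thr_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  map <- electrode_threshold_map(thresholds)
  fits <- stage("phosphene", {
    lapply(setNames(nm = run_electrodes), function(el) {
      s <- map$electrodes[map$electrodes$electrode == el, ]
      if (s$flagged) return(NULL)
      size_amplitude_slope(map, el, k_grid = config$k_grid)
    })
  })

  stats_tab <- stage("stats", {
    kept <- inclusion_filter(measurements,
                             threshold_cap_uA = config$threshold_cap_uA)
    regression_table(kept, covariates = c("distance_mm", "thickness_mm",
                                          "impedance_kohm"))
  })
  write.table(stats_tab, file.path(out_dir, "regression_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    electrodes = map$electrodes,
    phosphene = lapply(fits, function(f) if (is.null(f)) NULL else
      f[c("k", "area_deg2", "slope_deg2_per_k", "r_squared")])
  )
  jsonlite::write_json(report, file.path(out_dir, "phosphene_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed,
                   electrodes = run_electrodes,
                   timings_s = timings,
                   outputs = c("electrodes.tsv", "neuron_thresholds.tsv",
                               "regression_table.tsv",
                               "phosphene_report.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log, file.path(out_dir, "run.log"))

  invisible(list(map = map, phosphene = fits, measurements = measurements,
                 regression = stats_tab, out_dir = out_dir,
                 manifest = manifest))
}
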