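# End-to-end impact experiment: geometry -> materials -> explicit dynamics
# -> traces, peak table, snapshots.

#' Impact experiment configuration
#'
#' @param geometry a [geometry_spec()].
#' @param impactor an [impactor_spec()].
#' @param initial_velocity impactor speed at release toward the skull, m/s
#'   (default 4.54).
#' @param standoff initial tip-skull gap, mm (default taken from
#'   `geometry$impactor_standoff`, 0.9); the standoff flight is simulated.
#' @param duration total simulated time, ms.
#' @param output_every monitor-trace sampling interval, ms.
#' @param snapshot_every full-field snapshot interval, ms (0 = none).
#' @param penalty contact penalty stiffness (Pa/m); `NULL` selects 10x the
#'   stiffest adjacent skull element's stiffness estimate.
#' @param poisson_eff effective Poisson ratio of the brain materials.
#' @param safety CFL safety factor.
#' @param material_overrides named list overriding built-in materials, see
#'   [material_table_with_overrides()].
#' @param seed integer seed (geometry jitter; the solver itself is
#'   deterministic).
#' @param output_dir if non-`NULL`, artifacts (traces CSV, peak TSV, energy
#'   CSV, VTK snapshots, run log) are written there.
#' @return object of class `impact_config`.
#' @export
impact_config <- function(geometry = geometry_spec(),
                          impactor = impactor_spec(),
                          initial_velocity = 4.54,
                          standoff = geometry$impactor_standoff,
                          duration = 4.0, output_every = 0.01,
                          snapshot_every = 0, penalty = NULL,
                          poisson_eff = 0.4995, safety = 0.8,
                          material_overrides = NULL,
                          seed = 1L, output_dir = NULL) {
  if (initial_velocity < 0) stop("initial_velocity must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (output_every <= 0 || output_every > duration)
    stop("output_every must lie in (0, duration]")
  if (standoff < 0) stop("standoff must be >= 0")
  structure(list(geometry = geometry, impactor = impactor,
                 initial_velocity = initial_velocity, standoff = standoff,
                 duration = duration, output_every = output_every,
                 snapshot_every = snapshot_every, penalty = penalty,
                 poisson_eff = poisson_eff, safety = safety,
                 material_overrides = material_overrides,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "impact_config")
}

#' Read an impact configuration from YAML
#'
#' Recognized blocks: `geometry:`, `impactor:`, `materials:` and the scalar
#' fields of [impact_config()].
#'
#' @param path YAML file.
#' @export
impact_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  geo <- do.call(geometry_spec, c(y$geometry, list()))
  imp <- do.call(impactor_spec, c(y$impactor, list()))
  args <- y[setdiff(names(y), c("geometry", "impactor", "materials"))]
  args$geometry <- geo
  args$impactor <- imp
  args$material_overrides <- y$materials
  do.call(impact_config, args)
}

# default penalty: 10x the stiffest adjacent (skull) element stiffness
# estimate M/h, M = K + 4G/3
default_penalty <- function(model) {
  tab <- stable_dt_table(model)
  Ginst <- model$emat[, "G0"] * (model$emat[, "g1"] + model$emat[, "g2"] +
                                 model$emat[, "gL"])
  M <- model$emat[, "K"] + 4 * Ginst / 3
  10 * max(M / tab$char_length)
}

#' Run the impact experiment
#'
#' Builds the synthetic sagittal geometry, assigns materials, drops the rigid
#' impactor onto the skull at the configured speed, and post-processes the
#' monitor histories into traces and a peak table.  Deterministic given
#' (config, seed).
#'
#' @param config an [impact_config()].
#' @param mesh optional pre-built `regioned_mesh` (with monitors); default is
#'   generated from `config$geometry`.
#' @return object of class `simulation_result`: `traces`
#'   (`monitor_traces`), `peaks`, `energy`, `energy_residual`,
#'   `momentum_drift`, `impactor` trajectory, `status`, `files`, provenance.
#' @export
run_impact <- function(config, mesh = NULL) {
  stopifnot(inherits(config, "impact_config"))
  if (is.null(mesh)) {
    geo <- config$geometry
    geo$seed <- config$seed
    mesh <- build_sagittal_domain(geo)
  }
  if (is.null(mesh$monitors)) mesh$monitors <- place_monitors(mesh)
  materials <- material_table_with_overrides(config$material_overrides,
                                             poisson_eff = config$poisson_eff)
  model <- assemble_model(mesh, materials)
  imp <- build_impactor(config$impactor, materials)

  # contact surface: tip face in SI, edges at y = -standoff
  segs <- attr(imp, "face_segments") * 1e-3
  segs[, c(2, 4)] <- segs[, c(2, 4)] - config$standoff * 1e-3
  outer <- mesh$boundary_sets$skull_outer
  xr <- (config$impactor$tip_radius + 1.0) * 1e-3
  slab <- model$nodes[outer$nodes, , drop = FALSE]
  sel <- abs(slab[, 1]) <= xr &
    slab[, 2] <= (mesh$spec$skull_thickness) * 1e-3
  slaves <- outer$nodes[sel]
  if (length(slaves) == 0) stop("no skull nodes under the impactor face")
  # tributary lengths along the outer surface
  osegs <- outer$segments
  p1 <- model$nodes[osegs[, 1], , drop = FALSE]
  p2 <- model$nodes[osegs[, 2], , drop = FALSE]
  slen <- sqrt(rowSums((p2 - p1)^2))
  trib <- numeric(length(slaves))
  for (i in seq_along(slaves)) {
    adj <- which(osegs[, 1] == slaves[i] | osegs[, 2] == slaves[i])
    trib[i] <- 0.5 * sum(slen[adj])
  }
  penalty <- if (is.null(config$penalty)) default_penalty(model) else config$penalty
  kn <- penalty * trib

  dt_cfl <- stable_dt(model, config$safety)
  mass <- lumped_mass(model)
  dt_contact <- 2 / sqrt(max(kn) / min(mass[slaves]))
  dt <- min(dt_cfl, config$safety * 0.5 * dt_contact)
  nsteps <- ceiling(config$duration * 1e-3 / dt)
  out_every <- max(1L, round(config$output_every * 1e-3 / dt))
  snap_every <- if (config$snapshot_every > 0)
    max(1L, round(config$snapshot_every * 1e-3 / dt)) else 0L

  contacts <- list(list(segs = segs, rigid = TRUE,
                        mass = attr(imp, "mass_per_thickness"),
                        v0 = config$initial_velocity, slaves = slaves,
                        kn = kn))
  res <- run_explicit(model, dt, nsteps, contacts = contacts,
                      monitors = mesh$monitors, out_every = out_every,
                      snap_every = snap_every)
  traces <- monitor_traces(res$times, res$mon_vm, res$mon_e1, res$mon_s1)
  peaks <- peak_table(traces)
  # contact onset: first recorded time with contact energy storage
  onset <- res$energy$time[which(res$energy$contact_penalty > 0)[1]]
  hmin <- min(stable_dt_table(model)$char_length)
  if (res$max_penetration > 0.1 * hmin)
    warning(sprintf("contact penetration %.3g m exceeds 10%% of local element size (penalty too soft)",
                    res$max_penetration))
  out <- list(traces = traces, peaks = peaks, energy = res$energy,
              energy_residual = energy_audit(res),
              momentum_drift = momentum_drift(res),
              impactor = data.frame(time_ms = res$times * 1e3,
                                    y_mm = res$rigid_y[1, ] * 1e3,
                                    v_m_s = res$rigid_v[1, ]),
              contact_onset_ms = if (is.na(onset)) NA_real_ else onset * 1e3,
              snapshots = res$snapshots, mesh = mesh, dt = dt,
              nsteps = nsteps, max_penetration = res$max_penetration,
              status = res$status,
              provenance = list(package_version =
                                  as.character(utils::packageVersion("neuroimpact")),
                                config_yaml = yaml::as.yaml(strip_config(config))),
              files = character(0))
  class(out) <- "simulation_result"
  if (!is.null(config$output_dir))
    out$files <- write_result(out, config$output_dir, model)
  out
}

strip_config <- function(config) {
  cf <- unclass(config)
  cf$geometry <- unclass(cf$geometry)
  cf$geometry$region_layout <- NULL
  cf$impactor <- unclass(cf$impactor)
  cf$output_dir <- NULL
  cf
}

write_result <- function(result, dir, model) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "traces.csv")
  write_traces(result$traces, f); files <- c(files, f)
  f <- file.path(dir, "peaks.tsv")
  write.table(result$peaks, f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "energy.csv")
  write.csv(result$energy, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "config.yaml")
  writeLines(result$provenance$config_yaml, f); files <- c(files, f)
  if (!is.null(result$snapshots)) {
    ns <- length(result$snapshots$times)
    nn <- nrow(result$mesh$nodes)
    for (s in seq_len(ns)) {
      f <- file.path(dir, sprintf("snapshot_%04d.vtk", s))
      u <- matrix(result$snapshots$u[, s], nn, 2, byrow = TRUE)
      v <- matrix(result$snapshots$vel[, s], nn, 2, byrow = TRUE)
      write_mesh(result$mesh, f,
                 cell_data = list(
                   von_mises_kPa = result$snapshots$von_mises[, s] * 1e-3,
                   max_principal_strain = result$snapshots$max_principal_strain[, s]),
                 point_data = list(displacement_mm = u * 1e3,
                                   velocity_m_s = v))
      files <- c(files, f)
    }
  }
  f <- file.path(dir, "run.jsonl")
  con <- file(f, "w")
  writeLines(sprintf('{"event":"run","dt_s":%.6g,"steps":%d,"energy_residual":%.6g,"momentum_drift":%.6g,"status":"%s"}',
                     result$dt, result$nsteps, result$energy_residual,
                     result$momentum_drift, result$status$message), con)
  close(con)
  files <- c(files, f)
  files
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d steps @ dt = %.3g us, status: %s\n",
              x$nsteps, x$dt * 1e6, x$status$message))
  cat(sprintf("  energy residual %.3g, momentum drift %.3g, contact onset %.3g ms\n",
              x$energy_residual, x$momentum_drift, x$contact_onset_ms))
  print(x$peaks[, c("monitor", "t_first_stress_ms", "first_stress_kPa",
                    "max_strain", "arrival_order")])
  invisible(x)
}
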