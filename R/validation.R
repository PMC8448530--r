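# Built-in verification harness: each check has a closed-form oracle that is
# independent of the solver path it exercises.

#' Relaxation check: element assembly vs closed-form Prony curve
#'
#' @param material a [prony_material()].
#' @param t_end end time, ms.
#' @param dt step, ms; default `min(tau1, tau2) / 20`.
#' @return maximum relative error of the apparent relaxation modulus against
#'   [relaxation_modulus()] over (0, t_end].
#' @export
relaxation_check <- function(material, t_end = 500, dt = NULL) {
  if (is.null(dt)) dt <- min(material$tau1, material$tau2) / 20
  times <- seq(dt, t_end, by = dt)
  out <- element_relaxation(material, gamma0 = 0.01, times = times)
  Gref <- relaxation_modulus(material, out$t_ms)
  max(abs(out$G_apparent - Gref) / Gref)
}

#' Wave-speed check: pulse arrival in a laterally confined bar
#'
#' A homogeneous bar in uniaxial-strain conditions (lateral displacement
#' fixed) is struck at one end with a uniform velocity; the compressive pulse
#' front must arrive at the far end after `L / c`, with
#' `c = sqrt((K + 4 G_inst / 3) / rho)` the dilatational wave speed.
#'
#' @param material material, default built-in cortex.
#' @param L_mm bar length, mm.
#' @param nel number of elements along the bar.
#' @param v0 strike velocity, m/s.
#' @param arrival_frac velocity fraction defining the front arrival.
#' @return list with `t_arrival_ms`, `t_expected_ms`, `rel_error`, `c`.
#' @export
wave_bar_check <- function(material = builtin_material("Cortex"), L_mm = 10,
                           nel = 200, v0 = 1, arrival_frac = 0.05) {
  h <- L_mm / nel
  mesh <- make_block_mesh(nel, 1, c(0, L_mm), c(0, h), region = "bar",
                          material = material$name)
  mats <- stats::setNames(list(material), material$name)
  model <- assemble_model(mesh, mats)
  nn <- nrow(model$nodes)
  fixed <- matrix(FALSE, nn, 2)
  fixed[, 2] <- TRUE  # lateral confinement -> uniaxial strain
  v <- matrix(0, nn, 2)
  left <- which(model$nodes[, 1] == 0)
  right <- which(model$nodes[, 1] == max(model$nodes[, 1]))
  v[left, 1] <- v0
  Ginst <- instantaneous_shear_modulus(material)
  K <- bulk_modulus(material)
  cw <- sqrt((K + 4 * Ginst / 3) / material$density)
  t_exp <- L_mm * 1e-3 / cw
  dt <- stable_dt(model)
  nsteps <- ceiling(1.4 * t_exp / dt)
  res <- run_explicit(model, dt, nsteps, v0 = v, fixed = fixed,
                      probes = right[1], out_every = 1L,
                      jac_every = as.integer(nsteps + 1L), bvisc = 0)
  vx <- res$probe_v[1, ]
  idx <- which(abs(vx) >= arrival_frac * abs(v0))[1]
  if (is.na(idx)) stop("pulse never arrived; bar too short or run too brief")
  # linear interpolation between samples for sub-step arrival time
  t_arr <- if (idx == 1) res$times[1] else {
    t1 <- res$times[idx - 1]; t2 <- res$times[idx]
    y1 <- abs(vx[idx - 1]); y2 <- abs(vx[idx])
    t1 + (arrival_frac * abs(v0) - y1) / (y2 - y1) * (t2 - t1)
  }
  list(t_arrival_ms = t_arr * 1e3, t_expected_ms = t_exp * 1e3,
       rel_error = abs(t_arr - t_exp) / t_exp, c = cw)
}

#' Single-element oscillator period check
#'
#' An elastic quad with the base fixed and the top face moving vertically as
#' a rigid mass is released from a small static displacement; the simulated
#' period must match the closed-form single-DOF value `2 pi sqrt(m / k)`,
#' with `k` measured by a static force probe and `m` the lumped top mass.
#'
#' @param E,nu,rho oscillator material.
#' @param dt_frac time step as a fraction of the stable step.
#' @return list with `T_sim_ms`, `T_ref_ms`, `rel_error`.
#' @export
sdof_period_check <- function(E = 1e6, nu = 0.3, rho = 1000, dt_frac = 0.1) {
  mat <- elastic_material("osc", E = E, nu = nu, density = rho)
  mesh <- make_block_mesh(1, 1, c(0, 10), c(0, 10), region = "osc",
                          material = "osc")
  model <- assemble_model(mesh, stats::setNames(list(mat), "osc"))
  nn <- nrow(model$nodes)
  top <- which(model$nodes[, 2] == max(model$nodes[, 2]))
  bot <- which(model$nodes[, 2] == min(model$nodes[, 2]))
  fixed <- matrix(FALSE, nn, 2)
  fixed[bot, ] <- TRUE
  fixed[, 1] <- TRUE   # vertical motion only
  u0amp <- 1e-5 * diff(range(model$nodes[, 2]))
  u0 <- matrix(0, nn, 2)
  u0[top, 2] <- u0amp
  # static stiffness probe (independent of the dynamic path)
  k <- -sum(internal_forces(model, u0)$force[top, 2]) / u0amp
  m <- sum(lumped_mass(model)[top])
  T_ref <- 2 * pi * sqrt(m / k)
  dt <- stable_dt(model) * dt_frac
  nsteps <- ceiling(6 * T_ref / dt)
  res <- run_explicit(model, dt, nsteps, u0 = u0, fixed = fixed,
                      probes = top[1], out_every = 1L,
                      jac_every = as.integer(nsteps + 1L), bvisc = 0)
  uy <- res$probe_u[2, ]
  sgn <- sign(uy)
  cross <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  if (length(cross) < 4) stop("too few zero crossings to estimate a period")
  tc <- res$times[cross]
  T_sim <- 2 * mean(diff(tc))
  list(T_sim_ms = T_sim * 1e3, T_ref_ms = T_ref * 1e3,
       rel_error = abs(T_sim - T_ref) / T_ref)
}

#' Elastic penalty-bounce energy check
#'
#' An elastic block falls onto a rigid frictionless floor; through contact,
#' bounce, and separation the energy ledger (kinetic + stored + dissipated +
#' penalty storage) must stay at the initial kinetic energy.
#'
#' @param E,nu,rho block material.
#' @param v0 approach speed, m/s.
#' @return list with `residual` (relative energy residual over the run) and
#'   `rebounded` (block moving away at the end).
#' @export
bounce_energy_check <- function(E = 1e5, nu = 0.3, rho = 1000, v0 = 1) {
  mat <- elastic_material("block", E = E, nu = nu, density = rho)
  mesh <- make_block_mesh(8, 8, c(0, 10), c(0, 10), region = "block",
                          material = "block")
  model <- assemble_model(mesh, stats::setNames(list(mat), "block"))
  nn <- nrow(model$nodes)
  v <- matrix(0, nn, 2)
  v[, 2] <- v0  # toward the floor (+y)
  gap <- 1e-3   # 1 mm
  floor_y <- max(model$nodes[, 2]) + gap
  # floor segments ordered so the outward normal points up (-y) at the block
  segs <- matrix(c(0.1, floor_y, -0.09, floor_y), 1, 4)
  bottom <- which(model$nodes[, 2] == max(model$nodes[, 2]))
  h <- 10e-3 / 8
  kn <- rep(E / h * h, length(bottom))  # ~element stiffness scale
  contacts <- list(list(segs = segs, rigid = FALSE, mass = 0, v0 = 0,
                        slaves = bottom, kn = kn))
  dt <- min(stable_dt(model), 0.5 * 2 / sqrt(max(kn) / min(lumped_mass(model))))
  t_total <- 3 * gap / v0 + 4 * 10e-3 / sqrt(E / rho)
  nsteps <- ceiling(t_total / dt)
  res <- run_explicit(model, dt, nsteps, v0 = v, contacts = contacts,
                      out_every = max(1L, nsteps %/% 2000L), bvisc = 0)
  vy_end <- mean(res$final$v[, 2])
  list(residual = as.numeric(energy_audit(res)), rebounded = vy_end < 0)
}

#' Run the verification suite
#'
#' Executes the closed-form checks: single-element relaxation against the
#' Prony curve for every built-in brain material, the dilatational
#' wave-arrival test, the single-DOF oscillator period, and the elastic
#' bounce energy audit.  Failures are reported, not raised.
#'
#' @param quick logical; use a coarser wave bar for speed.
#' @return data.frame with check name, measured error, tolerance and pass
#'   flag.
#' @export
run_validation_suite <- function(quick = FALSE) {
  mats <- builtin_material_table()
  brain <- c("Pons", "Cortex", "Cerebellum", "Thalamus", "Medulla",
             "Hippocampus")
  rows <- list()
  for (nm in brain) {
    err <- relaxation_check(mats[[nm]], t_end = if (quick) 100 else 500)
    rows[[length(rows) + 1]] <-
      data.frame(check = paste0("relaxation_", tolower(nm)), error = err,
                 tolerance = 0.005)
  }
  wb <- wave_bar_check()
  rows[[length(rows) + 1]] <-
    data.frame(check = "wave_arrival", error = wb$rel_error, tolerance = 0.02)
  sd <- sdof_period_check()
  rows[[length(rows) + 1]] <-
    data.frame(check = "sdof_period", error = sd$rel_error, tolerance = 0.01)
  bc <- bounce_energy_check()
  rows[[length(rows) + 1]] <-
    data.frame(check = "bounce_energy", error = bc$residual, tolerance = 0.02)
  out <- do.call(rbind, rows)
  out$pass <- out$error < out$tolerance
  rownames(out) <- NULL
  out
}
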