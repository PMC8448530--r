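# Model assembly and R-level interface to the compiled explicit solver.
#
# Geometry lives in mm; `assemble_model()` is the single place where the
# mesh and the material tables are converted to SI (m, s, kg, Pa).

#' Assemble a finite-element model from a regioned mesh
#'
#' Converts coordinates to SI, resolves each element's region to a material,
#' and expands the material table into the per-element parameter rows the
#' compiled kernels consume.
#'
#' @param mesh a `regioned_mesh` (mm).
#' @param materials named material table, see [builtin_material_table()].
#' @return object of class `fem_model`.
#' @export
assemble_model <- function(mesh, materials = builtin_material_table()) {
  stopifnot(inherits(mesh, "regioned_mesh"))
  regs <- unique(mesh$region)
  rows <- matrix(0, length(regs), 8,
                 dimnames = list(regs, c("G0", "g1", "g2", "gL", "tau1",
                                         "tau2", "K", "rho")))
  for (rg in regs) {
    mn <- unname(mesh$region_materials[rg])
    if (is.na(mn) || !mn %in% names(materials))
      stop(sprintf("no material assigned to region '%s'", rg))
    rows[rg, ] <- material_si_row(materials[[mn]])
  }
  emat <- rows[mesh$region, , drop = FALSE]
  structure(list(nodes = mesh$nodes * 1e-3, elements = mesh$elements,
                 emat = emat, mesh = mesh, materials = materials),
            class = "fem_model")
}

# per-element geometry helpers on the SI node set
element_geometry <- function(model) {
  el <- model$elements
  x <- matrix(model$nodes[el, 1], nrow(el), 4)
  y <- matrix(model$nodes[el, 2], nrow(el), 4)
  area <- abs(0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
                     (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
                     (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
                     (x[, 4] * y[, 1] - x[, 1] * y[, 4])))
  d1 <- sqrt((x[, 3] - x[, 1])^2 + (y[, 3] - y[, 1])^2)
  d2 <- sqrt((x[, 4] - x[, 2])^2 + (y[, 4] - y[, 2])^2)
  list(area = area, char_length = area / pmax(d1, d2))
}

#' Lumped nodal masses (row-sum lumping)
#'
#' Total mass equals the exact density x area integral per unit thickness.
#'
#' @param model a `fem_model`.
#' @return numeric vector of nodal masses, kg (per metre thickness).
#' @export
lumped_mass <- function(model) {
  el <- model$elements
  nn <- nrow(model$nodes)
  rho <- model$emat[, "rho"]
  gs <- 1 / sqrt(3)
  sx <- c(-1, 1, 1, -1) * gs
  sy <- c(-1, -1, 1, 1) * gs
  x <- matrix(model$nodes[el, 1], nrow(el), 4)
  y <- matrix(model$nodes[el, 2], nrow(el), 4)
  mass <- numeric(nn)
  for (g in 1:4) {
    xi <- sx[g]; eta <- sy[g]
    dxi <- 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta))
    deta <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
    N <- 0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
                  (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
    j11 <- x %*% dxi; j12 <- y %*% dxi
    j21 <- x %*% deta; j22 <- y %*% deta
    det <- as.vector(j11 * j22 - j12 * j21)
    for (a in 1:4) {
      contrib <- rowsum(rho * det * N[a], el[, a])
      idx <- as.integer(rownames(contrib))
      mass[idx] <- mass[idx] + contrib[, 1]
    }
  }
  mass
}

#' Per-element stable time step table
#'
#' Characteristic length over dilatational wave speed per element,
#' c = sqrt((K + 4 G_inst / 3) / rho).
#'
#' @param model a `fem_model`.
#' @return data.frame with element id, region, char length (m), wave speed
#'   (m/s) and critical dt (s).
#' @export
stable_dt_table <- function(model) {
  geo <- element_geometry(model)
  Ginst <- model$emat[, "G0"] * (model$emat[, "g1"] + model$emat[, "g2"] +
                                 model$emat[, "gL"])
  c0 <- sqrt((model$emat[, "K"] + 4 * Ginst / 3) / model$emat[, "rho"])
  data.frame(elem = seq_len(nrow(model$elements)),
             region = model$mesh$region,
             char_length = geo$char_length, wave_speed = unname(c0),
             dt_crit = unname(geo$char_length / c0))
}

#' Stable explicit time step (CFL bound)
#'
#' `dt = safety * min(char_length / c)` over all elements.
#'
#' @param model a `fem_model`.
#' @param safety safety factor in (0, 1], default 0.8.
#' @return time step, s.
#' @export
stable_dt <- function(model, safety = 0.8) {
  if (safety <= 0 || safety > 1) stop("safety must lie in (0, 1]")
  if (nrow(model$elements) == 0) stop("empty mesh")
  safety * min(stable_dt_table(model)$dt_crit)
}

#' Internal force evaluation
#'
#' Assembles nodal internal forces from the current displacement field via
#' 2x2 Gauss quadrature of the deviatoric (viscoelastic) plus volumetric
#' (elastic) stress.  With `state = NULL` and `dt = 0` the response is the
#' instantaneous elastic one.
#'
#' @param model a `fem_model`.
#' @param u displacement field, n x 2 matrix (m).
#' @param dt time step (s) used for the viscoelastic branch decay.
#' @param state gauss-point state matrix from a previous call, or `NULL`.
#' @return list with `force` (n x 2, N per metre thickness), gauss-point
#'   `sigma` (4n_e x 4: sxx, syy, sxy, szz, Pa), `eps` (4n_e x 3), updated
#'   `state`, `work_increment` and `stored_energy` (J/m).
#' @export
internal_forces <- function(model, u, dt = 0, state = NULL) {
  stopifnot(inherits(model, "fem_model"))
  u <- as.matrix(u)
  if (nrow(u) != nrow(model$nodes) || ncol(u) != 2)
    stop("u must be an n_nodes x 2 matrix")
  res <- fem_forces_once(model$nodes, model$elements, model$emat,
                         u[, 1], u[, 2], dt, state, 0)
  list(force = cbind(res$fx, res$fy), sigma = res$sigma, eps = res$eps,
       state = res$state, work_increment = res$work_increment,
       stored_energy = res$stored_energy)
}

#' Frictionless node-to-segment penalty contact forces
#'
#' Each point penetrating the master surface by depth `delta` receives a
#' purely normal force `kn * delta`; separated points receive none.  The
#' master outward normal of a segment (x1,y1)->(x2,y2) is the direction
#' rotated 90 degrees counter-clockwise; order segments so normals point
#' toward the slave side.
#'
#' @param points slave point positions, n x 2 (m).
#' @param segments master segments, m x 4 (x1, y1, x2, y2) (m).
#' @param kn per-point penalty stiffness (N/m per metre thickness), scalar or
#'   length n.
#' @param yoff vertical offset applied to the master segments (rigid-body
#'   translation), m.
#' @return list with `force` (n x 2), `master_fy` (total vertical reaction on
#'   the master), `stored_energy`, `max_penetration`.
#' @export
contact_forces <- function(points, segments, kn, yoff = 0) {
  points <- as.matrix(points)
  segments <- matrix(segments, ncol = 4)
  if (any(kn <= 0)) stop("penalty stiffness must be > 0")
  kn <- rep_len(kn, nrow(points))
  fem_contact_once(segments, yoff, points, kn)
}

#' Run the explicit central-difference integration
#'
#' Low-level driver around the compiled leapfrog loop.  Monitors are
#' (element, xi, eta) probes of the stress/strain field; probes record nodal
#' kinematics.  Contact surfaces are either static walls or one-DOF vertical
#' rigid bodies.
#'
#' @param model a `fem_model`.
#' @param dt time step, s.
#' @param nsteps number of steps.
#' @param v0,u0 initial nodal velocity/displacement, n x 2 (m/s, m).
#' @param fixed n x 2 logical matrix of constrained DOFs.
#' @param contacts list of contact surfaces: each
#'   `list(segs, rigid, mass, v0, slaves, kn)` with `segs` an m x 4 segment
#'   matrix (m), `slaves` node ids and `kn` per-slave penalty stiffness.
#' @param monitors data.frame with `elem`, `xi`, `eta` (and optionally
#'   `name`).
#' @param probes node ids whose displacement/velocity are recorded.
#' @param out_every record every this many steps.
#' @param snap_every store full-field snapshots every this many steps (0 =
#'   none).
#' @param jac_every NaN/element-inversion screening interval in steps.
#' @param bvisc linear bulk-viscosity coefficient (fraction of critical,
#'   applied to the volumetric strain rate; the standard explicit-dynamics
#'   regularization of dilatational ringing).  Default 0.06; set 0 for
#'   undamped benchmark problems.
#' @return list with `times` (s), monitor matrices `mon_vm`, `mon_e1`,
#'   `mon_s1`, an `energy` data.frame (kinetic, internal stored, viscous
#'   dissipated, contact stored, internal work, momentum), probe and
#'   snapshot arrays, final state, and a `status`.
#' @export
run_explicit <- function(model, dt, nsteps, v0 = NULL, u0 = NULL,
                         fixed = NULL, contacts = list(), monitors = NULL,
                         probes = integer(0), out_every = 1L, snap_every = 0L,
                         jac_every = NULL, bvisc = 0.06) {
  nn <- nrow(model$nodes)
  if (is.null(v0)) v0 <- matrix(0, nn, 2)
  if (is.null(u0)) u0 <- matrix(0, nn, 2)
  if (is.null(fixed)) fixed <- matrix(FALSE, nn, 2)
  if (is.null(jac_every)) jac_every <- max(1L, as.integer(out_every))
  if (dt <= 0 || nsteps < 1) stop("dt must be > 0 and nsteps >= 1")
  mass <- lumped_mass(model)
  if (any(mass <= 0)) stop("non-positive lumped mass (degenerate element?)")
  me <- integer(0); mxi <- numeric(0); meta <- numeric(0); mnm <- character(0)
  if (!is.null(monitors) && nrow(monitors) > 0) {
    me <- as.integer(monitors$elem); mxi <- monitors$xi; meta <- monitors$eta
    mnm <- if (!is.null(monitors$name)) monitors$name
           else paste0("monitor", seq_along(me))
  }
  res <- fem_run(model$nodes, model$elements, model$emat, mass,
                 fixed[, 1], fixed[, 2], u0[, 1], u0[, 2], v0[, 1], v0[, 2],
                 contacts, dt, as.integer(nsteps), as.integer(out_every),
                 me, mxi, meta, as.integer(probes), as.integer(snap_every),
                 as.integer(jac_every), bvisc)
  keep <- seq_len(res$n_out)
  en <- res$energy[keep, , drop = FALSE]
  energy <- data.frame(time = en[, 8], kinetic = en[, 1], internal = en[, 2],
                       viscous_dissipated = en[, 3], contact_penalty = en[, 4],
                       internal_work = en[, 5], momentum_x = en[, 6],
                       momentum_y = en[, 7])
  dimnames(res$mon_vm) <- dimnames(res$mon_e1) <- dimnames(res$mon_s1) <-
    list(mnm, NULL)
  out <- list(times = res$times[keep],
              mon_vm = res$mon_vm[, keep, drop = FALSE],
              mon_e1 = res$mon_e1[, keep, drop = FALSE],
              mon_s1 = res$mon_s1[, keep, drop = FALSE],
              energy = energy,
              rigid_y = res$rigid_y[, keep, drop = FALSE],
              rigid_v = res$rigid_v[, keep, drop = FALSE],
              probe_u = res$probe_u[, keep, drop = FALSE],
              probe_v = res$probe_v[, keep, drop = FALSE],
              snapshots = if (res$n_snap > 0)
                list(times = res$snap_t[seq_len(res$n_snap)],
                     u = res$snap_u[, seq_len(res$n_snap), drop = FALSE],
                     vel = res$snap_vel[, seq_len(res$n_snap), drop = FALSE],
                     von_mises = res$snap_vm[, seq_len(res$n_snap), drop = FALSE],
                     max_principal_strain = res$snap_e1[, seq_len(res$n_snap),
                                                        drop = FALSE])
              else NULL,
              final = list(u = cbind(res$ux, res$uy), v = cbind(res$vx, res$vy),
                           state = res$state),
              max_penetration = res$max_penetration,
              dt = dt, nsteps = nsteps,
              status = list(ok = res$ok, message = res$message,
                            bad_elem = res$bad_elem, bad_time = res$bad_time))
  class(out) <- "explicit_result"
  out
}

#' Energy-ledger audit
#'
#' Residual of the energy balance kinetic + stored internal + viscous
#' dissipated + contact penalty storage - external work against the initial
#' kinetic energy, maximized over the recorded history.  With zero initial
#' kinetic energy the absolute residual is returned (attribute `"absolute"`
#' set to `TRUE`).
#'
#' @param result an `explicit_result` from [run_explicit()].
#' @param external_work external work history (J/m), default 0.
#' @return relative (or absolute) energy residual.
#' @export
energy_audit <- function(result, external_work = 0) {
  en <- result$energy
  tot <- en$kinetic + en$internal + en$viscous_dissipated +
    en$contact_penalty - external_work
  e0 <- tot[1]
  if (abs(e0) > 0) {
    res <- max(abs(tot - e0)) / abs(e0)
    attr(res, "absolute") <- FALSE
  } else {
    res <- max(abs(tot - e0))
    attr(res, "absolute") <- TRUE
  }
  res
}

#' Momentum drift of a free system
#'
#' @param result an `explicit_result`.
#' @return maximum drift of total momentum magnitude relative to its initial
#'   magnitude.
#' @export
momentum_drift <- function(result) {
  en <- result$energy
  p0 <- c(en$momentum_x[1], en$momentum_y[1])
  n0 <- sqrt(sum(p0^2))
  if (n0 == 0) return(max(sqrt(en$momentum_x^2 + en$momentum_y^2)))
  max(sqrt((en$momentum_x - p0[1])^2 + (en$momentum_y - p0[2])^2)) / n0
}

#' Single-element stress-relaxation test
#'
#' Drives one plane-strain quad of the given material through a step simple
#' shear held constant and records the apparent relaxation modulus
#' (shear stress / applied shear strain) at the requested times, exercising
#' the full element-assembly stress path rather than the scalar kernel.
#'
#' @param material a [prony_material()].
#' @param gamma0 applied engineering shear strain.
#' @param times output times, ms (strictly positive, increasing).
#' @return data.frame with `t_ms` and `G_apparent` (Pa).
#' @export
element_relaxation <- function(material, gamma0 = 0.01,
                               times = c(1e-4, seq(0.5, 500, by = 0.5))) {
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("times must be positive and strictly increasing")
  mesh <- make_block_mesh(1, 1, c(0, 1), c(0, 1), region = "specimen",
                          material = material$name)
  mats <- stats::setNames(list(material), material$name)
  model <- assemble_model(mesh, mats)
  # simple shear u_x = gamma * y (y in m)
  u <- cbind(gamma0 * model$nodes[, 2], 0)
  dts <- diff(c(0, times)) * 1e-3
  state <- NULL
  G <- numeric(length(times))
  for (i in seq_along(dts)) {
    r <- internal_forces(model, u, dt = dts[i], state = state)
    state <- r$state
    G[i] <- r$sigma[1, 3] / gamma0
  }
  data.frame(t_ms = times, G_apparent = G)
}
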