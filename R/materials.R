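# Constitutive models: two-term Prony-series linear viscoelasticity for the
# brain regions, isotropic linear elasticity for skull and impactor metals.
#
# Convention adopted for the printed tables: G(t) = G0 * (gL + g1*exp(-t/tau1)
# + g2*exp(-t/tau2)), i.e. the tabulated G0 is the instantaneous shear modulus
# scale and the dimensionless ratio columns sum to ~1.  Material tables are
# stored as printed (Pa, ms, kg/m^3); conversion to SI (s) happens in one
# audited place, `material_si_row()`.

#' Prony-series viscoelastic material
#'
#' Constructs a linear viscoelastic shear material with a two-term Prony
#' relaxation series \eqn{G(t) = G_0 (g_L + g_1 e^{-t/\tau_1} + g_2
#' e^{-t/\tau_2})}.  The deviatoric response is viscoelastic; the volumetric
#' response is elastic, governed by `poisson_eff` (see
#' [volumetric_stress()]).
#'
#' @param name region/material name.
#' @param G0 instantaneous shear modulus scale, Pa.
#' @param g1,g2,gL dimensionless Prony ratios; `gL` is the long-term ratio
#'   (so \eqn{G_\infty = G_0 g_L}).
#' @param tau1,tau2 relaxation times, ms.
#' @param density mass density, kg/m^3.
#' @param poisson_eff effective Poisson ratio for the elastic volumetric
#'   response, in (0, 0.5).
#' @param quiet suppress the ratio-sum warning (used for tabulated materials
#'   whose printed ratio sums are intentionally kept as published).
#' @return an object of class `prony_material`.
#' @export
prony_material <- function(name, G0, g1, g2, gL, tau1, tau2,
                           density = 1040, poisson_eff = 0.4995,
                           quiet = FALSE) {
  if (!is.numeric(G0) || G0 <= 0) stop("G0 must be > 0")
  if (g1 < 0 || g2 < 0 || gL <= 0) stop("Prony ratios must be positive (gL > 0)")
  if (tau1 <= 0 || tau2 <= 0) stop("relaxation times must be > 0")
  if (poisson_eff <= 0 || poisson_eff >= 0.5)
    stop("poisson_eff must lie in (0, 0.5)")
  gsum <- g1 + g2 + gL
  if (gsum < 0.80 || gsum > 1.05)
    stop(sprintf("Prony ratio sum %.3f outside admissible range [0.80, 1.05]", gsum))
  if (!quiet && (gsum < 0.99 || gsum > 1.01))
    warning(sprintf("Prony ratio sum %.3f for '%s' deviates from 1", gsum, name))
  structure(list(name = name, G0 = G0, g1 = g1, g2 = g2, gL = gL,
                 tau1 = tau1, tau2 = tau2, density = density,
                 poisson_eff = poisson_eff),
            class = "prony_material")
}

#' Isotropic linear elastic material
#'
#' @param name material name.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @param density mass density, kg/m^3.
#' @return an object of class `elastic_material`.
#' @export
elastic_material <- function(name, E, nu, density) {
  if (E <= 0) stop("E must be > 0")
  if (nu <= -1 || nu >= 0.5) stop("nu must lie in (-1, 0.5)")
  if (density <= 0) stop("density must be > 0")
  structure(list(name = name, E = E, nu = nu, density = density),
            class = "elastic_material")
}

#' @export
print.prony_material <- function(x, ...) {
  cat(sprintf("<prony_material '%s'>  G0 = %g Pa, g = (%.3f, %.3f, %.3f), tau = (%g, %g) ms, rho = %g kg/m^3\n",
              x$name, x$G0, x$g1, x$g2, x$gL, x$tau1, x$tau2, x$density))
  invisible(x)
}

#' @export
print.elastic_material <- function(x, ...) {
  cat(sprintf("<elastic_material '%s'>  E = %g Pa, nu = %g, rho = %g kg/m^3\n",
              x$name, x$E, x$nu, x$density))
  invisible(x)
}

#' Built-in material table
#'
#' The six tabulated P56 mouse-brain regions (hippocampus parameters are the
#' published adult-rat fit), the skull, and the impactor metals.  Values are
#' stored exactly as published; the hippocampus Prony ratio sum (0.862) is
#' retained as printed, not renormalized.
#'
#' @param poisson_eff effective Poisson ratio assigned to brain materials.
#' @return named list of [prony_material()] / [elastic_material()] objects
#'   with names `Pons`, `Cortex`, `Cerebellum`, `Thalamus`, `Medulla`,
#'   `Hippocampus`, `Skull`, `Brass`, `Nylon`.
#' @export
builtin_material_table <- function(poisson_eff = 0.4995) {
  rows <- list(
    c(7643, 0.578, 0.267, 0.162, 12, 182),   # Pons
    c(6343, 0.568, 0.264, 0.168, 14, 182),   # Cortex
    c(2807, 0.518, 0.310, 0.171, 14, 190),   # Cerebellum
    c(2674, 0.578, 0.248, 0.174, 15, 206),   # Thalamus
    c(3859, 0.520, 0.300, 0.180, 17, 226),   # Medulla
    c(5422, 0.187, 0.554, 0.121, 265, 18))   # Hippocampus
  names(rows) <- c("Pons", "Cortex", "Cerebellum", "Thalamus", "Medulla",
                   "Hippocampus")
  mats <- lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    prony_material(nm, G0 = r[1], g1 = r[2], g2 = r[3], gL = r[4],
                   tau1 = r[5], tau2 = r[6], density = 1040,
                   poisson_eff = poisson_eff, quiet = TRUE)
  })
  names(mats) <- names(rows)
  mats$Skull <- elastic_material("Skull", E = 1e9, nu = 0.33, density = 1710)
  mats$Brass <- elastic_material("Brass", E = 100e9, nu = 0.34, density = 8480)
  mats$Nylon <- elastic_material("Nylon", E = 2.3e9, nu = 0.40, density = 1120)
  mats
}

#' Look up one built-in material
#'
#' @param name material name (case sensitive, e.g. `"Thalamus"`).
#' @param ... passed to [builtin_material_table()].
#' @export
builtin_material <- function(name, ...) {
  tab <- builtin_material_table(...)
  if (!name %in% names(tab))
    stop(sprintf("unknown material '%s'; available: %s", name,
                 paste(names(tab), collapse = ", ")))
  tab[[name]]
}

#' Shear relaxation modulus G(t)
#'
#' Evaluates the Prony relaxation function \eqn{G(t) = G_0 (g_L + g_1
#' e^{-t/\tau_1} + g_2 e^{-t/\tau_2})}.
#'
#' @param m a [prony_material()].
#' @param t time(s) since the step strain, ms; must be >= 0 (vectorized).
#' @return shear modulus in Pa, same length as `t`.
#' @export
relaxation_modulus <- function(m, t) {
  stopifnot(inherits(m, "prony_material"))
  if (any(t < 0)) stop("t must be >= 0")
  m$G0 * (m$gL + m$g1 * exp(-t / m$tau1) + m$g2 * exp(-t / m$tau2))
}

#' Instantaneous shear modulus G(0+) = G0 * (g1 + g2 + gL)
#' @param m a `prony_material` or `elastic_material`.
#' @export
instantaneous_shear_modulus <- function(m) {
  if (inherits(m, "elastic_material")) return(m$E / (2 * (1 + m$nu)))
  m$G0 * (m$g1 + m$g2 + m$gL)
}

#' Elastic bulk modulus of a material
#'
#' For viscoelastic materials \eqn{K = 2 G_{inst} (1+\nu) / (3 (1-2\nu))}
#' with \eqn{G_{inst} = G_0 (g_1+g_2+g_L)} and \eqn{\nu} the effective
#' Poisson ratio; for elastic materials \eqn{K = E / (3(1-2\nu))}.
#' @param m material object.
#' @export
bulk_modulus <- function(m) {
  if (inherits(m, "elastic_material")) {
    return(m$E / (3 * (1 - 2 * m$nu)))
  }
  nu <- m$poisson_eff
  if (nu >= 0.5) stop("poisson_eff must be < 0.5")
  2 * instantaneous_shear_modulus(m) * (1 + nu) / (3 * (1 - 2 * nu))
}

#' Elastic volumetric (pressure) response
#'
#' Pure elastic pressure `p = -K * vol_strain` with `K` from
#' [bulk_modulus()]; positive `p` in compression.
#'
#' @param m material object.
#' @param vol_strain volumetric strain (trace of the strain tensor),
#'   |vol_strain| < 0.5.
#' @return pressure, Pa.
#' @export
volumetric_stress <- function(m, vol_strain) {
  if (any(abs(vol_strain) >= 0.5))
    stop("volumetric strain out of range (|ev| < 0.5 expected)")
  -bulk_modulus(m) * vol_strain
}

#' Fresh viscoelastic point state
#'
#' State carried by [deviatoric_stress_update()]: accumulated deviatoric
#' strain, the two Prony internal stress tensors (components xx, yy, xy;
#' zz follows from trace-freeness), accumulated deviatoric work and
#' dissipation.
#' @export
visco_state <- function() {
  list(e = c(0, 0, 0), s1 = c(0, 0, 0), s2 = c(0, 0, 0),
       work = 0, dissipated = 0)
}

#' Incremental deviatoric stress update (hereditary integral kernel)
#'
#' Advances the Prony internal variables over one time step: each branch
#' decays by \eqn{e^{-dt/\tau_i}} after accruing the increment's contribution
#' (the increment is treated as a jump at the step start, which reproduces
#' step-strain relaxation exactly and is first-order accurate for smooth
#' histories).
#'
#' @param vs state from [visco_state()] or a previous call.
#' @param m a [prony_material()].
#' @param dstrain trace-free in-plane deviatoric strain increment: either a
#'   2x2 symmetric matrix or a length-3 vector `c(dexx, deyy, dexy)` (tensor
#'   shear component).
#' @param dt time step, ms.
#' @return list with `stress` (length 4: sxx, syy, sxy, szz of the deviatoric
#'   stress, Pa) and `state` (updated state).
#' @export
deviatoric_stress_update <- function(vs, m, dstrain, dt) {
  stopifnot(inherits(m, "prony_material"))
  if (dt <= 0) stop("dt must be > 0")
  if (is.matrix(dstrain)) {
    if (any(dim(dstrain) != c(2, 2)) ||
        abs(dstrain[1, 2] - dstrain[2, 1]) > 1e-12 * max(1, max(abs(dstrain))))
      stop("dstrain must be a symmetric 2x2 matrix")
    dstrain <- c(dstrain[1, 1], dstrain[2, 2], dstrain[1, 2])
  }
  tr <- dstrain[1] + dstrain[2]
  if (abs(tr) > 1e-12 * max(1, max(abs(dstrain))))
    stop("deviatoric strain increment must be trace-free")
  f1 <- exp(-dt / m$tau1)
  f2 <- exp(-dt / m$tau2)
  s1 <- f1 * (vs$s1 + 2 * m$G0 * m$g1 * dstrain)
  s2 <- f2 * (vs$s2 + 2 * m$G0 * m$g2 * dstrain)
  e <- vs$e + dstrain
  sL <- 2 * m$G0 * m$gL * e
  stot <- sL + s1 + s2
  szz <- -(stot[1] + stot[2])
  # deviatoric work (midpoint) and stored energy -> dissipation ledger
  sprev <- 2 * m$G0 * m$gL * vs$e + vs$s1 + vs$s2
  smid <- 0.5 * (stot + sprev)
  dwork <- smid[1] * dstrain[1] + smid[2] * dstrain[2] + 2 * smid[3] * dstrain[3]
  phi <- function(s) {
    zz <- -(s[1] + s[2])
    s[1]^2 + s[2]^2 + zz^2 + 2 * s[3]^2
  }
  stored <- phi(sL) / (4 * m$G0 * m$gL)
  if (m$g1 > 0) stored <- stored + phi(s1) / (4 * m$G0 * m$g1)
  if (m$g2 > 0) stored <- stored + phi(s2) / (4 * m$G0 * m$g2)
  work <- vs$work + dwork
  state <- list(e = e, s1 = s1, s2 = s2, work = work,
                dissipated = max(vs$dissipated, work - stored))
  list(stress = c(stot, szz), state = state)
}

# Single audited unit conversion: one material -> per-element SI row
# (G0 Pa, g1, g2, gL, tau1 s, tau2 s, K Pa, rho kg/m^3) as consumed by the
# compiled solver.  Elastic materials map onto the same Prony structure with
# g1 = g2 = 0, gL = 1.
material_si_row <- function(m) {
  if (inherits(m, "elastic_material")) {
    G <- m$E / (2 * (1 + m$nu))
    K <- m$E / (3 * (1 - 2 * m$nu))
    return(c(G0 = G, g1 = 0, g2 = 0, gL = 1, tau1 = 1, tau2 = 1,
             K = K, rho = m$density))
  }
  stopifnot(inherits(m, "prony_material"))
  c(G0 = m$G0, g1 = m$g1, g2 = m$g2, gL = m$gL,
    tau1 = m$tau1 * 1e-3, tau2 = m$tau2 * 1e-3,
    K = bulk_modulus(m), rho = m$density)
}

#' Export the built-in material table to CSV
#'
#' @param path output file.
#' @param ... passed to [builtin_material_table()].
#' @export
write_material_table <- function(path, ...) {
  tab <- builtin_material_table(...)
  rows <- lapply(tab, function(m) {
    if (inherits(m, "prony_material"))
      data.frame(name = m$name, model = "prony", G0_Pa = m$G0, g1 = m$g1,
                 g2 = m$g2, gL = m$gL, tau1_ms = m$tau1, tau2_ms = m$tau2,
                 E_Pa = NA, nu = m$poisson_eff, density_kg_m3 = m$density)
    else
      data.frame(name = m$name, model = "elastic", G0_Pa = NA, g1 = NA,
                 g2 = NA, gL = NA, tau1_ms = NA, tau2_ms = NA, E_Pa = m$E,
                 nu = m$nu, density_kg_m3 = m$density)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a material override block
#'
#' Accepts a named list (e.g. parsed from the `materials:` block of a YAML
#' config) where each entry has either Prony fields (`G0`, `g1`, `g2`, `gL`,
#' `tau1`, `tau2`) or elastic fields (`E`, `nu`), plus `density`.  Unlisted
#' materials fall back to the built-in table.
#'
#' @param overrides named list of material definitions, may be `NULL`.
#' @param poisson_eff default effective Poisson ratio for Prony entries.
#' @export
material_table_with_overrides <- function(overrides = NULL, poisson_eff = 0.4995) {
  tab <- builtin_material_table(poisson_eff = poisson_eff)
  if (is.null(overrides)) return(tab)
  for (nm in names(overrides)) {
    o <- overrides[[nm]]
    tab[[nm]] <- if (!is.null(o$E)) {
      elastic_material(nm, E = o$E, nu = o$nu, density = o$density)
    } else {
      prony_material(nm, G0 = o$G0, g1 = o$g1, g2 = o$g2, gL = o$gL,
                     tau1 = o$tau1, tau2 = o$tau2, density = o$density,
                     poisson_eff = if (is.null(o$poisson_eff)) poisson_eff
                                   else o$poisson_eff)
    }
  }
  tab
}
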