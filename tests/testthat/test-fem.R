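# Solver building blocks: mass lumping, internal forces, contact, stable
# time step, integration benchmarks, energy and momentum ledgers.

test_that("lumped mass reproduces density x area and is conserved on refinement", {
  mats <- builtin_material_table()
  # 1 m x 1 m of brain tissue (coordinates are mm)
  m1 <- assemble_model(make_block_mesh(1, 1, c(0, 1000), c(0, 1000),
                                       material = "Cortex"), mats)
  expect_equal(sum(lumped_mass(m1)), 1040, tolerance = 1e-9)
  m2 <- assemble_model(make_block_mesh(4, 4, c(0, 1000), c(0, 1000),
                                       material = "Cortex"), mats)
  expect_equal(sum(lumped_mass(m2)), 1040, tolerance = 1e-9)
  # skull element of area A -> A x 1710
  m3 <- assemble_model(make_block_mesh(2, 3, c(0, 40), c(0, 30),
                                       material = "Skull"), mats)
  expect_equal(sum(lumped_mass(m3)), 1710 * 0.04 * 0.03, tolerance = 1e-12)
  expect_true(all(lumped_mass(m3) > 0))
})

test_that("rigid translations produce no internal forces; forces self-equilibrate", {
  model <- assemble_model(make_block_mesh(4, 3, c(0, 8), c(0, 6),
                                          material = "Thalamus"))
  nn <- nrow(model$nodes)
  u <- matrix(rep(c(3e-4, -2e-4), each = nn), nn, 2)
  f <- internal_forces(model, u)$force
  expect_lt(max(abs(f)), 1e-12)
  # random small displacement fields: Newton's third law (sum of forces = 0)
  set.seed(42)
  for (i in 1:5) {
    u <- matrix(rnorm(2 * nn, sd = 1e-5), nn, 2)
    f <- internal_forces(model, u)$force
    expect_lt(max(abs(colSums(f))), 1e-9 * sum(abs(f)))
  }
})

test_that("single elastic element matches the plane-strain closed form", {
  mat <- elastic_material("el", E = 1.2e6, nu = 0.3, density = 1000)
  model <- assemble_model(make_block_mesh(1, 1, c(0, 1000), c(0, 1000),
                                          region = "el", material = "el"),
                          stats::setNames(list(mat), "el"))
  eps <- 1e-4
  u <- cbind(eps * model$nodes[, 1], 0)  # uniform uniaxial strain exx
  f <- internal_forces(model, u)$force
  G <- mat$E / (2 * (1 + mat$nu))
  K <- mat$E / (3 * (1 - 2 * mat$nu))
  sxx <- (K + 4 * G / 3) * eps
  syy <- (K - 2 * G / 3) * eps
  # closed-form consistent nodal forces of a unit square under uniform
  # stress; node storage order is (0,0), (1,0), (0,1), (1,1)
  expect_equal(f, rbind(c(sxx, syy), c(-sxx, syy), c(sxx, -syy), c(-sxx, -syy)) / 2,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stable time step follows the dilatational CFL bound", {
  mat <- elastic_material("el", E = 1e6, nu = 0.25, density = 2000)
  model <- assemble_model(make_block_mesh(1, 1, c(0, 2), c(0, 2),
                                          region = "el", material = "el"),
                          stats::setNames(list(mat), "el"))
  G <- 1e6 / (2 * 1.25)
  K <- 1e6 / (3 * 0.5)
  cw <- sqrt((K + 4 * G / 3) / 2000)
  h <- (2e-3 * 2e-3) / (2e-3 * sqrt(2))  # area / max diagonal
  expect_equal(stable_dt(model, safety = 0.8), 0.8 * h / cw, tolerance = 1e-12)
  # halving the element size halves dt
  model2 <- assemble_model(make_block_mesh(2, 2, c(0, 2), c(0, 2),
                                           region = "el", material = "el"),
                           stats::setNames(list(mat), "el"))
  expect_equal(stable_dt(model2), stable_dt(model) / 2, tolerance = 1e-12)
  expect_error(stable_dt(model, safety = 0), "safety")
})

test_that("stiff skull elements, not brain, control the default-mesh time step", {
  mesh <- build_sagittal_domain(geometry_spec(target_element_count = 1250))
  model <- assemble_model(mesh)
  tab <- stable_dt_table(model)
  expect_identical(tab$region[which.min(tab$dt_crit)], "skull")
  # brute-force minimum over the per-element table matches stable_dt
  expect_equal(stable_dt(model, 1), min(tab$dt_crit), tolerance = 1e-15)
})

test_that("penalty contact is normal-only, linear in penetration, zero at a gap", {
  # flat master segment at y = 0, normal +y (toward slave below)
  segs <- matrix(c(-1, 0, 1, 0), 1, 4)
  # separated point (on the outward-normal side): no force
  r <- contact_forces(matrix(c(0.2, 0.3), 1, 2), segs, kn = 1e4)
  expect_equal(r$force, matrix(0, 1, 2))
  expect_equal(r$max_penetration, 0)
  # penetration delta -> force kn * delta along +y
  d <- 0.01
  r <- contact_forces(matrix(c(0.2, -d), 1, 2), segs, kn = 1e4)
  expect_equal(r$force[1, ], c(0, -1e4 * d) * -1)
  expect_equal(r$max_penetration, d)
  expect_equal(r$master_fy, -1e4 * d)
  expect_equal(r$stored_energy, 0.5 * 1e4 * d^2)
  # oblique sliding on an inclined segment: force exactly normal (frictionless)
  segs2 <- matrix(c(0, 0, 1, 0.5), 1, 4)
  tvec <- c(1, 0.5) / sqrt(1.25)
  p <- c(0.4, 0.2 - 0.005)  # slightly behind the surface
  r <- contact_forces(matrix(p, 1, 2), segs2, kn = 5e3)
  expect_gt(sqrt(sum(r$force^2)), 0)
  expect_lt(abs(sum(r$force[1, ] * tvec)), 1e-12 * sqrt(sum(r$force^2)))
})

test_that("free flight conserves kinetic energy and momentum to round-off", {
  model <- assemble_model(make_block_mesh(3, 3, c(0, 6), c(0, 6),
                                          material = "Cortex"))
  nn <- nrow(model$nodes)
  v0 <- matrix(rep(c(1.5, -0.5), each = nn), nn, 2)
  res <- run_explicit(model, dt = 1e-6, nsteps = 400, v0 = v0, out_every = 40L)
  en <- res$energy
  expect_lt(max(abs(en$kinetic - en$kinetic[1])), 1e-12 * en$kinetic[1])
  expect_lt(max(abs(en$internal)), 1e-12 * en$kinetic[1])
  expect_lt(momentum_drift(res), 1e-12)
})

test_that("oscillator period and wave arrival match their closed forms", {
  sd <- sdof_period_check()
  expect_lt(sd$rel_error, 0.01)
  wb <- wave_bar_check(nel = 200)
  expect_lt(wb$rel_error, 0.02)
  # analytic speed sanity: c = sqrt((K + 4G/3)/rho) for the cortex row
  m <- builtin_material("Cortex")
  expect_equal(wb$c, sqrt((bulk_modulus(m) +
                           4 * instantaneous_shear_modulus(m) / 3) / 1040),
               tolerance = 1e-12)
})

test_that("elastic penalty bounce conserves energy; relaxation dissipates", {
  bc <- bounce_energy_check()
  expect_lt(bc$residual, 0.02)
  expect_true(bc$rebounded)
  # viscoelastic element under held shear: work splits into stored + dissipated
  model <- single_element_model(builtin_material("Thalamus"))
  u <- cbind(0.05 * model$nodes[, 2], 0)
  state <- NULL
  W <- 0
  for (i in 1:40) {
    r <- internal_forces(model, u, dt = 5e-3, state = state)  # 5 ms steps
    state <- r$state
    W <- W + r$work_increment
  }
  U <- r$stored_energy
  expect_gt(W - U, 0)              # dissipated energy is positive
  expect_lt(U, W)                  # and internal + dissipated = work done
})

test_that("the solver aborts with a diagnostic on blow-up", {
  model <- assemble_model(make_block_mesh(2, 2, c(0, 2), c(0, 2),
                                          material = "Cortex"))
  nn <- nrow(model$nodes)
  v0 <- matrix(0, nn, 2)
  v0[1, ] <- c(5e4, 0)  # absurd velocity at an unstable dt
  dt <- stable_dt(model) * 50
  res <- run_explicit(model, dt, nsteps = 2000, v0 = v0, out_every = 10L,
                      jac_every = 10L)
  expect_false(res$status$ok)
  expect_match(res$status$message, "inverted|NaN")
  expect_false(is.na(res$status$bad_time))
})
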