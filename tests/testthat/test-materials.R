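# Constitutive layer: published material table, Prony relaxation function,
# incremental kernel vs closed forms, volumetric response.

test_that("built-in table carries the published values exactly", {
  tab <- builtin_material_table()
  expect_identical(tab$Pons$G0, 7643)
  expect_identical(tab$Thalamus$G0, 2674)
  expect_identical(tab$Cortex$G0, 6343)
  expect_identical(tab$Hippocampus$tau1, 265)
  expect_identical(tab$Hippocampus$tau2, 18)
  expect_identical(tab$Skull$E, 1e9)
  expect_identical(tab$Skull$density, 1710)
  expect_identical(tab$Brass$density, 8480)
  expect_identical(tab$Nylon$E, 2.3e9)
  # ratio sums as recorded (not renormalized)
  gsum <- function(m) m$g1 + m$g2 + m$gL
  expect_equal(gsum(tab$Cortex), 1.000, tolerance = 1e-3)
  expect_equal(gsum(tab$Thalamus), 1.000, tolerance = 1e-3)
  expect_equal(gsum(tab$Pons), 1.007, tolerance = 1e-9)
  expect_equal(gsum(tab$Hippocampus), 0.862, tolerance = 1e-9)
  expect_error(builtin_material("Granite"), "unknown material")
})

test_that("relaxation modulus follows the Prony closed form and its limits", {
  tab <- builtin_material_table()
  th <- tab$Thalamus
  expect_equal(relaxation_modulus(th, 0), 2674)  # ratio columns sum to 1.000
  # frozen oracle: direct high-precision evaluation of the pons row at 12 ms
  expect_equal(relaxation_modulus(tab$Pons, 12), 4773.80051401291,
               tolerance = 1e-12)
  for (m in tab[c("Pons", "Cortex", "Cerebellum", "Thalamus", "Medulla",
                  "Hippocampus")]) {
    tgrid <- c(0, 10^seq(-2, 4, length.out = 60))
    G <- relaxation_modulus(m, tgrid)
    expect_true(all(diff(G) <= 0))                      # monotone non-increasing
    expect_true(all(G <= m$G0 * (m$g1 + m$g2 + m$gL) + 1e-9))
    expect_true(all(G >= m$G0 * m$gL - 1e-9))           # G(inf) floor
    expect_equal(relaxation_modulus(m, 1e7), m$G0 * m$gL, tolerance = 1e-6)
  }
  expect_error(relaxation_modulus(th, -1), "t must be")
})

test_that("kernel reproduces step-strain relaxation within 0.5% at dt = tau_min/20", {
  tab <- builtin_material_table()
  for (nm in c("Pons", "Cortex", "Cerebellum", "Thalamus", "Medulla",
               "Hippocampus")) {
    m <- tab[[nm]]
    dt <- min(m$tau1, m$tau2) / 20
    vs <- visco_state()
    gamma0 <- 0.01
    up <- deviatoric_stress_update(vs, m, c(0, 0, gamma0 / 2), dt)
    times <- dt
    err <- abs(up$stress[3] - gamma0 * relaxation_modulus(m, dt)) /
      (gamma0 * relaxation_modulus(m, dt))
    while (times < 500) {
      up <- deviatoric_stress_update(up$state, m, c(0, 0, 0), dt)
      times <- times + dt
      ref <- gamma0 * relaxation_modulus(m, times)
      err <- max(err, abs(up$stress[3] - ref) / ref)
    }
    expect_lt(err, 0.005)
  }
})

test_that("kernel is first-order accurate against the hereditary-integral closed form", {
  m <- builtin_material("Cortex")
  # constant shear strain rate 0.02/ms for 20 ms; frozen closed-form stress
  sigma_ref <- 1827.61190882926
  run <- function(dt) {
    vs <- visco_state()
    n <- round(20 / dt)
    dg <- 0.02 * dt
    for (i in seq_len(n))
      vs <- deviatoric_stress_update(vs, m, c(0, 0, dg / 2), dt)$state
    s <- deviatoric_stress_update(vs, m, c(0, 0, 0), 1e-9)$stress[3]
    s
  }
  e1 <- abs(run(0.5) - sigma_ref)
  e2 <- abs(run(0.25) - sigma_ref)
  expect_lt(e2, e1)
  expect_lt(e2 / e1, 0.65)  # error halves when dt halves (O(dt))
})

test_that("kernel rejects bad increments and dissipation behaves", {
  m <- builtin_material("Thalamus")
  vs <- visco_state()
  expect_error(deviatoric_stress_update(vs, m, c(0.01, 0.01, 0), 0.1),
               "trace-free")
  expect_error(deviatoric_stress_update(vs, m, c(0.01, -0.01, 0), 0),
               "dt must be")
  # zero history -> zero stress
  up <- deviatoric_stress_update(vs, m, c(0, 0, 0), 1)
  expect_equal(up$stress, c(0, 0, 0, 0))
  # held shear dissipates monotonically in a viscoelastic material
  up <- deviatoric_stress_update(vs, m, c(0, 0, 0.005), 1)
  d <- up$state$dissipated
  for (i in 1:50) {
    up <- deviatoric_stress_update(up$state, m, c(0, 0, 0), 5)
    expect_gte(up$state$dissipated, d)
    d <- up$state$dissipated
  }
  expect_gt(d, 0)
  # purely elastic limit (g1 = g2 = 0, gL = 1): no dissipation
  el <- prony_material("elastic-limit", G0 = 1000, g1 = 0, g2 = 0, gL = 1,
                       tau1 = 1, tau2 = 1)
  vs <- visco_state()
  up <- deviatoric_stress_update(vs, el, c(0.002, -0.002, 0.001), 0.5)
  for (i in 1:20)
    up <- deviatoric_stress_update(up$state, el,
                                   c(0.001, -0.001, -0.0005) * (-1)^i, 0.5)
  expect_lt(abs(up$state$dissipated), 1e-9 * abs(up$state$work) + 1e-12)
})

test_that("volumetric response is the stated elastic law", {
  th <- builtin_material("Thalamus", poisson_eff = 0.49)
  expect_equal(volumetric_stress(th, 0), 0)
  # frozen hand evaluation: K = 2*2674*1.49/(3*0.02)
  expect_equal(bulk_modulus(th), 132808.666666667, tolerance = 1e-12)
  expect_equal(volumetric_stress(th, -0.001), 132.808666666667,
               tolerance = 1e-12)
  # linearity
  expect_equal(volumetric_stress(th, -0.002), 2 * volumetric_stress(th, -0.001))
  expect_error(volumetric_stress(th, 0.6), "out of range")
  expect_error(prony_material("bad", 1000, 0.5, 0.3, 0.2, 10, 100,
                              poisson_eff = 0.5), "poisson_eff")
})

test_that("material constructors validate and warn as specified", {
  expect_error(prony_material("bad", -1, 0.5, 0.3, 0.2, 10, 100), "G0")
  expect_error(prony_material("bad", 1000, 0.5, 0.3, 0.2, -1, 100),
               "relaxation times")
  expect_error(prony_material("bad", 1000, 0.1, 0.1, 0.1, 10, 100),
               "outside admissible range")
  expect_warning(prony_material("offsum", 1000, 0.5, 0.3, 0.15, 10, 100),
                 "deviates from 1")
  expect_silent(prony_material("onsum", 1000, 0.5, 0.3, 0.2, 10, 100))
  expect_error(elastic_material("bad", 1e9, 0.6, 1000), "nu")
})
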