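# Synthetic sagittal geometry: element counts, labeling, monitors,
# mesh quality, refinement invariants, impactor construction.

test_that("default domain meets the target count with valid labeled quads", {
  mesh <- build_sagittal_domain(geometry_spec(target_element_count = 5000))
  ne <- nrow(mesh$elements)
  expect_gte(ne, 4000)
  expect_lte(ne, 6250)
  expect_true(all(mesh_jacobian_min(mesh) > 0))
  expect_setequal(unique(mesh$region),
                  c("cortex", "hippocampus", "thalamus", "cerebellum",
                    "medulla", "midbrain", "pons", "skull"))
  expect_true(all(nchar(mesh$region) > 0))
  # skull shell present on the dorsal boundary: skull elements above the brain
  sk <- which(mesh$region == "skull")
  ymin_sk <- min(mesh$nodes[mesh$elements[sk, ], 2])
  expect_lt(ymin_sk, 0.5)  # reaches the outer dorsal surface near y = 0
})

test_that("degenerate specs raise validation errors naming the field", {
  expect_error(geometry_spec(skull_thickness = 0), "skull_thickness")
  expect_error(geometry_spec(brain_width = -1), "brain_width")
  lay <- default_region_layout()
  expect_error(geometry_spec(region_layout = lay[0, ]), "region_layout")
  expect_error(geometry_spec(region_layout = lay[-1, ]), "region_layout")
  lay2 <- lay; lay2$u1[2] <- 1.4
  expect_error(geometry_spec(region_layout = lay2), "fractions")
})

test_that("identical spec and seed give byte-identical meshes", {
  s <- geometry_spec(target_element_count = 1250, seed = 7L, jitter = 0.1)
  m1 <- build_sagittal_domain(s)
  m2 <- build_sagittal_domain(s)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  m3 <- build_sagittal_domain(geometry_spec(target_element_count = 1250,
                                            seed = 8L, jitter = 0.1))
  expect_false(identical(m1$nodes, m3$nodes))
})

test_that("monitors sit at the published offsets inside their regions", {
  mesh <- build_sagittal_domain(geometry_spec(target_element_count = 1250))
  mon <- mesh$monitors
  expect_equal(mon$name, c("cortex", "thalamus", "substantia_nigra",
                           "cerebellum", "brainstem"))
  expect_equal(mon$x, c(0, 0, 0, 4.7, 4.7))
  expect_equal(mon$y, c(2.4, 4.1, 8.2, 4.1, 8.2))
  expect_equal(mon$region, c("cortex", "thalamus", "midbrain", "cerebellum",
                             "pons"))
  # local coordinates inside the isoparametric square
  expect_true(all(abs(mon$xi) <= 1 + 1e-8))
  expect_true(all(abs(mon$eta) <= 1 + 1e-8))
  # each monitor position reproduces from its host element's bilinear map
  for (i in seq_len(nrow(mon))) {
    xn <- mesh$nodes[mesh$elements[mon$elem[i], ], ]
    N <- 0.25 * c((1 - mon$xi[i]) * (1 - mon$eta[i]),
                  (1 + mon$xi[i]) * (1 - mon$eta[i]),
                  (1 + mon$xi[i]) * (1 + mon$eta[i]),
                  (1 - mon$xi[i]) * (1 + mon$eta[i]))
    expect_equal(colSums(N * xn), c(mon$x[i], mon$y[i]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("monitors outside a shallow brain raise a placement error", {
  mesh <- suppressWarnings(
    build_sagittal_domain(geometry_spec(brain_height = 6,
                                        target_element_count = 1250)))
  expect_error(place_monitors(mesh), "substantia_nigra")
})

test_that("region areas are conserved under 4x refinement", {
  a1 <- region_areas(build_sagittal_domain(geometry_spec(target_element_count = 1250)))
  a2 <- region_areas(build_sagittal_domain(geometry_spec(target_element_count = 5000)))
  for (rg in names(a1))
    expect_lt(abs(a2[[rg]] - a1[[rg]]) / a1[[rg]], 0.01)
})

test_that("impactor carries published materials and reports its mass", {
  imp <- build_impactor(impactor_spec())
  expect_true(attr(imp, "rigid"))
  expect_equal(attr(imp, "mass_per_thickness"), 13.75)
  # geometric mass = sum over blocks of density x area (kg per metre)
  ar <- region_areas(imp) * 1e-6
  expect_equal(attr(imp, "mass_geometric"),
               unname(8480 * ar[["impactor_body"]] + 1120 * ar[["impactor_tip"]]),
               tolerance = 1e-12)
  # brass-only impactor: mass = 8480 * area
  brass <- build_impactor(impactor_spec(tip_material = "Brass"))
  expect_equal(attr(brass, "mass_geometric"),
               unname(8480 * sum(region_areas(brass)) * 1e-6), tolerance = 1e-12)
  expect_equal(builtin_material("Nylon")$E, 2.3e9)
  expect_error(build_impactor(impactor_spec(tip_material = "Teflon")),
               "unknown material")
  # concave tip: face edges lower (larger y) than the recessed center
  fs <- attr(imp, "face_segments")
  expect_lt(min(fs[, c(2, 4)]), 0)
  expect_equal(max(fs[, c(2, 4)]), 0)
})
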