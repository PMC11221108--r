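test_that("absorption enters the slab solution only through exp(-mua v t)", {
  g <- grid_20ps
  with_abs <- slab_td_reflectance(test_props(0.1), slab_geometry(5), 3, g)
  no_abs <- slab_td_reflectance(test_props(0), slab_geometry(5), 3, g)
  v <- 29.9792458 / 1.4
  predicted <- no_abs$value * exp(-0.1 * v * g$centers)
  keep <- with_abs$value > 0
  expect_true(any(keep))
  expect_lt(max(abs(predicted[keep] / with_abs$value[keep] - 1)), 1e-12)
})

test_that("slab reflectance is causal, finite and non-negative", {
  curve <- slab_td_reflectance(test_props(), slab_geometry(5), 3, grid_8ps)
  expect_true(all(is.finite(curve$value)))
  expect_true(all(curve$value >= 0))
  expect_lt(curve$value[1], 1e-12 * max(curve$value))
})

test_that("slab solution matches the frozen independent reference value", {
  # flux density at the 8-ps bin center nearest 1 ns, sdd 3 cm,
  # mua 0.1, musp 10, n 1.4, 5-cm slab; reference from an independently coded
  # image-series evaluation (quadrature-checked)
  curve <- slab_td_reflectance(test_props(0.1), slab_geometry(5), 3, grid_8ps)
  i <- which.min(abs(curve$time - 1.0))
  expect_equal(curve$time[i], 0.996)
  expect_equal(curve$value[i] / 0.008, 5.1955986879745065e-05,
               tolerance = 1e-8)
})

test_that("invalid optical properties and geometries are rejected", {
  expect_error(optical_properties(-0.1, 10), "mua")
  expect_error(optical_properties(0.1, 0), "musp")
  expect_error(optical_properties(0.1, 10, 0.9), "n")
  expect_error(slab_td_reflectance(test_props(), slab_geometry(5), -1,
                                   grid_20ps), "sdd")
  expect_error(bilayer_td_reflectance(test_props(), test_props(),
                                      bilayer_geometry(), 12, grid_20ps),
               "radius")
  expect_error(bilayer_td_reflectance(test_props(),
                                      optical_properties(0.1, 10, 1.33),
                                      bilayer_geometry(), 2, grid_20ps),
               "refractive")
})

test_that("identical-layer bilayer degenerates to the homogeneous slab", {
  props <- test_props(0.1)
  slab <- slab_td_reflectance(props, slab_geometry(5), 3, grid_20ps)
  bil <- bilayer_td_reflectance(props, props, bilayer_geometry(10, 1, 4), 3,
                                grid_20ps)
  expect_lt(attr(bil, "series_tail_rel"), 1e-8)
  keep <- slab$value >= 1e-6 * max(slab$value)
  expect_lt(max(abs(bil$value[keep] / slab$value[keep] - 1)), 0.01)
})

test_that("raising a layer's absorption never raises reflectance, and deep
           changes grow with detection time", {
  base_p <- test_props(0.1136)
  pert_p <- test_props(0.1136 * 1.02)
  base <- bilayer_td_reflectance(base_p, base_p, bilayer_geometry(), 3,
                                 grid_20ps)
  dw <- bilayer_td_reflectance(base_p, pert_p, bilayer_geometry(), 3,
                               grid_20ps)
  up <- bilayer_td_reflectance(pert_p, base_p, bilayer_geometry(), 3,
                               grid_20ps)
  keep <- base$value >= 1e-6 * max(base$value)
  ratio_dw <- dw$value[keep] / base$value[keep]
  expect_true(all(ratio_dw <= 1 + 1e-9))
  expect_true(all(up$value[keep] <= base$value[keep] * (1 + 1e-9)))
  # late photons accumulate deep pathlength: the attenuation deepens with t
  expect_true(all(diff(ratio_dw) <= 1e-6))
})

test_that("early photons at short SDD respond as if the medium were purely
           superficial", {
  base_p <- test_props(0.1136)
  bump_p <- test_props(0.1136 + 0.01)
  base <- bilayer_td_reflectance(base_p, base_p, bilayer_geometry(), 1,
                                 grid_20ps)
  up <- bilayer_td_reflectance(bump_p, base_p, bilayer_geometry(), 1,
                               grid_20ps)
  hom <- bilayer_td_reflectance(bump_p, bump_p, bilayer_geometry(), 1,
                                grid_20ps)
  early <- grid_20ps$centers <= 0.5 & base$value > 1e-9 * max(base$value)
  rel_up <- up$value[early] / base$value[early]
  rel_hom <- hom$value[early] / base$value[early]
  expect_lt(max(abs(rel_up / rel_hom - 1)), 0.05)
})

test_that("cw intensity is a linear functional with the expected SDD falloff", {
  g <- grid_8ps
  zero <- slab_td_reflectance(test_props(), slab_geometry(5), 1, g)
  zero$value <- zero$value * 0
  expect_identical(cw_intensity(zero), 0)
  c1 <- slab_td_reflectance(test_props(0.1), slab_geometry(5), 1, g)
  c4 <- slab_td_reflectance(test_props(0.1), slab_geometry(5), 4, g)
  scaled <- c1
  scaled$value <- scaled$value * 3.7
  expect_equal(cw_intensity(scaled), 3.7 * cw_intensity(c1))
  # frozen quadrature oracle of the intensity ratio between 4 and 1 cm
  expect_equal(cw_intensity(c4) / cw_intensity(c1), 3.42423372085518e-04,
               tolerance = 1e-6)
})

test_that("binned curve integrals are stable under grid refinement", {
  coarse <- slab_td_reflectance(test_props(0.1), slab_geometry(5), 3,
                                time_grid(0, 5, 0.02))
  fine <- slab_td_reflectance(test_props(0.1), slab_geometry(5), 3,
                              time_grid(0, 5, 0.01))
  expect_lt(abs(cw_intensity(fine) / cw_intensity(coarse) - 1), 0.001)
  bil_c <- bilayer_td_reflectance(test_props(0.1), test_props(0.1),
                                  bilayer_geometry(), 2, time_grid(0, 5, 0.04))
  bil_f <- bilayer_td_reflectance(test_props(0.1), test_props(0.1),
                                  bilayer_geometry(), 2, time_grid(0, 5, 0.02))
  expect_lt(abs(cw_intensity(bil_f) / cw_intensity(bil_c) - 1), 0.001)
})

test_that("boundary coefficient reproduces the standard value for tissue-air", {
  expect_equal(boundary_coefficient_A(1.4), 2.9485, tolerance = 1e-4)
  expect_equal(boundary_coefficient_A(1), 1)
})
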