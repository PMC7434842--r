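test_that("default discretization yields 2048 Gauss points", {
  mesh <- ts_mesh()
  expect_identical(mesh$n_gauss, 2048L)
  expect_identical(nrow(mesh$conn), 256L)
  expect_identical(dim(mesh$fibers), c(2048L, 3L))
})

test_that("element volumes integrate the cross-sectional-area profile", {
  sub <- ts_subject()
  mesh <- ts_mesh()
  csa_fun <- splinefun(sub$geometry$stations, sub$geometry$csa_profile,
                       method = "natural")
  vol_true <- integrate(csa_fun, 0, 1)$value * sub$geometry$length
  expect_lt(abs(sum(mesh_element_volumes(mesh)) - vol_true) / vol_true, 0.02)
  expect_true(all(mesh_element_volumes(mesh) > 0))
})

test_that("fiber field is helical with linearly accumulating twist", {
  sub <- ts_subject()
  mesh <- ts_mesh()
  expect_equal(rowSums(mesh$fibers^2), rep(1, mesh$n_gauss), tolerance = 1e-12)
  # zero twist collapses onto the longitudinal axis
  g0 <- sub$geometry
  g0$twist_total <- 0
  m0 <- build_tendon_mesh(g0, n_axial = 4, n_section = 2)
  expect_equal(m0$fibers[, 3], rep(1, m0$n_gauss), tolerance = 1e-12)
  # off-axis inclination grows linearly with radius at fixed twist rate
  r <- sqrt(rowSums(mesh$gp_pos[, 1:2]^2))
  tangential <- sqrt(rowSums(mesh$fibers[, 1:2]^2))
  tau <- 30 * pi / 180 / mesh$length
  expect_equal(tangential, r * tau / sqrt(1 + (r * tau)^2), tolerance = 1e-9)
})

test_that("non-positive cross-sections are rejected", {
  g <- ts_subject()$geometry
  g$csa_profile[5] <- -10
  expect_error(build_tendon_mesh(g), "csa_profile")
})

test_that("fiber stress derivative is piecewise exponential-linear and continuous", {
  cf <- material_coefficients(C1 = 1, C3 = 1, C4 = 10, C5 = 100,
                              lambda_star = 1.05)
  expect_identical(fiber_stress_derivative(1, cf), 0)
  expect_identical(fiber_stress_derivative(0.98, cf), 0)
  expect_equal(fiber_stress_derivative(1.05 - 1e-12, cf), exp(0.5) - 1,
               tolerance = 1e-6)
  lo <- fiber_stress_derivative(cf$lambda_star - 1e-10, cf)
  hi <- fiber_stress_derivative(cf$lambda_star + 1e-10, cf)
  expect_lt(abs(hi - lo), 1e-7)
})

test_that("C6 enforces stress continuity at the transition stretch", {
  cf <- list(C3 = 1, C4 = 10, C5 = 100, lambda_star = 1.05)
  expect_equal(compute_C6(cf), exp(0.5) - 1 - 105, tolerance = 1e-9)
  expect_equal(compute_C6(cf), -104.35128, tolerance = 1e-5)
  cf$C3 <- 0
  expect_equal(compute_C6(cf), -105)
  expect_error(material_coefficients(C1 = 1, C3 = 1, C4 = 10, C5 = 100,
                                     lambda_star = 1.05, kappa = 50))
})

test_that("C5 is tendon stiffness over mean cross-sectional area, in GPa", {
  geom <- list(length = 50, csa_profile = rep(50, 9),
               stations = seq(0, 1, length.out = 9))
  # two loaded points on a 29 kN-per-unit-strain line
  iso <- data.frame(level = c(0.4, 0.7), torque = c(0.4, 0.7) * 100,
                    elongation = 50 * c(0.4, 0.7) * 100 / 0.05 / 29000)
  expect_equal(compute_C5(iso, geom, 0.05), 0.58, tolerance = 1e-9)
  geom2 <- geom
  geom2$csa_profile <- rep(100, 9)
  expect_equal(compute_C5(iso, geom2, 0.05), 0.29, tolerance = 1e-9)
  bad <- iso
  bad$elongation <- rev(bad$elongation)
  expect_error(compute_C5(bad, geom, 0.05), "non-increasing")
  expect_error(compute_C5(iso[1, ], geom, 0.05), "at least 2")
})

test_that("subject-derived C5 recovers the generator's modulus within 1%", {
  sub <- ts_subject()
  c5 <- compute_C5(ts_iso(), sub$geometry, sub$profile$at_moment_arm)
  expect_lt(abs(1000 * c5 - sub$truth$material$C5) / sub$truth$material$C5,
            0.01)
})

test_that("strain conversion utilities invert each other", {
  e <- c(0, 0.03, 0.1)
  expect_equal(convert_strain(convert_strain(e, "green"), "engineering"), e,
               tolerance = 1e-12)
  expect_equal(convert_strain(0.05, "green"), 0.5 * (1.05^2 - 1))
})

test_that("VTK export writes a well-formed unstructured grid", {
  mesh <- build_tendon_mesh(ts_subject()$geometry, n_axial = 2, n_section = 1)
  path <- tempfile(fileext = ".vtk")
  write_vtk(mesh, path, strains = rep(0.05, mesh$n_gauss))
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl(sprintf("POINTS %d double", nrow(mesh$nodes)), lines)))
  expect_true(any(grepl(sprintf("CELLS %d", nrow(mesh$conn)), lines)))
  expect_true(any(grepl("SCALARS fiber_strain", lines)))
})
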