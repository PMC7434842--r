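test_that("zero force gives the undeformed state", {
  mesh <- ts_small_mesh()
  sol <- solve_fe(mesh, ts_subject()$truth$material, 0)
  expect_identical(max(abs(sol$u)), 0)
  expect_lt(max(abs(sol$strains)), 1e-12)
  expect_equal(sol$elongation, 0)
})

test_that("distal reaction balances the applied proximal force", {
  sol <- ts_small_solution()
  expect_equal(sol$reaction[3], -1200, tolerance = 1e-6 * 1200)
  expect_lt(max(abs(sol$reaction[1:2])), 1e-5 * 1200)
})

test_that("converged solutions stay nearly incompressible", {
  sol <- ts_small_solution()
  expect_gte(sol$Jbar_range[1], 0.95)
  expect_lte(sol$Jbar_range[2], 1.05)
  tab <- ts_table()
  expect_gte(min(tab$Jbar_range), 0.95)
  expect_lte(max(tab$Jbar_range), 1.05)
})

test_that("uniform-cylinder solves match the 1D incompressible oracle within 1%", {
  mesh <- build_tendon_mesh(cylinder_geometry())
  cf <- ts_subject()$truth$material
  mvicF <- ts_mvic_force()
  u <- NULL
  for (frac in seq(0.25, 2, by = 0.25)) {
    f <- frac * mvicF
    sol <- solve_fe(mesh, cf, f, u0 = u)
    u <- sol$u
    oracle <- oracle_uniaxial_elongation(cf, 60, 60, f)
    expect_lt(abs(sol$elongation - oracle) / oracle, 0.01,
              label = sprintf("relative elongation error at %.0f%% MVIC",
                              100 * frac))
  }
})

test_that("localized strains are objective and fiber-aligned", {
  sub <- ts_subject()
  mesh <- build_tendon_mesh(sub$geometry, n_axial = 2, n_section = 1)
  sol <- solve_fe(mesh, sub$truth$material, 400)
  strains <- extract_localized_strains(sol)
  # rigid rotation of the deformed configuration leaves strains unchanged
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  def <- (mesh$nodes + sol$u) %*% t(R)
  u_rot <- as.numeric(t(def - mesh$nodes))
  dg <- tendonstrain:::fe_defgrad(mesh$conn, u_rot, mesh$dNdX, mesh$a0,
                                  mesh$wdet)
  expect_equal(dg$lambda - 1, strains, tolerance = 1e-10)
})

test_that("homogeneous stretch maps to fiber strains as the geometry dictates", {
  sub <- ts_subject()
  g0 <- cylinder_geometry(twist = 0)
  m0 <- build_tendon_mesh(g0, n_axial = 4, n_section = 2)
  lam <- 1.05
  u_aff <- cbind(0 * m0$nodes[, 1], 0 * m0$nodes[, 2],
                 (lam - 1) * m0$nodes[, 3])
  dg <- tendonstrain:::fe_defgrad(m0$conn, as.numeric(t(u_aff)), m0$dNdX,
                                  m0$a0, m0$wdet)
  expect_equal(dg$lambda - 1, rep(lam - 1, m0$n_gauss), tolerance = 1e-12)
  # identity deformation: all strains zero
  dg0 <- tendonstrain:::fe_defgrad(m0$conn, numeric(3 * nrow(m0$nodes)),
                                   m0$dNdX, m0$a0, m0$wdet)
  expect_identical(max(abs(dg0$lambda - 1)), 0)
  # with twisted fibers the same axial stretch strains fibers less
  g30 <- cylinder_geometry(twist = 30)
  m30 <- build_tendon_mesh(g30, n_axial = 4, n_section = 2)
  dg30 <- tendonstrain:::fe_defgrad(m30$conn, as.numeric(t(u_aff)), m30$dNdX,
                                    m30$a0, m30$wdet)
  expect_true(all(dg30$lambda - 1 < lam - 1 + 1e-12))
  expect_true(any(dg30$lambda - 1 < lam - 1 - 1e-6))
})

test_that("inverse material calibration reproduces the measured elongation", {
  cal <- ts_material_cal()
  expect_lt(abs(cal$achieved_elongation - cal$target) / cal$target, 5e-3)
  expect_true(cal$converged)
  # C6 refreshed from continuity at the returned coefficients
  expect_equal(cal$coefficients$C6, compute_C6(cal$coefficients),
               tolerance = 1e-12)
})

test_that("calibration starting at the generating coefficients is a fixed point", {
  sub <- ts_subject()
  mesh <- ts_small_mesh()
  truthcf <- sub$truth$material
  target <- solve_fe(mesh, truthcf, 1500)$elongation
  cal <- calibrate_material(mesh, truthcf, target, 1500, maxit = 12L)
  expect_lt(cal$objective, (1e-4 * target)^2)
  expect_lt(abs(cal$achieved_elongation - target) / target, 1e-3)
})

test_that("the training table has the stated shape and ordering properties", {
  tab <- ts_table()
  expect_identical(length(tab$force), 21L)
  expect_identical(ncol(tab$strains), 2048L)
  expect_identical(tab$fraction, seq(0, 2, by = 0.1))
  expect_true(all(diff(tab$force) > 0))
  expect_identical(max(abs(tab$strains[1, ])), 0)
  expect_equal(tab$elongation[1], 0)
  # each Gauss point's strain is non-decreasing across force levels
  expect_true(all(apply(tab$strains, 2, function(col) all(diff(col) >= -1e-10))))
})

test_that("halving the element size changes the peak strain by less than 5%", {
  sub <- ts_subject()
  cf <- sub$truth$material
  mvicF <- ts_mvic_force()
  coarse <- solve_fe(ts_mesh(), cf, mvicF)
  fine_mesh <- build_tendon_mesh(sub$geometry, n_axial = 32L, n_section = 8L)
  fine <- solve_fe(fine_mesh, cf, mvicF)
  expect_lt(abs(max(fine$strains) - max(coarse$strains)) / max(coarse$strains),
            0.05)
  expect_lt(abs(fine$elongation - coarse$elongation) / coarse$elongation,
            0.05)
})
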