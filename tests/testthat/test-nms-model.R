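test_that("EMG processing is causal and clipped to [0, 1]", {
  fs <- 1500
  set.seed(4)
  x <- rnorm(3000, 0, 0.4)
  env <- process_emg(x, fs)
  expect_true(all(env >= 0 & env <= 1))
  expect_identical(process_emg(numeric(500), fs), numeric(500))
  # causality: changing the signal after sample T leaves earlier output alone
  x2 <- x
  x2[2001:3000] <- x2[2001:3000] + 5
  expect_identical(process_emg(x2, fs)[1:2000], env[1:2000])
  expect_error(process_emg(x, fs, time = c(0, 1e-3, 3e-3, 4e-3)),
               "non-uniform")
})

test_that("sine-wave envelope settles at the rectified-mean filter response", {
  fs <- 1500
  spec <- emg_filter_spec(mvic = 1)
  t <- seq(0, 4, by = 1 / fs)
  A <- 0.6
  x <- A * sin(2 * pi * 100 * t)
  env <- process_emg(x, fs, spec)
  # oracle: band-pass gain at 100 Hz from the filter polynomials, then the
  # mean of the rectified sine (2/pi of its amplitude) through a unit-DC
  # low-pass
  bp <- signal::butter(spec$band_order, spec$band / (fs / 2), type = "pass")
  z <- exp(1i * 2 * pi * 100 / fs)
  gain <- abs(sum(bp$b * z^-(seq_along(bp$b) - 1)) /
                sum(bp$a * z^-(seq_along(bp$a) - 1)))
  expected <- 2 * gain * A / pi
  expect_equal(mean(env[t > 3]), expected, tolerance = 0.02)
})

test_that("activation dynamics has unit DC gain and exponential shaping", {
  fs <- 250
  act <- activation_params(A = -2, tau_act = 0.012, tau_deact = 0.024,
                           emd = 0.01)
  n <- 1000
  expect_identical(activation_dynamics(numeric(n), fs, act), numeric(n))
  a1 <- activation_dynamics(rep(1, n), fs, act)
  expect_equal(a1[n], 1, tolerance = 1e-6)
  a05 <- activation_dynamics(rep(0.5, n), fs, act)
  expect_equal(a05[n], (exp(-1) - 1) / (exp(-2) - 1), tolerance = 1e-6)
  expect_equal(a05[n], 0.7311, tolerance = 1e-4)
  expect_true(all(a05 >= 0 & a05 <= 1))
  expect_error(activation_params(tau_act = -0.01))
  expect_error(activation_dynamics(rep(0.5, 10), fs,
                                   structure(list(A = -2, tau_act = Inf,
                                                  tau_deact = 0.02, emd = 0),
                                             class = "activation_params")))
})

test_that("maximum isometric force follows specific tension on PCSA", {
  expect_equal(compute_fmax_from_volume(300, 6), 2750)
  expect_equal(compute_fmax_from_volume(250, 5), 2750)
  expect_equal(compute_fmax_from_volume(600, 6), 5500)   # linear in volume
  expect_error(compute_fmax_from_volume(300, 0))
})

test_that("MTU B-spline surrogate interpolates and differentiates correctly", {
  grid <- list(knee = c(-10, 10, 30, 50, 70),
               ankle = c(-30, -15, 0, 15, 30, 45),
               sub = c(-20, 0, 20, 25))
  full <- expand.grid(k = grid$knee, a = grid$ankle, s = grid$sub)
  rad <- full * pi / 180
  L <- 0.44 - 0.012 * rad$k - 0.05 * rad$a + 0.008 * rad$a^2 - 0.004 * rad$s
  srg <- fit_mtu_spline(grid, list(mg = array(L, c(5, 6, 4))))
  # exact at the grid nodes
  nodes <- as.matrix(full[c(1, 37, 119), ])
  for (i in 1:3) {
    got <- predict(srg, nodes[i, ], "mg", "length")
    expect_equal(as.numeric(got), L[c(1, 37, 119)][i], tolerance = 1e-12)
  }
  # moment arm equals a central finite difference of length
  q <- matrix(c(22, 7, -3), 1)
  h <- 1e-4  # radians
  qp <- q; qp[2] <- qp[2] + h * 180 / pi
  qm <- q; qm[2] <- qm[2] - h * 180 / pi
  fd <- -(predict(srg, qp, "mg") - predict(srg, qm, "mg")) / (2 * h)
  expect_equal(as.numeric(predict(srg, q, "mg", "moment_arm")),
               as.numeric(fd), tolerance = 1e-6)
  # length linear in the knee angle implies a constant knee moment arm
  ma_k <- sapply(c(-5, 20, 60), function(k)
    predict(srg, matrix(c(k, 5, 5), 1), "mg", "moment_arm", dof = 1L))
  expect_equal(as.numeric(ma_k), rep(0.012, 3), tolerance = 1e-9)
  expect_error(predict(srg, matrix(c(200, 0, 0), 1), "mg"), "outside")
})

test_that("Achilles moment arm calibration is exact and bounded", {
  srg <- build_mtu_surrogate(ts_subject())
  neutral <- matrix(0, 1, 3)
  cur <- as.numeric(predict(srg, neutral, "sol", "moment_arm"))
  same <- calibrate_moment_arm(srg, cur)
  expect_equal(attr(same, "moment_arm_report")$offset, 0, tolerance = 1e-12)
  adj <- calibrate_moment_arm(srg, 0.055)
  for (m in c("mg", "lg", "sol")) {
    expect_equal(as.numeric(predict(adj, neutral, m, "moment_arm")), 0.055,
                 tolerance = 1e-4)
  }
  expect_error(calibrate_moment_arm(srg, 10),
               class = "tendonstrain_unreachable")
})

test_that("fiber-tendon equilibrium solves satisfy the balance equation", {
  sub <- ts_subject()
  p <- sub$truth$muscles$mg
  crv <- sub$truth$curve
  phi0 <- p$phi0 * pi / 180
  # zero activation with the tendon exactly at slack: zero force
  r0 <- solve_muscle_force(0, p$lts + 0.96 * p$lopt * cos(phi0), p, crv)
  expect_identical(r0$force, 0)
  # fully active isometric state engineered so the fiber sits at optimal
  # length: transmitted force is fmax cos(pennation)
  epsstar <- strain_at_force(crv, cos(phi0))
  lmtu <- p$lts * (1 + epsstar) + p$lopt * cos(phi0)
  r1 <- solve_muscle_force(1, lmtu, p, crv)
  expect_equal(r1$force, p$fmax * cos(phi0), tolerance = 1e-6 * p$fmax)
  expect_equal(r1$fiber_length, p$lopt, tolerance = 1e-8)
  expect_equal(r1$tendon_strain, epsstar, tolerance = 1e-9)
  expect_false(r1$clamped)
  # force is non-decreasing in activation at fixed kinematics
  f <- vapply(seq(0, 1, 0.1), function(a)
    solve_muscle_force(a, lmtu, p, crv)$force, numeric(1))
  expect_true(all(diff(f) >= -1e-9))
})
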