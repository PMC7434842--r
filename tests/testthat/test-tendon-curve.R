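test_that("fit recovers a known curve from exact samples", {
  crv <- tendon_curve(a = 200, eps0 = 0.04)
  s <- c(0.005, 0.012, 0.02, 0.03, 0.045, 0.06, 0.08, 0.095)
  fit <- fit_tendon_curve(data.frame(strain = s, force = predict(crv, s)))
  expect_lt(abs(fit$a - 200), 1e-6 * 200)
  expect_lt(abs(fit$eps0 - 0.04), 1e-6)
  expect_equal(fit$m, 16, tolerance = 1e-6)
  expect_equal(fit$q, -0.32, tolerance = 1e-6)
})

test_that("C1 continuity constraints hold exactly for fitted curves", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- runif(1, 20, 400)
    e0 <- runif(1, 0.01, 0.08)
    crv0 <- tendon_curve(a, e0)
    s <- sort(runif(8, 0.2 * e0, 3 * e0))
    fit <- fit_tendon_curve(data.frame(strain = s, force = predict(crv0, s)))
    expect_identical(fit$m, 2 * fit$a * fit$eps0)
    expect_identical(fit$q, -fit$a * fit$eps0^2)
    expect_lt(abs(fit$a - a) / a, 1e-5)
  }
})

test_that("evaluation follows the piecewise quadratic-linear form", {
  crv <- tendon_curve(150, 0.05)
  expect_identical(predict(crv, -0.01), 0)
  expect_identical(predict(crv, 0), 0)
  # both branches agree at the transition
  expect_equal(crv$a * crv$eps0^2, crv$m * crv$eps0 + crv$q, tolerance = 1e-12)
  # derivative from both sides equals 2 a eps0
  h <- 1e-7
  d_lo <- (predict(crv, crv$eps0) - predict(crv, crv$eps0 - h)) / h
  d_hi <- (predict(crv, crv$eps0 + h) - predict(crv, crv$eps0)) / h
  expect_equal(d_lo, 2 * crv$a * crv$eps0, tolerance = 1e-5)
  expect_equal(d_hi, 2 * crv$a * crv$eps0, tolerance = 1e-5)
  # monotone non-decreasing for a sample of valid curves
  for (seed in 1:5) {
    set.seed(seed)
    c2 <- tendon_curve(runif(1, 10, 500), runif(1, 0.01, 0.1))
    f <- predict(c2, seq(-0.02, 0.2, length.out = 400))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("analytic inverse matches forward evaluation", {
  crv <- tendon_curve(120, 0.045)
  f <- c(0, 0.05, crv$a * crv$eps0^2, 0.4, 1.2)
  expect_equal(predict(crv, strain_at_force(crv, f)), f, tolerance = 1e-12)
})

test_that("degenerate inputs signal fit failure", {
  expect_error(fit_tendon_curve(data.frame(strain = rep(0.03, 5),
                                           force = rep(0.2, 5))),
               class = "tendonstrain_fit_error")
  expect_error(fit_tendon_curve(data.frame(strain = c(0.01, 0.02, 0.03),
                                           force = c(0.3, 0.2, 0.1))),
               class = "tendonstrain_fit_error")
  expect_error(fit_tendon_curve(data.frame(strain = c(0.01, 0.02, 0.03),
                                           force = c(0, 0, 0))),
               class = "tendonstrain_fit_error")
})

test_that("noisy fit attains the brute-force grid optimum", {
  crv0 <- tendon_curve(180, 0.05)
  set.seed(11)
  s <- seq(0.01, 0.1, length.out = 12)
  y <- predict(crv0, s) + rnorm(12, 0, 0.01)
  pts <- data.frame(strain = s, force = y)
  fit <- fit_tendon_curve(pts)
  # independent oracle: dense grid over (a, eps0)
  rss <- function(a, e0) {
    p <- ifelse(s < e0, s^2, 2 * e0 * s - e0^2)
    sum((y - a * p)^2)
  }
  grid <- expand.grid(a = seq(100, 300, length.out = 160),
                      e0 = seq(0.02, 0.09, length.out = 160))
  best <- min(mapply(rss, grid$a, grid$e0))
  expect_lte(fit$rss, best + 1e-10)
  expect_equal(fit$rss, sum(residuals(fit)^2), tolerance = 1e-12)
})

test_that("fit is idempotent on its own samples", {
  crv0 <- tendon_curve(95, 0.06)
  s <- seq(0.01, 0.12, length.out = 9)
  fit1 <- fit_tendon_curve(data.frame(strain = s, force = predict(crv0, s)))
  fit2 <- fit_tendon_curve(data.frame(strain = s, force = predict(fit1, s)))
  expect_equal(fit2$a, fit1$a, tolerance = 1e-9)
  expect_equal(fit2$eps0, fit1$eps0, tolerance = 1e-9)
})

test_that("isometric measurements normalize by moment arm, length and force", {
  profile <- list(at_moment_arm = 0.05, tendon_resting_length = 50)
  m <- data.frame(level = c(0, 0.5), torque = c(0, 70),
                  elongation = c(0, 2.5))
  pts <- normalize_measurements(m, profile, fmax_total = 7000)
  expect_equal(pts$force[2], 1400 / 7000)   # 70 N m over 0.05 m is 1400 N
  expect_equal(pts$strain[2], 0.05)
  expect_equal(unlist(pts[1, ]), c(strain = 0, force = 0))
  profile$at_moment_arm <- 0
  expect_error(normalize_measurements(m, profile, 7000), "moment arm")
})
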