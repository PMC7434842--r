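# small synthetic table with strains exactly linear in force
linear_table <- function(n_lev = 21L, n_gp = 40L) {
  force <- seq(0, 4000, length.out = n_lev)
  slopes <- seq(1e-5, 5e-5, length.out = n_gp)
  structure(list(force = force, fraction = force / 2000,
                 strains = outer(force, slopes),
                 elongation = force * 1.5e-3, mvic_force = 2000,
                 n_gauss = n_gp),
            class = "strain_table")
}

test_that("spline surrogates reproduce every training row exactly", {
  tab <- ts_table()
  for (method in c("cubic_spline", "basis_spline")) {
    srg <- fit_surrogate(tab, method)
    pred <- predict(srg, tab$force)
    expect_equal(pred$strains, tab$strains, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(pred$elongation, tab$elongation, tolerance = 1e-9)
  }
})

test_that("a perfectly linear table is learned exactly by all methods", {
  tab <- linear_table()
  loo <- loo_validate(tab)
  expect_lt(loo$rmse[["cubic_spline"]], 1e-12)
  expect_lt(loo$rmse[["basis_spline"]], 1e-12)
  expect_lt(loo$rmse[["pls"]], 1e-8)
  expect_true(all(loo$r > 1 - 1e-9))
})

test_that("surrogate predictions respect range and monotonicity", {
  srg <- ts_surrogate()
  tab <- ts_table()
  expect_identical(max(abs(predict(srg, 0)$strains)), 0)
  expect_error(predict(srg, -5), "negative")
  over <- predict(srg, max(tab$force) * 1.2)
  expect_true(over$clamped)
  expect_equal(as.numeric(over$strains), tab$strains[21, ], tolerance = 1e-9)
  # dense sweep: non-decreasing in force at every Gauss point
  sweep <- predict(srg, seq(0, max(tab$force), length.out = 250))$strains
  expect_true(all(apply(sweep, 2, function(col) all(diff(col) >= -1e-9))))
})

test_that("cubic interpolation midway between levels matches a direct FE solve", {
  tab <- ts_table()
  srg <- ts_surrogate()
  f_mid <- mean(tab$force[15:16])
  pred <- as.numeric(predict(srg, f_mid)$strains)
  sol <- solve_fe(ts_mesh(), ts_material_cal()$coefficients, f_mid,
                  u0 = tab$u_top)
  expect_lt(max(abs(pred - sol$strains)), 1e-3)
})

test_that("leave-one-out validation reports are deterministic and complete", {
  tab <- ts_table()
  loo <- ts_loo()
  expect_named(loo$rmse, c("pls", "cubic_spline", "basis_spline"))
  expect_true(all(loo$r >= -1 & loo$r <= 1))
  expect_true(all(loo$rmse >= 0))
  expect_identical(loo$selected, names(loo$rmse)[which.min(loo$rmse)])
  expect_identical(loo$n_pooled, 19L * 2048L)
  loo2 <- loo_validate(tab)
  expect_identical(loo$rmse, loo2$rmse)
  expect_identical(loo$r, loo2$r)
  expect_error(loo_validate(tab, character(0)), "empty")
})

test_that("surrogate serialization round-trips through JSON", {
  tab <- ts_table()
  srg <- ts_surrogate()
  path <- tempfile(fileext = ".json")
  write_surrogate(srg, tab, path)
  srg2 <- read_surrogate(path)
  f <- c(0, 500, 1234.5, max(tab$force))
  expect_equal(predict(srg2, f)$strains, predict(srg, f)$strains,
               tolerance = 1e-9)
})

test_that("degenerate tables are rejected", {
  tab <- linear_table(n_lev = 3L)
  expect_error(fit_surrogate(tab), "at least 4")
  tab2 <- linear_table()
  tab2$force[5] <- tab2$force[4]
  expect_error(fit_surrogate(tab2), "non-increasing|duplicate")
  expect_error(loo_validate(linear_table(n_lev = 4L)), "at least 5")
})
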