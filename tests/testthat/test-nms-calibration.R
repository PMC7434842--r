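test_that("forward model reconstructs reference moments with true parameters", {
  tr <- ts_walk_trial()
  fw <- nms_forward(ts_truth_model(), tr)
  expect_lt(sqrt(mean((fw$moments - tr$reference_moment)^2)), 0.1)
  expect_true(all(fw$force >= 0))
  expect_true(all(fw$activation >= 0 & fw$activation <= 1))
  # open-loop determinism
  fw2 <- nms_forward(ts_truth_model(), tr)
  expect_identical(fw$moments, fw2$moments)
})

test_that("calibration from the true parameters is a fixed point", {
  tm <- ts_truth_model()
  tr <- make_trial("walking", ts_subject(), duration = 1.2, truth_model = tm)
  cal <- calibrate_nms(tm, list(tr), maxit = 60L, restarts = 0L)
  rep <- attr(cal, "calibration")
  expect_lt(rep$objective_initial, 1e-10)
  expect_lte(rep$objective_final, rep$objective_initial + 1e-12)
  for (m in names(tm$muscles)) {
    expect_equal(cal$muscles[[m]]$lts, tm$muscles[[m]]$lts,
                 tolerance = 5e-3)
  }
})

test_that("calibration recovers perturbed tendon slack lengths within 2%", {
  rec <- ts_nms_recovery()
  expect_lt(rec$report$objective_final, rec$report$objective_initial)
  for (m in names(rec$truth$muscles)) {
    tru <- rec$truth$muscles[[m]]$lts
    est <- rec$calibrated$muscles[[m]]$lts
    expect_lt(abs(est - tru) / tru, 0.02)
  }
})

test_that("clamped-equilibrium frames are flagged, not silently accepted", {
  sub <- ts_subject()
  p <- sub$truth$muscles$mg
  # an MTU too short for the fiber bracket (active muscle, slack tendon)
  r <- solve_muscle_force(0.8, p$lts + 0.25 * p$lopt, p, sub$truth$curve)
  expect_true(r$clamped)
})
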