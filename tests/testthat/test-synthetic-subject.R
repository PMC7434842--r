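test_that("subject generation is seed-deterministic and seed-sensitive", {
  s0a <- make_subject(0)
  s0b <- make_subject(0)
  s1 <- make_subject(1)
  expect_identical(s0a, s0b)
  expect_false(s0a$profile$mvic_torque == s1$profile$mvic_torque)
})

test_that("generated subjects respect the anatomical invariants", {
  for (seed in 0:7) {
    sub <- make_subject(seed)
    p <- sub$profile
    expect_true(all(unlist(p[c("mass", "height", "mvic_torque",
                               "at_moment_arm", "tendon_resting_length")]) > 0))
    expect_gte(p$at_moment_arm, 0.03)
    expect_lte(p$at_moment_arm, 0.07)
    expect_gte(p$tendon_resting_length, 30)
    expect_lte(p$tendon_resting_length, 80)
    g <- sub$geometry
    expect_true(all(g$csa_profile > 0))
    expect_equal(g$twist_total, 30)
    # CSA minimum in the middle third of the length
    sfine <- seq(0, 1, length.out = 301)
    csa_fun <- splinefun(g$stations, g$csa_profile, method = "natural")
    smin <- sfine[which.min(csa_fun(sfine))]
    expect_gt(smin, 1 / 3)
    expect_lt(smin, 2 / 3)
  }
})

test_that("isometric series inverts the true curve exactly", {
  sub <- ts_subject()
  iso <- ts_iso()
  expect_equal(iso$elongation[iso$level == 0], 0)
  expect_equal(iso$torque, iso$level * sub$profile$mvic_torque)
  expect_error(make_isometric_series(sub, levels = c(0, 1.2)), "rejected")
  # elongation strictly increasing with level
  expect_true(all(diff(iso$elongation) > 0))
  # round trip: normalized points refit the ground-truth curve
  fit <- ts_curve()
  expect_lt(abs(fit$a - sub$truth$curve$a) / sub$truth$curve$a, 1e-6)
  expect_lt(abs(fit$eps0 - sub$truth$curve$eps0), 1e-6)
})

test_that("trial templates produce task-appropriate, bounded signals", {
  sub <- ts_subject()
  tm <- ts_truth_model()
  for (task in c("walking", "single_leg_hop", "eccentric_heel_drop", "mvic")) {
    for (seed in c(0, 3)) {
      tr <- make_trial(task, sub, seed = seed, duration = 1.8,
                       truth_model = tm)
      expect_true(all(tr$emg >= 0 & tr$emg <= 1))
      expect_true(all(abs(tr$angles) <= 60))
      expect_equal(diff(range(diff(tr$time))), 0, tolerance = 1e-12)
    }
  }
  expect_error(make_trial("sprinting", sub), "unknown task")
})

test_that("walking gastrocnemius activity peaks in the second half of stance", {
  tr <- ts_walk_trial()
  phase <- (tr$emg_time %% 1.2) / 1.2   # gait cycle fraction; stance 0-0.6
  for (ch in c("mg", "lg", "sol")) {
    pk <- phase[which.max(tr$emg[, ch])]
    expect_gt(pk, 0.3)
    expect_lt(pk, 0.6)
  }
})

test_that("zero-EMG trials carry passive-only reference moments", {
  tr0 <- make_trial("walking", ts_subject(), duration = 2.4, emg_scale = 0,
                    truth_model = ts_truth_model())
  expect_true(all(tr0$emg == 0))
  expect_lt(max(abs(tr0$reference_moment[, "ankle_pf"])), 5)
})

test_that("reference moments come from the ground-truth forward model", {
  tr <- ts_walk_trial()
  fw <- nms_forward(ts_truth_model(), tr)
  expect_lt(sqrt(mean((fw$moments - tr$reference_moment)^2)), 0.1)
})
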