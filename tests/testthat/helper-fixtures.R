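# Shared fixtures, built lazily once per test run and cached.  Everything is
# generated in code from the seeded synthetic subject; the heavier FE and
# calibration artifacts are reused across test files.

the <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(the[[name]])) the[[name]] <- force(expr)
  the[[name]]
}

ts_subject <- function() memo("subject", make_subject(0))

ts_truth_model <- function() memo("truth_model", truth_nms_model(ts_subject()))

ts_iso <- function() memo("iso", make_isometric_series(ts_subject()))

ts_curve <- function() memo("curve", {
  sub <- ts_subject()
  fit_tendon_curve(normalize_measurements(ts_iso(), sub$profile,
                                          sub$truth$fmax_total))
})

ts_mesh <- function() memo("mesh", build_tendon_mesh(ts_subject()$geometry))

# small mesh + moderate force for cheap solver unit tests
ts_small_mesh <- function() memo("small_mesh",
  build_tendon_mesh(ts_subject()$geometry, n_axial = 6L, n_section = 2L))

ts_small_solution <- function() memo("small_solution",
  solve_fe(ts_small_mesh(), ts_subject()$truth$material, 1200))

ts_mvic_force <- function() {
  sub <- ts_subject()
  sub$profile$mvic_torque / sub$profile$at_moment_arm
}

# inverse FE calibration from a generic starting coefficient set, as in the
# measurement workflow: C5 from the isometric series, target elongation at
# the highest measured level
ts_material_cal <- function() memo("material_cal", {
  sub <- ts_subject()
  iso <- ts_iso()
  C5 <- compute_C5(iso, sub$geometry, sub$profile$at_moment_arm)
  init <- material_coefficients(C1 = 1.5, C3 = 2.5, C4 = 30,
                                C5 = 1000 * C5,
                                lambda_star = 1 + ts_curve()$eps0)
  k <- which.max(iso$level)
  calibrate_material(ts_mesh(), init, iso$elongation[k],
                     iso$torque[k] / sub$profile$at_moment_arm)
})

ts_table <- function() memo("table",
  generate_training_table(ts_mesh(), ts_material_cal()$coefficients,
                          ts_mvic_force()))

ts_loo <- function() memo("loo", loo_validate(ts_table()))

ts_surrogate <- function() memo("surrogate",
  fit_surrogate(ts_table(), "cubic_spline"))

ts_walk_trial <- function() memo("walk_trial",
  make_trial("walking", ts_subject(), duration = 4,
             truth_model = ts_truth_model()))

ts_pipeline <- function() memo("pipeline",
  build_pipeline(ts_truth_model(), ts_surrogate(),
                 ts_subject()$profile$tendon_resting_length))

ts_walk_stream <- function() memo("walk_stream",
  process_trial(ts_pipeline(), ts_walk_trial()))

# NMS calibration recovery: slack lengths perturbed by up to 5%, one trial
# per dynamic task, everything else at the true values
ts_nms_recovery <- function() memo("nms_recovery", {
  sub <- ts_subject()
  tm <- ts_truth_model()
  trials <- list(make_trial("walking", sub, duration = 2.4,
                            truth_model = tm),
                 make_trial("single_leg_hop", sub, duration = 1.8,
                            truth_model = tm),
                 make_trial("eccentric_heel_drop", sub, duration = 3,
                            truth_model = tm))
  pert <- tm
  fac <- c(mg = 0.96, lg = 1.04, sol = 1.05, ta = 0.95)
  for (m in names(pert$muscles))
    pert$muscles[[m]]$lts <- pert$muscles[[m]]$lts * fac[[m]]
  cal <- calibrate_nms(pert, trials)
  list(truth = tm, perturbed = pert, calibrated = cal,
       report = attr(cal, "calibration"))
})

# uniform-cylinder geometry for oracle-equivalence tests
cylinder_geometry <- function(length = 60, csa = 60, twist = 0) {
  list(length = length, stations = seq(0, 1, length.out = 9L),
       csa_profile = rep(csa, 9L), twist_total = twist,
       ellipse_aspect = rep(1, 9L))
}

# independent 1D incompressible uniaxial oracle (bisection on the axial
# Cauchy stress), with its own piecewise fiber law
oracle_uniaxial_elongation <- function(coeffs, area, length, force) {
  if (force == 0) return(0)
  Tfib <- function(lam) {
    ifelse(lam <= 1, 0,
           ifelse(lam < coeffs$lambda_star,
                  coeffs$C3 * (exp(coeffs$C4 * (lam - 1)) - 1),
                  coeffs$C5 * lam + coeffs$C6))
  }
  g <- function(lam)
    (2 * coeffs$C1 * (lam^2 - 1 / lam) + Tfib(lam)) * area / lam - force
  lam <- uniroot(g, c(1 + 1e-12, 3), tol = 1e-13)$root
  (lam - 1) * length
}
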