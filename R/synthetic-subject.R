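# Seeded synthetic-subject generator: subject profile, free-tendon geometry,
# ground-truth model parameters, isometric force-elongation series and
# dynamic trials.  Every stochastic draw is scoped to the given seed, so a
# subject is bit-identical across calls, and ground truth is stored alongside
# the data so calibration stages can be tested by parameter recovery.

# Canonical defaults: anthropometrics of a young healthy adult, triceps-surae
# muscle architecture in the range of cadaveric/imaging literature, Achilles
# linear-region modulus centred on 0.58 GPa.
SUBJECT_DEFAULTS <- list(
  mass = 72, height = 1.74, mvic_torque = 140, at_moment_arm = 0.053,
  tendon_resting_length = 52, csa_min = 55, aspect = 1.7,
  c5_target = 580,                      # MPa, linear-region fiber modulus
  volumes = c(mg = 260, lg = 140, sol = 460),  # cm^3
  lopt = c(mg = 0.060, lg = 0.064, sol = 0.050, ta = 0.068),
  lts = c(mg = 0.400, lg = 0.385, sol = 0.260, ta = 0.223),
  phi0 = c(mg = 17, lg = 8, sol = 25, ta = 5),
  fmax_ta = 900,
  # MTU path coefficients: length(theta) = L0 - r_knee th_k - r_ankle th_a
  #   + c_ankle th_a^2 - r_sub th_s   (radians; plantarflexion positive)
  r_knee = c(mg = 0.012, lg = 0.010, sol = 0, ta = 0),
  c_ankle = c(mg = 0.008, lg = 0.008, sol = 0.008, ta = -0.004),
  r_sub = c(mg = 0.004, lg = -0.004, sol = 0.003, ta = -0.010),
  ta_moment_arm = -0.040,
  material = c(C1 = 1.5, C3 = 2.9, C4 = 35)    # MPa, MPa, -
)

MUSCLES <- c("mg", "lg", "sol", "ta")

#' Generate a synthetic subject with ground-truth model parameters
#'
#' Draws a subject profile (anthropometrics, MVIC torque, Achilles moment
#' arm, tendon resting length, muscle volumes), a free-tendon geometry with a
#' mid-portion cross-sectional-area minimum and 30 degrees of fiber twist,
#' and the full set of ground-truth parameters (Hill-type muscle parameters,
#' MTU path coefficients, dimensionless tendon curve, constitutive
#' coefficients).  The tendon curve's linear slope is chosen so the implied
#' linear-region modulus (stiffness over mean cross-sectional area) sits near
#' 0.58 GPa.  Identical seeds give bit-identical subjects.
#'
#' @param seed non-negative integer seed.
#' @return Object of class `at_subject`: list with `profile`, `geometry`,
#'   `truth` (muscles, path, curve, material, act, fmax_total) and `seed`.
#' @export
make_subject <- function(seed = 0L) {
  with_seed(seed, {
    d <- SUBJECT_DEFAULTS
    profile <- list(
      mass = stats::rnorm(1, d$mass, 7),
      height = stats::rnorm(1, d$height, 0.06),
      mvic_torque = stats::rnorm(1, d$mvic_torque, 12),
      at_moment_arm = min(max(stats::rnorm(1, d$at_moment_arm, 0.003), 0.045), 0.065),
      tendon_resting_length = min(max(stats::rnorm(1, d$tendon_resting_length, 5), 38), 70),
      muscle_volumes = d$volumes * stats::runif(3, 0.9, 1.1),
      emg_max = stats::setNames(rep(1, 4), MUSCLES))
    stopifnot(profile$mass > 0, profile$mvic_torque > 0)

    smin <- stats::runif(1, 0.42, 0.58)
    stations <- seq(0, 1, length.out = 9L)
    csa_min <- stats::rnorm(1, d$csa_min, 4)
    csa_dist <- csa_min * stats::runif(1, 1.2, 1.35)
    csa_prox <- csa_min * stats::runif(1, 1.25, 1.45)
    csa <- ifelse(stations < smin,
                  csa_min + (csa_dist - csa_min) * ((smin - stations) / smin)^2,
                  csa_min + (csa_prox - csa_min) * ((stations - smin) / (1 - smin))^2)
    geometry <- list(length = profile$tendon_resting_length,
                     stations = stations, csa_profile = csa,
                     twist_total = 30,
                     ellipse_aspect = rep(stats::rnorm(1, d$aspect, 0.08), 9L))

    vols <- profile$muscle_volumes
    fmax <- c(compute_fmax_from_volume(vols, 100 * d$lopt[c("mg", "lg", "sol")]),
              ta = d$fmax_ta)
    muscles <- lapply(MUSCLES, function(m)
      muscle_params(fmax = fmax[[m]],
                    lopt = d$lopt[[m]] * stats::runif(1, 0.97, 1.03),
                    lts = d$lts[[m]] * stats::runif(1, 0.97, 1.03),
                    phi0 = d$phi0[[m]]))
    names(muscles) <- MUSCLES
    fmax_total <- sum(fmax[c("mg", "lg", "sol")])

    # dimensionless curve: slope chosen so C5 = m * Fmax / mean CSA ~ target
    eps0 <- stats::rnorm(1, 0.05, 0.003)
    mean_csa <- mean(csa)
    m_slope <- d$c5_target * stats::runif(1, 0.95, 1.05) * mean_csa / fmax_total
    curve <- tendon_curve(a = m_slope / (2 * eps0), eps0 = eps0)

    r_ankle <- c(mg = profile$at_moment_arm, lg = profile$at_moment_arm,
                 sol = profile$at_moment_arm, ta = d$ta_moment_arm)
    path <- lapply(MUSCLES, function(m) {
      p <- muscles[[m]]
      list(L0 = p$lts + 0.96 * p$lopt * cos(p$phi0 * pi / 180),
           r_knee = d$r_knee[[m]], r_ankle = r_ankle[[m]],
           c_ankle = d$c_ankle[[m]], r_sub = d$r_sub[[m]])
    })
    names(path) <- MUSCLES

    C1 <- d$material[["C1"]] * stats::runif(1, 0.9, 1.1)
    mat <- material_coefficients(
      C1 = C1, C2 = 0,
      C3 = d$material[["C3"]] * stats::runif(1, 0.9, 1.1),
      C4 = d$material[["C4"]] * stats::runif(1, 0.9, 1.1),
      C5 = m_slope * fmax_total / mean_csa,
      lambda_star = 1 + eps0, kappa = 1000 * C1)

    structure(list(profile = profile, geometry = geometry,
                   truth = list(muscles = muscles, path = path, curve = curve,
                                material = mat, act = activation_params(),
                                fmax_total = fmax_total),
                   seed = seed),
              class = "at_subject")
  })
}

#' @export
print.at_subject <- function(x, ...) {
  p <- x$profile
  cat(sprintf("Synthetic subject (seed %d)\n", x$seed))
  cat(sprintf("  mass %.1f kg, height %.2f m, MVIC %.1f N m, AT moment arm %.1f mm\n",
              p$mass, p$height, p$mvic_torque, 1000 * p$at_moment_arm))
  cat(sprintf("  free tendon %.1f mm, CSA %.0f-%.0f mm^2, twist %g deg\n",
              p$tendon_resting_length, min(x$geometry$csa_profile),
              max(x$geometry$csa_profile), x$geometry$twist_total))
  invisible(x)
}

# Ground-truth MTU length (m) for a muscle at angles given in radians.
mtu_length_truth <- function(path, angles_rad) {
  th <- angles_rad
  path$L0 - path$r_knee * th[, 1] - path$r_ankle * th[, 2] +
    path$c_ankle * th[, 2]^2 - path$r_sub * th[, 3]
}

#' Default joint-angle grid for the MTU kinematics surrogate (degrees)
#' @export
default_mtu_grid <- function() {
  list(knee_fe = c(-10, 10, 30, 50, 70, 95),
       ankle_pf = c(-40, -25, -10, 0, 10, 25, 40, 55),
       ankle_ps = c(-25, -10, 0, 10, 25))
}

#' Fit the MTU kinematics surrogate from a subject's ground-truth geometry
#'
#' Samples the subject's MTU path functions on the angle grid and fits the
#' tensor-product cubic B-spline surrogate.  The path functions are
#' polynomial (quadratic in the ankle angles, linear in knee), which the
#' not-a-knot cubic interpolant reproduces exactly, so the surrogate equals
#' the ground-truth geometry to machine precision inside the grid.
#'
#' @param subject an `at_subject`.
#' @param grid angle grid in degrees (list of three vectors).
#' @export
build_mtu_surrogate <- function(subject, grid = default_mtu_grid()) {
  rad <- lapply(grid, function(g) g * pi / 180)
  full <- as.matrix(expand.grid(rad[[1]], rad[[2]], rad[[3]]))
  dims <- vapply(rad, length, 1L)
  lengths <- lapply(subject$truth$path, function(p)
    array(mtu_length_truth(p, full), dims))
  fit_mtu_spline(grid, lengths)
}

#' Ground-truth NMS model of a subject
#'
#' Assembles the forward model used to generate reference joint moments:
#' true Hill parameters, true tendon curve and the B-spline surrogate of the
#' true MTU geometry.
#'
#' @param subject an `at_subject`.
#' @param grid angle grid in degrees for the kinematics surrogate.
#' @export
truth_nms_model <- function(subject, grid = default_mtu_grid()) {
  nms_model(subject$truth$muscles, build_mtu_surrogate(subject, grid),
            subject$truth$curve, act = subject$truth$act)
}

#' Synthetic isometric force-elongation series
#'
#' Elongations are exact inversions of the ground-truth tendon curve at each
#' level's tendon force (torque over moment arm, normalized by the summed
#' triceps-surae maximum isometric force), so a curve fitted back to the
#' series recovers the truth exactly in the noise-free case.
#'
#' @param subject an `at_subject` (profile + truth curve are used).
#' @param levels contraction levels as fractions of MVIC (all <= 1).
#' @param noise_sd additive Gaussian noise SD on elongation (mm); seeded.
#' @param seed seed for the noise draws.
#' @return Data frame with columns `level`, `torque` (N m), `elongation` (mm).
#' @export
make_isometric_series <- function(subject, levels = c(0, 0.25, 0.50, 0.70),
                                  noise_sd = 0, seed = subject$seed) {
  if (any(levels > 1)) stop("contraction level above 1 (100% MVIC) rejected")
  stopifnot(all(levels >= 0))
  p <- subject$profile
  torque <- levels * p$mvic_torque
  fnorm <- (torque / p$at_moment_arm) / subject$truth$fmax_total
  strain <- strain_at_force(subject$truth$curve, fnorm)
  elong <- strain * p$tendon_resting_length
  if (noise_sd > 0) {
    elong <- elong + with_seed(seed + 1003L, stats::rnorm(length(elong), 0, noise_sd))
  }
  data.frame(level = levels, torque = torque, elongation = elong)
}

# -- dynamic trial templates ------------------------------------------------
# EMG envelopes are sums of Gaussian bumps (timing/width/amplitude per task)
# and joint angles are smooth splines through task keypoints; both are
# periodic for cyclic tasks.  Amplitudes and timings get small seeded jitter.

gauss_bump <- function(p, center, width, amp, periodic = TRUE) {
  v <- amp * exp(-0.5 * ((p - center) / width)^2)
  if (periodic) {
    v <- v + amp * exp(-0.5 * ((p - center - 1) / width)^2) +
      amp * exp(-0.5 * ((p - center + 1) / width)^2)
  }
  v
}

task_template <- function(task) {
  switch(task,
    walking = list(
      period = 1.2, duration = 4.8, periodic = TRUE,
      angles = list(
        knee_fe  = list(p = c(0, .1, .25, .4, .6, .75, .9, 1),
                        v = c(5, 18, 10, 5, 32, 52, 18, 5)),
        ankle_pf = list(p = c(0, .1, .3, .5, .6, .7, .85, 1),
                        v = c(0, -5, -10, 5, 20, 5, -5, 0)),
        ankle_ps = list(p = c(0, .25, .5, .75, 1), v = c(0, 4, 0, -4, 0))),
      emg = list(
        mg  = list(c(0.45, 0.07, 0.65)),
        lg  = list(c(0.45, 0.07, 0.55)),
        sol = list(c(0.42, 0.09, 0.70)),
        ta  = list(c(0.02, 0.05, 0.35), c(0.75, 0.10, 0.35)))),
    single_leg_hop = list(
      period = 0.6, duration = 3.0, periodic = TRUE,
      angles = list(
        knee_fe  = list(p = c(0, .15, .3, .55, .8, 1), v = c(10, 25, 12, 30, 15, 10)),
        ankle_pf = list(p = c(0, .1, .3, .5, .75, 1), v = c(0, -10, 18, 5, -5, 0)),
        ankle_ps = list(p = c(0, .5, 1), v = c(0, 2, 0))),
      emg = list(
        mg  = list(c(0.15, 0.08, 0.85)),
        lg  = list(c(0.15, 0.08, 0.75)),
        sol = list(c(0.13, 0.09, 0.85)),
        ta  = list(c(0.55, 0.10, 0.25)))),
    eccentric_heel_drop = list(
      period = NA, duration = 3.0, periodic = FALSE,
      ramp = list(ankle_from = 15, ankle_to = -15, knee = 5,
                  emg_from = 0.15, emg_to = 0.40, ta_level = 0.05)),
    mvic = list(
      period = NA, duration = 3.0, periodic = FALSE,
      plateau = list(level = 0.95, rise = 0.5, ta_level = 0.05)),
    stop(sprintf("unknown task '%s'", task)))
}

TASKS <- c("walking", "single_leg_hop", "eccentric_heel_drop", "mvic")

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

trial_signals <- function(task, tpl, t, jit) {
  if (!is.null(tpl$angles)) {
    p <- (t %% tpl$period) / tpl$period
    ang <- sapply(DOF_NAMES, function(dn) {
      k <- tpl$angles[[dn]]
      sf <- stats::splinefun(k$p, k$v * jit$angle_scale, method = "periodic")
      sf(p)
    })
    env <- sapply(MUSCLES, function(m) {
      bumps <- tpl$emg[[m]]
      v <- 0
      for (i in seq_along(bumps)) {
        b <- bumps[[i]]
        v <- v + gauss_bump(p, b[1] + jit$center_shift, b[2],
                            b[3] * jit$amp_scale[[m]])
      }
      pmin(pmax(v, 0), 1)
    })
  } else if (task == "eccentric_heel_drop") {
    r <- tpl$ramp
    s <- smoothstep((t - 0.3) / (max(t) - 0.6))
    ang <- cbind(knee_fe = rep(r$knee, length(t)),
                 ankle_pf = (r$ankle_from + (r$ankle_to - r$ankle_from) * s) *
                   jit$angle_scale,
                 ankle_ps = rep(0, length(t)))
    tri <- pmin(pmax((r$emg_from + (r$emg_to - r$emg_from) * s), 0), 1)
    env <- cbind(mg = tri * jit$amp_scale[["mg"]],
                 lg = 0.9 * tri * jit$amp_scale[["lg"]],
                 sol = 1.1 * pmin(tri, 0.9) * jit$amp_scale[["sol"]],
                 ta = rep(r$ta_level, length(t)))
  } else {  # mvic
    pl <- tpl$plateau
    s <- smoothstep(t / pl$rise)
    tri <- pl$level * s
    ang <- cbind(knee_fe = rep(5, length(t)), ankle_pf = rep(0, length(t)),
                 ankle_ps = rep(0, length(t)))
    env <- cbind(mg = tri, lg = tri, sol = tri, ta = rep(pl$ta_level, length(t)))
  }
  env <- pmin(pmax(env, 0), 1)
  list(angles = ang, env = env)
}

#' Generate a synthetic motion trial
#'
#' Joint angles (250 Hz) and EMG envelopes (1500 Hz) follow task-specific
#' templates: phasic gastrocnemius activity peaking in late stance for
#' walking, burst activity for hopping, a slow eccentric ankle ramp for heel
#' drops, and a ramp-and-hold plateau for MVIC.  Reference joint moments are
#' computed by running the subject's ground-truth NMS model forward on the
#' generated angles and envelopes, so calibration has an internally
#' consistent "inverse dynamics" target.
#'
#' @param task one of `"walking"`, `"single_leg_hop"`,
#'   `"eccentric_heel_drop"`, `"mvic"`.
#' @param subject an `at_subject`.
#' @param seed seed for the template jitter and noise.
#' @param duration trial length in s (default per task template).
#' @param emg_scale global multiplier on the EMG envelopes (0 gives the
#'   passive-only variant).
#' @param noise_sd additive Gaussian noise SD on the 1500 Hz envelopes.
#' @param truth_model optional precomputed [truth_nms_model()] (avoids
#'   refitting the kinematics surrogate for every trial).
#' @return Object of class `motion_trial`.
#' @export
make_trial <- function(task, subject, seed = subject$seed, duration = NULL,
                       emg_scale = 1, noise_sd = 0, truth_model = NULL) {
  tpl <- task_template(task)
  if (is.null(duration)) duration <- tpl$duration
  fs <- 250; emg_fs <- 1500
  n <- round(duration * fs)
  t <- seq(0, by = 1 / fs, length.out = n)
  te <- seq(0, by = 1 / emg_fs, length.out = n * (emg_fs / fs))
  jit <- with_seed(seed + 7L, list(
    angle_scale = stats::runif(1, 0.95, 1.05),
    center_shift = stats::rnorm(1, 0, 0.01),
    amp_scale = stats::setNames(as.list(stats::runif(4, 0.9, 1.1)), MUSCLES)))
  sig_frames <- trial_signals(task, tpl, t, jit)
  sig_emg <- trial_signals(task, tpl, te, jit)
  env <- sig_emg$env * emg_scale
  if (noise_sd > 0) {
    env <- env + with_seed(seed + 11L,
                           matrix(stats::rnorm(length(env), 0, noise_sd),
                                  nrow(env)))
  }
  env <- pmin(pmax(env, 0), 1)
  stopifnot(all(abs(sig_frames$angles) <= 60))
  trial <- structure(list(task = task, time = t, fs = fs, emg_fs = emg_fs,
                          angles = sig_frames$angles, emg = env,
                          emg_time = te, channels = MUSCLES),
                     class = "motion_trial")
  if (is.null(truth_model)) truth_model <- truth_nms_model(subject)
  trial$reference_moment <- nms_forward(truth_model, trial)$moments
  trial
}

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("Motion trial '%s': %.1f s, %d frames at %g Hz, EMG %d samples at %g Hz\n",
              x$task, max(x$time), length(x$time), x$fs, length(x$emg_time),
              x$emg_fs))
  invisible(x)
}
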