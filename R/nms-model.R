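# EMG-informed Hill-type model of the 3-DOF knee/ankle system:
# EMG processing, activation dynamics, B-spline MTU kinematics surrogate,
# muscle-tendon equilibrium, forward moment computation and calibration.
# DOF order everywhere: (knee flexion-extension, ankle plantar-dorsiflexion,
# ankle pronation-supination), angles in degrees at the interfaces,
# plantarflexion and knee flexion positive.

DOF_NAMES <- c("knee_fe", "ankle_pf", "ankle_ps")

#' EMG processing filter specification
#'
#' Causal chain applied to raw EMG: band-pass Butterworth, full-wave
#' rectification, low-pass Butterworth (the linear envelope), normalization by
#' the MVIC constant, clipping to \[0, 1\].  All filters are causal: the
#' envelope at time t depends only on samples at or before t.
#'
#' @param band band-pass corner frequencies in Hz.
#' @param band_order Butterworth order of the band-pass stage.
#' @param lowpass envelope low-pass cutoff in Hz.
#' @param lp_order Butterworth order of the low-pass stage.
#' @param mvic per-channel MVIC normalization constant (envelope units).
#' @export
emg_filter_spec <- function(band = c(30, 300), band_order = 2L,
                            lowpass = 6, lp_order = 2L, mvic = 1) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1], mvic > 0)
  structure(list(band = band, band_order = band_order, lowpass = lowpass,
                 lp_order = lp_order, mvic = mvic), class = "emg_filter_spec")
}

#' Compute a normalized EMG envelope from raw EMG
#'
#' @param x raw EMG signal (uniformly sampled).
#' @param fs sampling frequency in Hz.
#' @param spec an [emg_filter_spec()].
#' @param time optional time vector; if supplied it must be uniform.
#' @return Envelope in \[0, 1\], same length as `x`.
#' @export
process_emg <- function(x, fs, spec = emg_filter_spec(), time = NULL) {
  if (!is.null(time)) {
    dt <- diff(time)
    if (length(dt) && (max(dt) - min(dt)) > 1e-9 * max(abs(dt)))
      stop("non-uniform time grid")
  }
  bp <- signal::butter(spec$band_order, spec$band / (fs / 2), type = "pass")
  lp <- signal::butter(spec$lp_order, spec$lowpass / (fs / 2), type = "low")
  y <- biquad_run(list(b = as.numeric(bp$b), a = as.numeric(bp$a)), x)$y
  y <- abs(y)
  y <- biquad_run(list(b = as.numeric(lp$b), a = as.numeric(lp$a)), y)$y
  pmin(pmax(y / spec$mvic, 0), 1)
}

#' Activation dynamics parameters
#'
#' Second-order recursive filter (unit DC gain, poles set by the activation
#' and deactivation time constants) followed by the exponential shaping
#' nonlinearity `a = (exp(A u) - 1) / (exp(A) - 1)`.
#'
#' @param A shaping factor, dimensionless, in \[-3, 0).
#' @param tau_act,tau_deact activation / deactivation time constants in s.
#' @param emd electromechanical delay in s.
#' @export
activation_params <- function(A = -2, tau_act = 0.012, tau_deact = 0.024,
                              emd = 0.010) {
  stopifnot(A >= -3, A < 0, tau_act > 0, tau_deact > 0, emd >= 0)
  structure(list(A = A, tau_act = tau_act, tau_deact = tau_deact, emd = emd),
            class = "activation_params")
}

act_filter_coefs <- function(act, dt) {
  r1 <- exp(-dt / act$tau_act)
  r2 <- exp(-dt / act$tau_deact)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("unstable pole configuration")
  beta1 <- -(r1 + r2)
  beta2 <- r1 * r2
  list(alpha = 1 + beta1 + beta2, beta1 = beta1, beta2 = beta2)
}

#' Muscle activation from an EMG envelope
#'
#' Applies the electromechanical delay, the second-order recursive filter
#' (u(t) = alpha e(t-d) - beta1 u(t-1) - beta2 u(t-2), unit DC gain) and the
#' exponential shaping nonlinearity.  A constant envelope e therefore settles
#' at activation `(exp(A e) - 1) / (exp(A) - 1)`.
#'
#' @param envelope EMG envelope in \[0, 1\] sampled at `fs`.
#' @param fs sampling frequency in Hz.
#' @param act an [activation_params()].
#' @return Activation time series in \[0, 1\].
#' @export
activation_dynamics <- function(envelope, fs, act = activation_params()) {
  stopifnot(all(envelope >= 0), all(envelope <= 1))
  cf <- act_filter_coefs(act, 1 / fs)
  d <- as.integer(round(act$emd * fs))
  e <- if (d > 0) c(numeric(d), envelope[seq_len(max(0L, length(envelope) - d))]) else envelope
  u <- numeric(length(e))
  u1 <- 0; u2 <- 0
  for (t in seq_along(e)) {
    u[t] <- cf$alpha * e[t] - cf$beta1 * u1 - cf$beta2 * u2
    u2 <- u1; u1 <- u[t]
  }
  u <- pmin(pmax(u, 0), 1)
  (exp(act$A * u) - 1) / (exp(act$A) - 1)
}

# -- Hill-type curves -------------------------------------------------------
# Standard shapes with documented constants; lengths normalized by optimal
# fiber length, velocity by vmax * lopt.

FL_WIDTH <- 0.45       # Gaussian active force-length width
FP_SHAPE <- 4          # passive exponential shape factor
FP_STRAIN <- 0.6       # passive strain at which fp = 1
FV_AF <- 0.25          # force-velocity curvature (Hill a/F0)
FV_ECC_MAX <- 1.8      # eccentric force plateau

fl_active <- function(lnorm) exp(-(lnorm - 1)^2 / FL_WIDTH)

fp_passive <- function(lnorm) {
  ifelse(lnorm <= 1, 0,
         (exp(FP_SHAPE * (lnorm - 1) / FP_STRAIN) - 1) / (exp(FP_SHAPE) - 1))
}

fv_curve <- function(vnorm) {
  ifelse(vnorm >= 0,
         (FV_ECC_MAX * vnorm + FV_AF) / (vnorm + FV_AF),
         pmax(0, (1 + vnorm) / (1 - vnorm / FV_AF)))
}

#' Muscle parameter set for one Hill-type actuator
#'
#' @param fmax maximum isometric force (N).
#' @param lopt optimal fiber length (m).
#' @param lts tendon slack length (m).
#' @param phi0 pennation angle at optimal fiber length (degrees).
#' @param vmax maximum shortening velocity in optimal fiber lengths per s.
#' @export
muscle_params <- function(fmax, lopt, lts, phi0 = 0, vmax = 10) {
  stopifnot(fmax > 0, lopt > 0, lts > 0, phi0 >= 0, phi0 < 80, vmax > 0)
  structure(list(fmax = fmax, lopt = lopt, lts = lts, phi0 = phi0,
                 vmax = vmax), class = "muscle_params")
}

#' Maximum isometric force from muscle volume
#'
#' Applies the specific tension to the physiological cross-sectional area
#' PCSA = volume / optimal fiber length.
#'
#' @param volume_cm3 muscle volume in cm^3.
#' @param lopt_cm optimal fiber length in cm.
#' @param specific_tension specific tension in N/cm^2 (default 55).
#' @return Maximum isometric force in N.
#' @export
compute_fmax_from_volume <- function(volume_cm3, lopt_cm, specific_tension = 55) {
  stopifnot(all(volume_cm3 > 0), all(specific_tension > 0))
  if (any(lopt_cm <= 0)) stop("optimal fiber length must be positive")
  specific_tension * volume_cm3 / lopt_cm
}

pennation_at <- function(lf, params) {
  s <- pmin(sin(params$phi0 * pi / 180) * params$lopt / lf, 0.995)
  asin(s)
}

#' Solve fiber-tendon equilibrium for one muscle
#'
#' Finds the fiber length at which the projected fiber force
#' `fmax (a fl fv + fp) cos(phi)` equals the tendon force
#' `fmax f_t(strain)`, with pennation from the constant-thickness assumption
#' and tendon strain from the remaining MTU length.  Root-finding is
#' bisection-based (`uniroot`) on a physiologic fiber-length bracket; if the
#' equilibrium has no root inside the bracket the nearer bound is returned
#' with `clamped = TRUE`.
#'
#' @param activation muscle activation in \[0, 1\].
#' @param mtu_length muscle-tendon unit length (m).
#' @param params a [muscle_params()].
#' @param curve the tendon force-strain [tendon_curve()].
#' @param fiber_velocity fiber lengthening velocity (m/s, negative =
#'   shortening); held fixed during the solve (explicit causal scheme).
#' @return List with `force` (tendon force, N), `fiber_length` (m),
#'   `tendon_strain`, `pennation` (deg), `clamped`.
#' @export
solve_muscle_force <- function(activation, mtu_length, params, curve,
                               fiber_velocity = 0) {
  stopifnot(activation >= 0, activation <= 1, mtu_length > 0)
  vn <- fiber_velocity / (params$vmax * params$lopt)
  fv <- fv_curve(vn)
  g <- function(lf) {
    phi <- pennation_at(lf, params)
    eps <- (mtu_length - lf * cos(phi) - params$lts) / params$lts
    fm <- (activation * fl_active(lf / params$lopt) * fv +
             fp_passive(lf / params$lopt)) * cos(phi)
    fm - eval_tendon_force(curve, eps)
  }
  lo <- 0.3 * params$lopt
  hi <- 1.9 * params$lopt
  # degenerate slack case: tendon exactly at slack length, no fiber force
  lf_slack <- (mtu_length - params$lts)
  for (i in 1:30) {
    phi <- pennation_at(max(lf_slack, lo), params)
    lf_new <- (mtu_length - params$lts) / cos(phi)
    if (abs(lf_new - lf_slack) < 1e-14) break
    lf_slack <- lf_new
  }
  if (lf_slack >= lo && lf_slack <= hi) {
    fm0 <- activation * fl_active(lf_slack / params$lopt) * fv +
      fp_passive(lf_slack / params$lopt)
    if (fm0 < 1e-12) {
      return(list(force = 0, fiber_length = lf_slack, tendon_strain = 0,
                  pennation = pennation_at(lf_slack, params) * 180 / pi,
                  clamped = FALSE))
    }
  }
  glo <- g(lo); ghi <- g(hi)
  if (sign(glo) == sign(ghi)) {
    lf <- if (abs(glo) < abs(ghi)) lo else hi
    clamped <- TRUE
  } else {
    lf <- stats::uniroot(g, c(lo, hi), tol = 1e-13 * params$lopt,
                         maxiter = 1000L)$root
    clamped <- FALSE
  }
  phi <- pennation_at(lf, params)
  eps <- (mtu_length - lf * cos(phi) - params$lts) / params$lts
  list(force = params$fmax * eval_tendon_force(curve, eps),
       fiber_length = lf, tendon_strain = max(eps, 0),
       pennation = phi * 180 / pi, clamped = clamped)
}

# -- MTU kinematics surrogate ----------------------------------------------

#' Fit the multidimensional cubic B-spline MTU kinematics surrogate
#'
#' Tensor-product cubic B-spline (not-a-knot end conditions) interpolating
#' MTU length sampled on a full rectilinear grid over the three DOFs.  The
#' interpolant reproduces the samples at the grid nodes exactly and is
#' evaluated inside the grid only; moment arms are the negative partial
#' derivative of length with respect to the spanned joint angle in radians.
#'
#' @param grid list of three strictly increasing angle vectors in degrees
#'   (knee flexion, ankle plantarflexion, ankle pronation), each with at
#'   least 4 knots.
#' @param lengths named list (one entry per muscle) of 3-d arrays of MTU
#'   lengths (m) with dim `sapply(grid, length)`.
#' @return Object of class `mtu_surrogate`.
#' @export
fit_mtu_spline <- function(grid, lengths) {
  stopifnot(length(grid) == 3L, all(vapply(grid, length, 1L) >= 4L),
            all(vapply(grid, function(g) all(diff(g) > 0), TRUE)))
  rad <- lapply(grid, function(g) g * pi / 180)
  dims <- vapply(rad, length, 1L)
  kn <- lapply(rad, nak_knots)
  Ainv <- lapply(seq_len(3L), function(d) {
    A <- splines::splineDesign(kn[[d]], rad[[d]], ord = 4L)
    solve(A)
  })
  fits <- lapply(lengths, function(L) {
    stopifnot(all(dim(L) == dims))
    C <- L
    for (d in 1:3) {
      Cm <- apply(C, setdiff(1:3, d), identity)  # d-mode unfolding (nd x rest)
      Cm <- Ainv[[d]] %*% matrix(Cm, nrow = dims[d])
      C <- aperm(array(Cm, c(dims[d], dims[setdiff(1:3, d)])),
                 order(c(d, setdiff(1:3, d))))
    }
    C
  })
  structure(list(grid_rad = rad, knots = kn, dims = dims, coef = fits,
                 muscles = names(lengths),
                 ma_offset = stats::setNames(numeric(length(lengths)),
                                             names(lengths))),
            class = "mtu_surrogate")
}

mtu_basis <- function(object, angles_rad, deriv_dof = 0L) {
  lapply(1:3, function(d) {
    x <- angles_rad[, d]
    rng <- range(object$grid_rad[[d]])
    if (any(x < rng[1] - 1e-10 | x > rng[2] + 1e-10))
      stop("angle outside the fitted grid (no extrapolation)")
    x <- pmin(pmax(x, rng[1]), rng[2])
    dv <- if (d == deriv_dof) 1L else 0L
    splines::splineDesign(object$knots[[d]], x, ord = 4L,
                          derivs = rep(dv, length(x)))
  })
}

mtu_contract <- function(object, muscle, B) {
  C <- object$coef[[muscle]]
  d <- object$dims
  m <- nrow(B[[1]])
  T1 <- B[[1]] %*% matrix(C, d[1], d[2] * d[3])      # m x (n2 n3)
  T2 <- matrix(0, m, d[3])
  for (l in seq_len(d[3])) {
    T2[, l] <- rowSums(B[[2]] * T1[, (l - 1L) * d[2] + seq_len(d[2]), drop = FALSE])
  }
  rowSums(B[[3]] * T2)
}

#' Evaluate MTU lengths or moment arms from the kinematics surrogate
#'
#' @param object an `mtu_surrogate`.
#' @param angles matrix (or length-3 vector) of joint angles in degrees,
#'   columns (knee flexion, ankle plantarflexion, ankle pronation).
#' @param muscle muscle name.
#' @param what `"length"` (m) or `"moment_arm"` (m).
#' @param dof DOF index for the moment arm (default 2, ankle plantarflexion).
#' @param ... unused.
#' @export
predict.mtu_surrogate <- function(object, angles, muscle,
                                  what = c("length", "moment_arm"),
                                  dof = 2L, ...) {
  what <- match.arg(what)
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = 1L)
  a <- angles * pi / 180
  off <- object$ma_offset[[muscle]]
  if (what == "length") {
    v <- mtu_contract(object, muscle, mtu_basis(object, a, 0L))
    v - off * a[, 2]
  } else {
    v <- -mtu_contract(object, muscle, mtu_basis(object, a, dof))
    if (dof == 2L) v + off else v
  }
}

#' Adjust the surrogate so the model Achilles moment arm matches a measurement
#'
#' Adds a path offset (standing in for the distal attachment point of the
#' three triceps-surae musculotendon units) so that the model Achilles tendon
#' moment arm at the neutral ankle equals the measured value.  The moment arm
#' is linear in the offset, so the match is exact (well within 1e-4 m).
#'
#' @param object an `mtu_surrogate`.
#' @param target measured Achilles moment arm at neutral ankle (m).
#' @param muscles the triceps-surae muscle names sharing the Achilles path.
#' @param max_offset admissible attachment-point shift (m).
#' @return The adjusted surrogate, with attribute `"moment_arm_report"`.
#' @export
calibrate_moment_arm <- function(object, target,
                                 muscles = c("mg", "lg", "sol"),
                                 max_offset = 0.02) {
  neutral <- matrix(0, 1L, 3L)
  cur <- mean(vapply(muscles, function(m)
    predict(object, neutral, m, "moment_arm"), numeric(1)))
  delta <- target - cur
  if (abs(delta) > max_offset) {
    best <- cur + sign(delta) * max_offset
    stop(errorCondition(
      sprintf("target moment arm %.4f m unreachable; best achievable %.4f m",
              target, best),
      class = c("tendonstrain_unreachable", "error")))
  }
  object$ma_offset[muscles] <- object$ma_offset[muscles] + delta
  achieved <- mean(vapply(muscles, function(m)
    predict(object, neutral, m, "moment_arm"), numeric(1)))
  attr(object, "moment_arm_report") <-
    list(target = target, achieved = achieved, offset = delta)
  object
}
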