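# Open-loop forward NMS engine (batch) and its calibration.
#
# Fiber-tendon equilibrium uses a vectorized bisection over frames with a
# two-pass explicit fiber-velocity scheme: frames are first solved
# isometrically (zero fiber velocity), fiber velocity is then estimated by a
# causal first-order difference of those solved fiber lengths (low-pass
# filtered with the same causal Butterworth used for angles), and the frames
# are re-solved with that velocity held fixed.  Every quantity at frame i
# depends only on inputs at frames <= i, so the scheme is causal and the
# streaming pipeline reproduces the batch result frame by frame exactly.

#' Assemble an EMG-informed NMS model
#'
#' @param muscles named list of [muscle_params()] (expects `mg`, `lg`, `sol`,
#'   `ta`).
#' @param surrogate an `mtu_surrogate` from [fit_mtu_spline()].
#' @param curve the subject-fitted [tendon_curve()] installed on the three
#'   triceps-surae tendons.
#' @param curve_other tendon curve for the remaining (antagonist) MTUs; the
#'   default is a literature-shaped generic curve (a = 1300, eps0 = 0.015,
#'   i.e. about 3.5% strain at maximum isometric force).
#' @param act an [activation_params()].
#' @param fs frame rate in Hz.
#' @param smoothing_hz cutoff of the causal second-order Butterworth used for
#'   fiber-velocity (and, in the pipeline, angle/EMG) smoothing.
#' @return Object of class `nms_model`.
#' @export
nms_model <- function(muscles, surrogate, curve,
                      curve_other = tendon_curve(1300, 0.015),
                      act = activation_params(), fs = 250,
                      smoothing_hz = 6) {
  stopifnot(inherits(surrogate, "mtu_surrogate"),
            inherits(curve, "tendon_curve"),
            all(names(muscles) %in% surrogate$muscles))
  structure(list(muscles = muscles, surrogate = surrogate, curve = curve,
                 curve_other = curve_other, act = act, fs = fs,
                 smoothing_hz = smoothing_hz,
                 ts_muscles = intersect(names(muscles), c("mg", "lg", "sol"))),
            class = "nms_model")
}

#' @export
print.nms_model <- function(x, ...) {
  cat("EMG-informed Hill-type NMS model\n")
  cat("  muscles:", paste(names(x$muscles), collapse = ", "), "\n")
  cat(sprintf("  frame rate %g Hz, A = %.2f, tau_act/deact = %.0f/%.0f ms, emd = %.0f ms\n",
              x$fs, x$act$A, 1000 * x$act$tau_act, 1000 * x$act$tau_deact,
              1000 * x$act$emd))
  if (!is.null(attr(x, "calibration")))
    cat("  calibrated: objective", format(attr(x, "calibration")$objective_final,
                                          digits = 4), "\n")
  invisible(x)
}

muscle_curve <- function(model, muscle) {
  if (muscle %in% c("mg", "lg", "sol")) model$curve else model$curve_other
}

# Vectorized bisection on fiber length for one muscle across frames.
hill_bisect <- function(activation, mtu_length, vnorm, params, curve,
                        iters = 60L) {
  fv <- fv_curve(vnorm)
  g <- function(lf) {
    phi <- pennation_at(lf, params)
    cphi <- cos(phi)
    eps <- (mtu_length - lf * cphi - params$lts) / params$lts
    (activation * fl_active(lf / params$lopt) * fv +
       fp_passive(lf / params$lopt)) * cphi - eval_tendon_force(curve, eps)
  }
  lo <- rep(0.3 * params$lopt, length(mtu_length))
  hi <- rep(1.9 * params$lopt, length(mtu_length))
  glo <- g(lo); ghi <- g(hi)
  clamped <- sign(glo) == sign(ghi) & glo != 0 & ghi != 0
  nearer_lo <- abs(glo) < abs(ghi)
  for (k in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    gm <- g(mid)
    left <- (glo <= 0) == (gm <= 0)
    lo <- ifelse(left, mid, lo)
    glo <- ifelse(left, gm, glo)
    hi <- ifelse(left, hi, mid)
  }
  lf <- 0.5 * (lo + hi)
  lf[clamped] <- ifelse(nearer_lo[clamped], 0.3, 1.9) * params$lopt
  list(fiber_length = lf, clamped = clamped)
}

# Two-pass velocity scheme for one muscle over a whole trial.
forward_muscle <- function(activation, mtu_length, params, curve, fs,
                           smoothing_hz) {
  n <- length(activation)
  p1 <- hill_bisect(activation, mtu_length, numeric(n), params, curve)
  lf0 <- p1$fiber_length
  vraw <- numeric(n)
  if (n >= 3L) vraw[3:n] <- (lf0[2:(n - 1L)] - lf0[1:(n - 2L)]) * fs
  filt <- lowpass_biquad(smoothing_hz, fs)
  vf <- biquad_run(filt, vraw)$y
  p2 <- hill_bisect(activation, mtu_length, vf / (params$vmax * params$lopt),
                    params, curve)
  lf <- p2$fiber_length
  phi <- pennation_at(lf, params)
  eps <- (mtu_length - lf * cos(phi) - params$lts) / params$lts
  list(force = params$fmax * eval_tendon_force(curve, eps),
       fiber_length = lf, fiber_velocity = vf,
       tendon_strain = pmax(eps, 0), pennation = phi * 180 / pi,
       clamped = p2$clamped)
}

# Evaluate MTU lengths (nf x nm) and moment arms (nf x nm x 3) for all
# muscles at once; bases are shared across muscles.
mtu_eval_all <- function(surrogate, angles_deg) {
  a <- angles_deg * pi / 180
  bases <- lapply(0:3, function(d) mtu_basis(surrogate, a, d))
  nm <- length(surrogate$muscles)
  nf <- nrow(a)
  len <- matrix(0, nf, nm, dimnames = list(NULL, surrogate$muscles))
  ma <- array(0, c(nf, nm, 3L), dimnames = list(NULL, surrogate$muscles, DOF_NAMES))
  for (m in surrogate$muscles) {
    off <- surrogate$ma_offset[[m]]
    len[, m] <- mtu_contract(surrogate, m, bases[[1]]) - off * a[, 2]
    for (d in 1:3) {
      v <- -mtu_contract(surrogate, m, bases[[d + 1L]])
      ma[, m, d] <- if (d == 2L) v + off else v
    }
  }
  list(length = len, moment_arm = ma)
}

# Envelope samples aligned to the frame grid (EMG runs at an integer
# multiple of the frame rate; the sample sharing each frame's timestamp is
# used, i.e. the most recent one).
frame_envelopes <- function(trial) {
  step <- nrow(trial$emg) %/% nrow(trial$angles)
  idx <- seq(1L, by = step, length.out = nrow(trial$angles))
  trial$emg[idx, , drop = FALSE]
}

#' Run the calibrated NMS model forward over a trial
#'
#' Open-loop: EMG envelopes and joint angles in, per-muscle forces and
#' per-DOF joint moments out.  Deterministic for fixed inputs.
#'
#' @param model an [nms_model()].
#' @param trial a motion trial as produced by [make_trial()].
#' @return List with `time`, `activation`, `force` (N), `fiber_length`,
#'   `tendon_strain`, `moments` (N m, columns knee/ankle-pf/ankle-ps),
#'   `ts_force` (summed triceps-surae tendon force, N), `clamped_frames`.
#' @export
nms_forward <- function(model, trial) {
  env <- frame_envelopes(trial)
  kin <- mtu_eval_all(model$surrogate, trial$angles)
  nf <- nrow(trial$angles)
  mus <- names(model$muscles)
  act <- sapply(mus, function(m)
    activation_dynamics(env[, m], model$fs, model$act))
  force <- matrix(0, nf, length(mus), dimnames = list(NULL, mus))
  lf <- force; strain <- force
  clamped <- logical(nf)
  for (m in mus) {
    fm <- forward_muscle(act[, m], kin$length[, m], model$muscles[[m]],
                         muscle_curve(model, m), model$fs, model$smoothing_hz)
    force[, m] <- fm$force
    lf[, m] <- fm$fiber_length
    strain[, m] <- fm$tendon_strain
    clamped <- clamped | fm$clamped
  }
  moments <- sapply(1:3, function(d) rowSums(kin$moment_arm[, mus, d] * force))
  colnames(moments) <- DOF_NAMES
  list(time = trial$time, activation = act, force = force, fiber_length = lf,
       tendon_strain = strain, moments = moments,
       ts_force = rowSums(force[, model$ts_muscles, drop = FALSE]),
       clamped_frames = sum(clamped))
}

#' Calibrate NMS parameters against reference joint moments
#'
#' Minimizes the summed squared difference between model joint moments and
#' the reference ("inverse dynamics") moments stored in the trials, over the
#' tendon slack lengths of all modelled muscles and (optionally) the shared
#' activation/deactivation time constants.  Triceps-surae maximum isometric
#' forces stay fixed at their volume-derived values.  The search is a
#' derivative-free Nelder-Mead with parameters scaled to their initial
#' values and constrained to a +/-20% box (quadratic penalty outside); a
#' soft penalty keeps normalized fiber lengths inside \[0.4, 1.6\].
#'
#' @param model initial [nms_model()].
#' @param trials list of trials (one per task) with `reference_moment`.
#' @param calibrate character: parameter groups to optimize
#'   (`"tendon_slack_length"`, optionally also `"time_constants"`; the
#'   default calibrates slack lengths only, which are identifiable from the
#'   moment error, while time constants trade off against them).
#' @param bound_frac box half-width as a fraction of the initial values.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param restarts additional Nelder-Mead restarts from the best iterate.
#' @return The calibrated model; attribute `"calibration"` carries the
#'   objective report (initial/final objective, parameter table,
#'   convergence flag).
#' @export
calibrate_nms <- function(model, trials,
                          calibrate = "tendon_slack_length",
                          bound_frac = 0.2, maxit = 400L, restarts = 1L) {
  stopifnot(length(trials) >= 1L,
            all(vapply(trials, function(t) !is.null(t$reference_moment), TRUE)))
  mus <- names(model$muscles)
  use_tau <- "time_constants" %in% calibrate
  p0 <- c(stats::setNames(vapply(mus, function(m) model$muscles[[m]]$lts, 1),
                          paste0("lts_", mus)),
          if (use_tau) c(tau_act = model$act$tau_act,
                         tau_deact = model$act$tau_deact))
  apply_params <- function(model, p) {
    for (m in mus) model$muscles[[m]]$lts <- p[[paste0("lts_", m)]]
    if (use_tau) {
      model$act$tau_act <- p[["tau_act"]]
      model$act$tau_deact <- p[["tau_deact"]]
    }
    model
  }
  objective <- function(model) {
    tot <- 0
    for (tr in trials) {
      fw <- nms_forward(model, tr)
      tot <- tot + sum((fw$moments - tr$reference_moment)^2)
      ln <- sweep(fw$fiber_length, 2,
                  vapply(mus, function(m) model$muscles[[m]]$lopt, 1), "/")
      tot <- tot + 1e4 * sum(pmax(0, 0.25 - ln)^2 + pmax(0, ln - 1.8)^2)
    }
    tot
  }
  obj0 <- objective(model)
  fn <- function(x) {
    xc <- pmin(pmax(x, 1 - bound_frac), 1 + bound_frac)
    pen <- 1e6 * sum((x - xc)^2) * max(obj0, 1)
    objective(apply_params(model, stats::setNames(xc * p0, names(p0)))) + pen
  }
  opt <- stats::optim(rep(1, length(p0)), fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  for (r in seq_len(restarts)) {
    opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
  }
  xc <- pmin(pmax(opt$par, 1 - bound_frac), 1 + bound_frac)
  pfin <- stats::setNames(xc * p0, names(p0))
  out <- apply_params(model, pfin)
  attr(out, "calibration") <- list(
    objective_initial = obj0, objective_final = opt$value,
    converged = opt$convergence == 0L,
    params = data.frame(name = names(p0), initial = unname(p0),
                        final = unname(pfin)))
  if (opt$value > obj0)
    warning("calibration did not improve the objective; best iterate kept")
  out
}
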