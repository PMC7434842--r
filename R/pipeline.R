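# Frame-by-frame streaming engine: consume angle/EMG frames, advance the
# calibrated NMS model open-loop, sum the triceps-surae tendon forces, query
# the strain surrogate and emit strain frames with latency instrumentation.
# Every stage is strictly causal; batch processing of a trial and streamed
# processing of the same trial run the identical per-frame code and produce
# identical strain sequences.

#' Assemble the real-time strain pipeline
#'
#' @param nms a calibrated [nms_model()].
#' @param surrogate a [fit_surrogate()] strain surrogate (trained on the
#'   subject's FE table).
#' @param resting_length free-tendon resting length in mm (denominator of
#'   the global strain).
#' @param angle_cutoff_hz causal low-pass cutoff applied to incoming joint
#'   angles (the same second-order Butterworth family is applied to EMG).
#' @param emg_fs EMG sampling rate inside each frame block, Hz.
#' @return Object of class `strain_pipeline`.
#' @export
build_pipeline <- function(nms, surrogate, resting_length,
                           angle_cutoff_hz = 6, emg_fs = 1500) {
  stopifnot(inherits(nms, "nms_model"), inherits(surrogate, "strain_surrogate"),
            resting_length > 0)
  grid_deg <- lapply(nms$surrogate$grid_rad, function(g) range(g) * 180 / pi)
  structure(list(nms = nms, surrogate = surrogate,
                 resting_length = resting_length,
                 angle_filter = lowpass_biquad(angle_cutoff_hz, nms$fs),
                 emg_filter = lowpass_biquad(angle_cutoff_hz, emg_fs),
                 grid_deg = grid_deg,
                 act_coefs = act_filter_coefs(nms$act, 1 / nms$fs),
                 delay_frames = as.integer(round(nms$act$emd * nms$fs))),
            class = "strain_pipeline")
}

#' @export
print.strain_pipeline <- function(x, ...) {
  cat(sprintf("Real-time strain pipeline: %d muscles -> %d Gauss points, %g Hz frames\n",
              length(x$nms$muscles), x$surrogate$n_gauss, x$nms$fs))
  invisible(x)
}

#' Fresh streaming state for a pipeline
#'
#' Carries every piece of history the causal chain needs: filter states for
#' angles, EMG and fiber velocity, the activation recursion, the
#' electromechanical-delay buffers and the previous isometric fiber lengths.
#'
#' @param pipe a `strain_pipeline`.
#' @export
pipeline_state <- function(pipe) {
  mus <- names(pipe$nms$muscles)
  list(last_time = -Inf, frame = 0L, dropped = 0L, clamped_angles = 0L,
       emg_clipped = 0L,
       angle_f = replicate(3, biquad_state(pipe$angle_filter), simplify = FALSE),
       emg_f = stats::setNames(replicate(length(mus),
                                         biquad_state(pipe$emg_filter),
                                         simplify = FALSE), mus),
       delay = stats::setNames(replicate(length(mus),
                                         numeric(pipe$delay_frames),
                                         simplify = FALSE), mus),
       u1 = stats::setNames(numeric(length(mus)), mus),
       u2 = stats::setNames(numeric(length(mus)), mus),
       lf0_1 = stats::setNames(rep(NA_real_, length(mus)), mus),
       lf0_2 = stats::setNames(rep(NA_real_, length(mus)), mus),
       vf_f = stats::setNames(replicate(length(mus),
                                        biquad_state(pipe$angle_filter),
                                        simplify = FALSE), mus))
}

#' Advance the pipeline by one frame
#'
#' Causal low-pass of angles and EMG, electromechanical delay, activation
#' recursion, B-spline MTU kinematics, fiber-tendon equilibrium (isometric
#' solve, causal fiber-velocity estimate from the previous two frames,
#' velocity-corrected re-solve), triceps-surae force summation and surrogate
#' strain-field lookup.  Angles outside the fitted spline grid are clamped
#' and counted; a missing EMG channel is an error.
#'
#' @param pipe a `strain_pipeline`.
#' @param frame list with `timestamp` (s), `angles` (3 DOFs, degrees) and
#'   `emg` (matrix of envelope samples x channels for this frame period).
#' @param state a [pipeline_state()].
#' @return List with `frame` (the strain frame) and the updated `state`.
#' @export
pipeline_step <- function(pipe, frame, state) {
  t_start <- proc.time()[[3]]
  nms <- pipe$nms
  mus <- names(nms$muscles)
  if (!all(mus %in% colnames(frame$emg)))
    stop(sprintf("missing EMG channel(s): %s",
                 paste(setdiff(mus, colnames(frame$emg)), collapse = ", ")))
  # causal angle filtering + grid clamping
  ang <- numeric(3)
  for (d in 1:3) {
    st <- biquad_step(pipe$angle_filter, frame$angles[d], state$angle_f[[d]])
    ang[d] <- st$y
    state$angle_f[[d]] <- st$state
  }
  clamped <- FALSE
  for (d in 1:3) {
    r <- pipe$grid_deg[[d]]
    if (ang[d] < r[1] || ang[d] > r[2]) {
      ang[d] <- min(max(ang[d], r[1]), r[2])
      clamped <- TRUE
    }
  }
  if (clamped) state$clamped_angles <- state$clamped_angles + 1L
  # EMG: filter every sample in the block, consume the most recent
  env <- stats::setNames(numeric(length(mus)), mus)
  for (m in mus) {
    xs <- frame$emg[, m]
    stf <- state$emg_f[[m]]
    y <- 0
    for (x in xs) {
      st <- biquad_step(pipe$emg_filter, x, stf)
      y <- st$y
      stf <- st$state
    }
    state$emg_f[[m]] <- stf
    if (y > 1) state$emg_clipped <- state$emg_clipped + 1L
    env[m] <- min(max(y, 0), 1)
  }
  # electromechanical delay + activation recursion
  act <- stats::setNames(numeric(length(mus)), mus)
  cf <- pipe$act_coefs
  for (m in mus) {
    if (pipe$delay_frames > 0L) {
      buf <- state$delay[[m]]
      e_d <- buf[1]
      state$delay[[m]] <- c(buf[-1], env[m])
    } else e_d <- env[m]
    u <- cf$alpha * e_d - cf$beta1 * state$u1[[m]] - cf$beta2 * state$u2[[m]]
    state$u2[[m]] <- state$u1[[m]]
    state$u1[[m]] <- u
    u <- min(max(u, 0), 1)
    act[m] <- (exp(nms$act$A * u) - 1) / (exp(nms$act$A) - 1)
  }
  # kinematics and equilibrium (two-pass causal velocity scheme)
  kin <- mtu_eval_all(nms$surrogate, matrix(ang, 1L))
  force <- stats::setNames(numeric(length(mus)), mus)
  for (m in mus) {
    p <- nms$muscles[[m]]
    crv <- muscle_curve(nms, m)
    lmtu <- kin$length[1, m]
    lf0 <- hill_bisect(act[[m]], lmtu, 0, p, crv)$fiber_length
    vraw <- if (!is.na(state$lf0_2[[m]]))
      (state$lf0_1[[m]] - state$lf0_2[[m]]) * nms$fs else 0
    st <- biquad_step(pipe$angle_filter, vraw, state$vf_f[[m]])
    state$vf_f[[m]] <- st$state
    state$lf0_2[[m]] <- state$lf0_1[[m]]
    state$lf0_1[[m]] <- lf0
    sol <- hill_bisect(act[[m]], lmtu, st$y / (p$vmax * p$lopt), p, crv)
    phi <- pennation_at(sol$fiber_length, p)
    eps <- (lmtu - sol$fiber_length * cos(phi) - p$lts) / p$lts
    force[m] <- p$fmax * eval_tendon_force(crv, eps)
  }
  ts_force <- sum(force[nms$ts_muscles])
  pred <- predict(pipe$surrogate, ts_force)
  strains <- as.numeric(pred$strains)
  state$frame <- state$frame + 1L
  state$last_time <- frame$timestamp
  out <- list(timestamp = frame$timestamp, ts_force = ts_force,
              force = force, activation = act,
              global_strain = pred$elongation / pipe$resting_length,
              strains = strains,
              min_strain = min(strains), mean_strain = mean(strains),
              max_strain = max(strains),
              clamped_angles = clamped, force_clamped = pred$clamped,
              compute_time = max(proc.time()[[3]] - t_start, 1e-6) * 1000)
  list(frame = out, state = state)
}

#' Split a motion trial into frame messages
#'
#' One message per angle frame; each carries the EMG envelope samples of its
#' frame period (the block ending at the frame's timestamp).
#'
#' @param trial a [make_trial()] trial.
#' @export
trial_frames <- function(trial) {
  n <- nrow(trial$angles)
  step <- nrow(trial$emg) %/% n
  lapply(seq_len(n), function(i) {
    hi <- (i - 1L) * step + 1L
    lo <- max(1L, hi - step + 1L)
    list(timestamp = trial$time[i], angles = trial$angles[i, ],
         emg = trial$emg[lo:hi, , drop = FALSE])
  })
}

#' Stream frames through the pipeline
#'
#' Processes ordered frame messages one by one (frame conservation: one
#' strain frame per accepted message), drops out-of-order frames with a
#' count, optionally forwards each strain frame to a sink callback, and
#' returns the strain sequence plus a latency report (mean and 95th
#' percentile per-frame compute time, histogram).
#'
#' @param pipe a `strain_pipeline`.
#' @param frames list of frame messages (see [trial_frames()]).
#' @param state optional initial [pipeline_state()].
#' @param sink optional function called with each strain frame (e.g. a
#'   writer for live feedback).
#' @return Object of class `stream_result`: `time`, `ts_force`,
#'   `global_strain`, `strains` (frames x Gauss points), summary columns,
#'   `latency` (a `latency_report`), `state`.
#' @export
run_stream <- function(pipe, frames, state = pipeline_state(pipe),
                       sink = NULL) {
  n <- length(frames)
  keep <- logical(n)
  out_t <- numeric(n); out_f <- numeric(n); out_g <- numeric(n)
  out_min <- numeric(n); out_mean <- numeric(n); out_max <- numeric(n)
  out_ct <- numeric(n)
  strains <- matrix(NA_real_, n, pipe$surrogate$n_gauss)
  k <- 0L
  for (fr in frames) {
    if (fr$timestamp <= state$last_time) {
      state$dropped <- state$dropped + 1L
      next
    }
    res <- pipeline_step(pipe, fr, state)
    state <- res$state
    k <- k + 1L
    sf <- res$frame
    out_t[k] <- sf$timestamp; out_f[k] <- sf$ts_force
    out_g[k] <- sf$global_strain
    out_min[k] <- sf$min_strain; out_mean[k] <- sf$mean_strain
    out_max[k] <- sf$max_strain; out_ct[k] <- sf$compute_time
    strains[k, ] <- sf$strains
    if (!is.null(sink)) sink(sf)
  }
  idx <- seq_len(k)
  ct <- out_ct[idx]
  h <- graphics::hist(ct, breaks = 30L, plot = FALSE)
  latency <- structure(list(frames = k, mean = mean(ct),
                            p95 = unname(stats::quantile(ct, 0.95)),
                            histogram = list(breaks = h$breaks,
                                             counts = h$counts)),
                       class = "latency_report")
  structure(list(time = out_t[idx], ts_force = out_f[idx],
                 global_strain = out_g[idx], strains = strains[idx, , drop = FALSE],
                 min_strain = out_min[idx], mean_strain = out_mean[idx],
                 max_strain = out_max[idx], compute_time = ct,
                 dropped = state$dropped, latency = latency, state = state),
            class = "stream_result")
}

#' @export
print.latency_report <- function(x, ...) {
  cat(sprintf("Latency over %d frames: mean %.2f ms, 95th percentile %.2f ms\n",
              x$frames, x$mean, x$p95))
  invisible(x)
}

#' @export
print.stream_result <- function(x, ...) {
  cat(sprintf("Stream result: %d frames (%d dropped), peak global strain %.3f at %.2f s\n",
              length(x$time), x$dropped, max(x$global_strain),
              x$time[which.max(x$global_strain)]))
  print(x$latency)
  invisible(x)
}

#' Batch-process a whole trial through the pipeline
#'
#' Runs the identical per-frame streaming code over the trial's frames, so
#' the result equals [run_stream()] on [trial_frames()] exactly.
#'
#' @param pipe a `strain_pipeline`.
#' @param trial a `motion_trial`.
#' @export
process_trial <- function(pipe, trial) {
  run_stream(pipe, trial_frames(trial))
}

#' Global tendon strain from elongation
#'
#' Proximal-to-distal elongation normalized by the tendon resting length.
#'
#' @param elongation elongation in mm.
#' @param resting_length resting length in mm (> 0).
#' @export
compute_global_strain <- function(elongation, resting_length) {
  if (resting_length <= 0) stop("resting length must be positive")
  elongation / resting_length
}

#' Write a stream result as delimited text
#'
#' Per-frame summary columns (time, summed force, global/min/mean/max
#' strain, compute time); optionally the full per-Gauss-point field.
#'
#' @param result a `stream_result`.
#' @param path output TSV path.
#' @param full also write all Gauss-point strain columns.
#' @export
write_stream_result <- function(result, path, full = FALSE) {
  df <- data.frame(time = result$time, ts_force = result$ts_force,
                   global_strain = result$global_strain,
                   min_strain = result$min_strain,
                   mean_strain = result$mean_strain,
                   max_strain = result$max_strain,
                   compute_time_ms = result$compute_time)
  if (full) {
    gp <- as.data.frame(result$strains)
    names(gp) <- sprintf("gp%04d", seq_len(ncol(gp)))
    df <- cbind(df, gp)
  }
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
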