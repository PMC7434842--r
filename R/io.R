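# Plain-text artifact I/O: subject/geometry/parameters as nested-key YAML
# config files, trial time-series as tab-delimited text with a header row.
# All writers keep full double precision so files re-parse losslessly.

yaml_write <- function(x, path) {
  writeLines(yaml::as.yaml(x, precision = 17L), path)
  invisible(path)
}

#' Write / read a synthetic subject as a YAML config
#'
#' Stores the profile, tendon geometry and the full ground-truth parameter
#' set (Hill-type muscle parameters, MTU path coefficients, tendon curve,
#' constitutive coefficients) as a nested key-value config.
#'
#' @param subject an `at_subject`.
#' @param path file path (conventionally `subject.yaml`).
#' @export
write_subject <- function(subject, path) {
  tr <- subject$truth
  profile <- subject$profile
  profile$muscle_volumes <- as.list(profile$muscle_volumes)
  profile$emg_max <- as.list(profile$emg_max)
  yaml_write(list(
    seed = subject$seed,
    profile = profile,
    geometry = subject$geometry,
    truth = list(
      muscles = lapply(tr$muscles, unclass),
      path = tr$path,
      curve = unclass(tr$curve)[c("a", "eps0", "m", "q")],
      material = unclass(tr$material),
      act = unclass(tr$act),
      fmax_total = tr$fmax_total)), path)
}

#' @rdname write_subject
#' @export
read_subject <- function(path) {
  y <- yaml::read_yaml(path)
  y$profile$muscle_volumes <- unlist(y$profile$muscle_volumes)
  y$profile$emg_max <- unlist(y$profile$emg_max)
  muscles <- lapply(y$truth$muscles, function(m)
    do.call(muscle_params, m[c("fmax", "lopt", "lts", "phi0", "vmax")]))
  mat <- y$truth$material
  structure(list(
    profile = y$profile,
    geometry = y$geometry,
    truth = list(
      muscles = muscles, path = y$truth$path,
      curve = tendon_curve(y$truth$curve$a, y$truth$curve$eps0),
      material = material_coefficients(C1 = mat$C1, C2 = mat$C2, C3 = mat$C3,
                                       C4 = mat$C4, C5 = mat$C5,
                                       lambda_star = mat$lambda_star,
                                       kappa = mat$kappa),
      act = do.call(activation_params, y$truth$act),
      fmax_total = y$truth$fmax_total),
    seed = y$seed), class = "at_subject")
}

full_precision <- function(df) {
  as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col),
    stringsAsFactors = FALSE)
}

#' Write / read a motion trial as delimited-text time series
#'
#' Three files per trial: `<prefix>_angles.tsv` (time, joint angles, and the
#' reference joint moments at the frame rate), `<prefix>_emg.tsv` (time and
#' per-channel envelopes at the EMG rate) and `<prefix>_meta.yaml` (task and
#' rates).  Full double precision; reading the files back reconstructs the
#' trial exactly.
#'
#' @param trial a `motion_trial`.
#' @param prefix path prefix for the three files.
#' @export
write_trial <- function(trial, prefix) {
  ang <- data.frame(time = trial$time, trial$angles)
  if (!is.null(trial$reference_moment)) {
    rm <- as.data.frame(trial$reference_moment)
    names(rm) <- paste0("moment_", colnames(trial$reference_moment))
    ang <- cbind(ang, rm)
  }
  utils::write.table(full_precision(ang), paste0(prefix, "_angles.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  emg <- data.frame(time = trial$emg_time, trial$emg)
  utils::write.table(full_precision(emg), paste0(prefix, "_emg.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  yaml_write(list(task = trial$task, fs = trial$fs, emg_fs = trial$emg_fs,
                  channels = trial$channels), paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @rdname write_trial
#' @export
read_trial <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  ang <- utils::read.table(paste0(prefix, "_angles.tsv"), header = TRUE,
                           sep = "\t")
  emg <- utils::read.table(paste0(prefix, "_emg.tsv"), header = TRUE,
                           sep = "\t")
  mom_cols <- grep("^moment_", names(ang))
  trial <- structure(list(
    task = meta$task, time = ang$time, fs = meta$fs, emg_fs = meta$emg_fs,
    angles = as.matrix(ang[, DOF_NAMES]),
    emg = as.matrix(emg[, meta$channels]),
    emg_time = emg$time, channels = meta$channels), class = "motion_trial")
  if (length(mom_cols)) {
    rm <- as.matrix(ang[, mom_cols])
    colnames(rm) <- sub("^moment_", "", colnames(rm))
    trial$reference_moment <- rm
  }
  trial
}

#' Write / read a fitted tendon curve as a YAML config
#'
#' @param curve a `tendon_curve`.
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  yaml_write(list(a = curve$a, eps0 = curve$eps0, m = curve$m, q = curve$q,
                  rss = curve$rss), path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  y <- yaml::read_yaml(path)
  crv <- tendon_curve(y$a, y$eps0)
  crv$rss <- y$rss
  crv
}

#' Write / read calibrated material coefficients as YAML
#'
#' @param coeffs a `material_coefficients`.
#' @param path file path.
#' @export
write_material <- function(coeffs, path) yaml_write(unclass(coeffs), path)

#' @rdname write_material
#' @export
read_material <- function(path) {
  y <- yaml::read_yaml(path)
  material_coefficients(C1 = y$C1, C2 = y$C2, C3 = y$C3, C4 = y$C4,
                        C5 = y$C5, lambda_star = y$lambda_star,
                        kappa = y$kappa)
}

#' Write / read calibrated NMS parameters as YAML
#'
#' @param model an `nms_model`.
#' @param path file path.
#' @export
write_nms_params <- function(model, path) {
  yaml_write(list(muscles = lapply(model$muscles, unclass),
                  act = unclass(model$act),
                  curve = unclass(model$curve)[c("a", "eps0")],
                  curve_other = unclass(model$curve_other)[c("a", "eps0")],
                  fs = model$fs, smoothing_hz = model$smoothing_hz), path)
}

#' Read NMS parameters and rebuild the model on a kinematics surrogate
#' @param path file path written by [write_nms_params()].
#' @param surrogate an `mtu_surrogate` for the subject.
#' @export
read_nms_params <- function(path, surrogate) {
  y <- yaml::read_yaml(path)
  muscles <- lapply(y$muscles, function(m)
    do.call(muscle_params, m[c("fmax", "lopt", "lts", "phi0", "vmax")]))
  nms_model(muscles, surrogate,
            curve = tendon_curve(y$curve$a, y$curve$eps0),
            curve_other = tendon_curve(y$curve_other$a, y$curve_other$eps0),
            act = do.call(activation_params, y$act),
            fs = y$fs, smoothing_hz = y$smoothing_hz)
}
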