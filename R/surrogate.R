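# Fast force -> strain-field surrogates of the FE model: per-Gauss-point
# univariate interpolants over force (cubic B-spline with not-a-knot ends;
# linear order-2 B-spline) and a single multivariate PLS regression on
# polynomial force features.  Leave-one-out validation selects the method.

SURROGATE_METHODS <- c("pls", "cubic_spline", "basis_spline")

pls_features <- function(force) {
  X <- cbind(F1 = force, F2 = force^2, F3 = force^3)
  rownames(X) <- NULL
  X
}

fit_pls_surrogate <- function(force, Y, ncomp) {
  mixOmics::pls(pls_features(force), Y, ncomp = ncomp, mode = "regression",
                scale = TRUE)
}

# inner leave-one-out over the training levels to choose the number of
# PLS components (capped at 3)
choose_pls_ncomp <- function(force, Y, cap = 3L) {
  n <- length(force)
  rmse <- sapply(seq_len(cap), function(nc) {
    errs <- vapply(2:(n - 1L), function(k) {
      fit <- fit_pls_surrogate(force[-k], Y[-k, , drop = FALSE], nc)
      pred <- predict(fit, pls_features(force[k]))$predict[, , nc]
      sqrt(mean((pred - Y[k, ])^2))
    }, numeric(1))
    mean(errs)
  })
  which.min(rmse)
}

#' Fit a force-to-strain-field surrogate of the FE model
#'
#' Spline methods fit one univariate interpolant per Gauss point over the
#' training forces (so every training row is reproduced exactly); the PLS
#' method fits a single multivariate regression from polynomial force
#' features `(F, F^2, F^3)` to the strain vector, with the number of
#' components (at most 3) chosen by an inner leave-one-out over the
#' training levels.  All surrogates also carry a dedicated cubic spline
#' over the per-level global elongation.
#'
#' @param table a [generate_training_table()] `strain_table` with at least
#'   4 strictly increasing force levels.
#' @param method `"cubic_spline"`, `"basis_spline"` (order-2, i.e. broken
#'   linear, B-spline interpolant) or `"pls"`.
#' @return Object of class `strain_surrogate`.
#' @export
fit_surrogate <- function(table, method = c("cubic_spline", "basis_spline",
                                            "pls")) {
  method <- match.arg(method)
  f <- table$force
  if (length(f) < 4L) stop("need at least 4 force levels")
  if (any(diff(f) <= 0)) stop("duplicate or non-increasing force levels")
  core <- switch(method,
    cubic_spline = nak_spline_fit(f, table$strains, ord = 4L),
    basis_spline = nak_spline_fit(f, table$strains, ord = 2L),
    pls = {
      nc <- choose_pls_ncomp(f, table$strains)
      list(fit = fit_pls_surrogate(f, table$strains, nc), ncomp = nc)
    })
  structure(list(method = method, core = core,
                 elongation_spline = nak_spline_fit(f, cbind(table$elongation),
                                                    ord = 4L),
                 force_range = range(f), n_gauss = table$n_gauss,
                 mvic_force = table$mvic_force),
            class = "strain_surrogate")
}

#' @export
print.strain_surrogate <- function(x, ...) {
  cat(sprintf("Strain surrogate (%s): %d Gauss points, trained on %.0f-%.0f N\n",
              x$method, x$n_gauss, x$force_range[1], x$force_range[2]))
  invisible(x)
}

#' Predict the localized strain field at given tendon forces
#'
#' Within the training range the surrogate interpolates (spline methods
#' reproduce training rows exactly); forces above the range are clamped to
#' the top training level and flagged.  Evaluation is a small basis-times-
#' coefficient product, independent of the FE solver.
#'
#' @param object a `strain_surrogate`.
#' @param force tendon force in N (scalar or vector, >= 0).
#' @param ... unused.
#' @return List with `strains` (length(force) x n_gauss matrix),
#'   `elongation` (mm), `clamped` (logical per force).
#' @export
predict.strain_surrogate <- function(object, force, ...) {
  if (any(force < 0)) stop("negative force")
  clamped <- force > object$force_range[2] + 1e-9
  fq <- pmin(force, object$force_range[2])
  strains <- switch(object$method,
    cubic_spline = ,
    basis_spline = nak_spline_eval(object$core, fq),
    pls = {
      p <- predict(object$core$fit, pls_features(fq))$predict
      matrix(p[, , object$core$ncomp], nrow = length(fq))
    })
  elong <- as.numeric(nak_spline_eval(object$elongation_spline, fq))
  list(strains = strains, elongation = elong, clamped = clamped)
}

#' Leave-one-out validation of the surrogate methods
#'
#' For each interior force level, each method is retrained on the remaining
#' levels and predicts the held-out level; errors are pooled over all Gauss
#' points and levels into one RMSE and one correlation coefficient per
#' method.  The two extreme levels (0 and the top force) are excluded by
#' default because predicting them would require extrapolation; set
#' `include_extremes = TRUE` to include them (splines are then evaluated at
#' their clamped boundary).  The PLS component count is chosen once on the
#' full table and reused in every fold.
#'
#' @param table a `strain_table` with at least 5 levels.
#' @param methods character vector of methods to compare.
#' @param include_extremes also hold out the boundary levels.
#' @return Object of class `loo_report`: `rmse`, `r`, `per_level_rmse`,
#'   `selected`, `predictions` (long data frame of pooled pairs).
#' @export
loo_validate <- function(table, methods = SURROGATE_METHODS,
                         include_extremes = FALSE) {
  if (length(methods) == 0L) stop("method list is empty")
  stopifnot(all(methods %in% SURROGATE_METHODS))
  n <- length(table$force)
  if (n < 5L) stop("need at least 5 levels for leave-one-out")
  folds <- if (include_extremes) seq_len(n) else 2:(n - 1L)
  pls_nc <- if ("pls" %in% methods) choose_pls_ncomp(table$force, table$strains)
  err2 <- stats::setNames(numeric(length(methods)), methods)
  npair <- 0L
  per_level <- matrix(NA_real_, length(folds), length(methods),
                      dimnames = list(NULL, methods))
  pred_all <- stats::setNames(vector("list", length(methods)), methods)
  act_all <- NULL
  for (fi in seq_along(folds)) {
    k <- folds[fi]
    sub <- table
    sub$force <- table$force[-k]
    sub$fraction <- table$fraction[-k]
    sub$strains <- table$strains[-k, , drop = FALSE]
    sub$elongation <- table$elongation[-k]
    actual <- table$strains[k, ]
    act_all <- c(act_all, actual)
    for (m in methods) {
      pred <- if (m == "pls") {
        fit <- fit_pls_surrogate(sub$force, sub$strains, pls_nc)
        as.numeric(predict(fit, pls_features(table$force[k]))$predict[, , pls_nc])
      } else {
        srg <- fit_surrogate(sub, m)
        as.numeric(predict(srg, min(table$force[k], max(sub$force)))$strains)
      }
      e <- pred - actual
      err2[m] <- err2[m] + sum(e^2)
      per_level[fi, m] <- sqrt(mean(e^2))
      pred_all[[m]] <- c(pred_all[[m]], pred)
    }
    npair <- npair + length(actual)
  }
  rmse <- sqrt(err2 / npair)
  r <- vapply(pred_all, function(p) stats::cor(p, act_all), numeric(1))
  structure(list(rmse = rmse, r = r, per_level_rmse = per_level,
                 levels = table$force[folds],
                 selected = methods[which.min(rmse)],
                 n_pooled = npair, pls_ncomp = pls_nc,
                 predictions = pred_all, actual = act_all),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat("Leave-one-out surrogate validation\n")
  for (m in names(x$rmse)) {
    cat(sprintf("  %-13s RMSE = %.3e strain, R = %.6f%s\n", m, x$rmse[m],
                x$r[m], if (m == x$selected) "  <- selected" else ""))
  }
  invisible(x)
}

#' @export
plot.loo_report <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$predictions)))
  on.exit(graphics::par(old))
  for (m in names(x$predictions)) {
    graphics::plot(x$actual, x$predictions[[m]], pch = ".",
                   xlab = "FE strain", ylab = "surrogate strain",
                   main = sprintf("%s (RMSE %.1e)", m, x$rmse[m]), ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

#' Serialize / load a surrogate training table and method tag as JSON
#'
#' The surrogate is reconstructed from its training data on load (the fits
#' are deterministic), keeping the on-disk format plain text.
#'
#' @param object a `strain_surrogate` or `strain_table` plus method.
#' @param table the training `strain_table`.
#' @param path file path.
#' @export
write_surrogate <- function(object, table, path) {
  jsonlite::write_json(list(method = object$method,
                            force = table$force, fraction = table$fraction,
                            elongation = table$elongation,
                            mvic_force = table$mvic_force,
                            strains = table$strains),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- structure(list(force = j$force, fraction = j$fraction,
                        strains = j$strains, elongation = j$elongation,
                        mvic_force = j$mvic_force,
                        n_gauss = ncol(j$strains)),
                   class = "strain_table")
  fit_surrogate(tab, j$method)
}
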