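#' Piecewise quadratic-linear tendon force-strain curve
#'
#' Constructs the dimensionless, C1-continuous tendon force-strain curve
#' \deqn{f(\epsilon) = 0 \;(\epsilon < 0);\quad a\epsilon^2 \;(0 \le \epsilon <
#' \epsilon_0);\quad m\epsilon + q \;(\epsilon \ge \epsilon_0)}
#' where force is normalized by maximum isometric force.  C1 continuity at the
#' toe-to-linear transition fixes the linear branch: `m = 2 a eps0` and
#' `q = -a eps0^2`, so the curve has exactly two free parameters.
#'
#' @param a quadratic (toe-region) coefficient, normalized force per strain^2;
#'   must be positive.
#' @param eps0 transition strain between the quadratic and linear branches
#'   (dimensionless, positive).
#' @return An object of class `tendon_curve` with elements `a`, `eps0`, `m`,
#'   `q` and, when produced by [fit_tendon_curve()], the fit residual and data.
#' @seealso [fit_tendon_curve()], [predict.tendon_curve()], [strain_at_force()]
#' @export
#' @examples
#' crv <- tendon_curve(a = 200, eps0 = 0.04)
#' predict(crv, strain = c(-0.01, 0.02, 0.04, 0.08))
tendon_curve <- function(a, eps0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(eps0), length(eps0) == 1L, is.finite(eps0), eps0 > 0)
  structure(list(a = a, eps0 = eps0, m = 2 * a * eps0, q = -a * eps0^2),
            class = "tendon_curve")
}

#' @export
print.tendon_curve <- function(x, ...) {
  cat("Tendon force-strain curve (piecewise quadratic-linear, C1)\n")
  cat(sprintf("  a = %.6g, eps0 = %.6g, m = %.6g, q = %.6g\n",
              x$a, x$eps0, x$m, x$q))
  if (!is.null(x$rss))
    cat(sprintf("  fitted to %d points, residual sum of squares = %.4g\n",
                nrow(x$data), x$rss))
  invisible(x)
}

#' @export
coef.tendon_curve <- function(object, ...) {
  c(a = object$a, eps0 = object$eps0, m = object$m, q = object$q)
}

#' Evaluate normalized tendon force at given strains
#'
#' @param object a [tendon_curve()].
#' @param strain numeric vector of tendon strains (dimensionless).
#' @param ... unused.
#' @return Normalized tendon force, same length as `strain`.  Zero for
#'   non-positive strains; non-decreasing everywhere.
#' @export
predict.tendon_curve <- function(object, strain, ...) {
  eval_tendon_force(object, strain)
}

eval_tendon_force <- function(curve, strain) {
  f <- numeric(length(strain))
  toe <- strain > 0 & strain < curve$eps0
  lin <- strain >= curve$eps0
  f[toe] <- curve$a * strain[toe]^2
  f[lin] <- curve$m * strain[lin] + curve$q
  f
}

#' Invert the tendon curve: strain at a given normalized force
#'
#' Analytic inverse of the piecewise curve on its monotone branch
#' (`strain >= 0`): the toe branch for forces below `a eps0^2`, the linear
#' branch above.
#'
#' @param curve a [tendon_curve()].
#' @param force normalized tendon force (>= 0), vectorized.
#' @return Strain values such that `predict(curve, strain) == force`.
#' @export
strain_at_force <- function(curve, force) {
  stopifnot(all(is.finite(force)), all(force >= 0))
  f0 <- curve$a * curve$eps0^2
  ifelse(force <= f0, sqrt(force / curve$a), (force - curve$q) / curve$m)
}

#' Fit the C1 piecewise tendon curve to normalized force-strain points
#'
#' Least-squares fit of the two free parameters `(a, eps0)`; the linear-branch
#' slope and intercept follow from C1 continuity and are therefore satisfied
#' exactly rather than approximately.  For fixed `eps0` the model is linear in
#' `a`, so the fit profiles `a` out analytically and minimizes the residual
#' over `eps0` alone (coarse grid scan followed by local refinement), which is
#' robust to the kink the transition strain introduces in the objective.
#'
#' @param points a data frame or matrix with columns `strain` and `force`
#'   (normalized force).  At least 3 points with positive strain and force.
#' @param eps0_range optional search interval for the transition strain;
#'   defaults to the span of the positive strains.
#' @return A [tendon_curve()] with extra elements `rss` (residual sum of
#'   squares at the optimum) and `data` (the points used).
#' @export
fit_tendon_curve <- function(points, eps0_range = NULL) {
  pts <- as.data.frame(points)
  if (!all(c("strain", "force") %in% names(pts))) {
    colnames(pts)[1:2] <- c("strain", "force")
  }
  keep <- pts$strain > 0 & pts$force > 0
  x <- pts$strain[keep]
  y <- pts$force[keep]
  if (length(unique(x)) < 3L)
    stop_fit("need at least 3 distinct points with positive strain and force")
  ord <- order(x)
  if (all(diff(y[ord]) <= 0) || all(y == 0))
    stop_fit("degenerate input: forces are non-increasing with strain")

  # basis value for unit a at transition eps0 (model is linear in a)
  phi <- function(eps0) ifelse(x < eps0, x^2, 2 * eps0 * x - eps0^2)
  rss_at <- function(eps0) {
    p <- phi(eps0)
    a <- sum(y * p) / sum(p * p)
    if (!is.finite(a) || a <= 0) return(Inf)
    sum((y - a * p)^2)
  }
  if (is.null(eps0_range)) eps0_range <- c(min(x) * 0.05, max(x) * 1.5)
  grid <- seq(eps0_range[1], eps0_range[2], length.out = 400L)
  r <- vapply(grid, rss_at, numeric(1))
  if (!any(is.finite(r))) stop_fit("no admissible transition strain found")
  i <- which.min(r)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-12)
  eps0 <- opt$minimum
  p <- phi(eps0)
  a <- sum(y * p) / sum(p * p)
  crv <- tendon_curve(a = a, eps0 = eps0)
  crv$rss <- sum((y - a * p)^2)
  crv$data <- data.frame(strain = x, force = y)
  crv
}

#' @export
residuals.tendon_curve <- function(object, ...) {
  if (is.null(object$data)) stop("curve was not fitted to data")
  object$data$force - eval_tendon_force(object, object$data$strain)
}

#' @export
plot.tendon_curve <- function(x, ..., n = 200L) {
  smax <- if (!is.null(x$data)) max(x$data$strain) * 1.2 else 2 * x$eps0
  s <- seq(0, smax, length.out = n)
  graphics::plot(s, eval_tendon_force(x, s), type = "l",
                 xlab = "tendon strain (-)", ylab = "normalized force (-)", ...)
  if (!is.null(x$data)) graphics::points(x$data$strain, x$data$force)
  graphics::abline(v = x$eps0, lty = 3)
  invisible(x)
}

#' Normalize isometric measurements to dimensionless force-strain points
#'
#' Converts torque/elongation pairs from an isometric series to the
#' dimensionless plane of the tendon curve: strain is elongation over tendon
#' resting length, tendon force is torque over the Achilles moment arm, and
#' force is normalized by the summed triceps-surae maximum isometric force.
#'
#' @param measurements data frame with columns `level`, `torque` (N m) and
#'   `elongation` (mm), as produced by [make_isometric_series()].
#' @param profile a subject profile (needs `at_moment_arm` in m and
#'   `tendon_resting_length` in mm).
#' @param fmax_total summed triceps-surae maximum isometric force in N.
#' @return Data frame with columns `strain` and `force` (normalized).
#' @export
normalize_measurements <- function(measurements, profile, fmax_total) {
  m <- as.data.frame(measurements)
  stopifnot(all(c("torque", "elongation") %in% names(m)))
  if (!is.numeric(profile$at_moment_arm) || profile$at_moment_arm <= 0)
    stop("moment arm must be positive")
  if (profile$tendon_resting_length <= 0)
    stop("tendon resting length must be positive")
  if (fmax_total <= 0) stop("fmax_total must be positive")
  data.frame(strain = m$elongation / profile$tendon_resting_length,
             force = (m$torque / profile$at_moment_arm) / fmax_total)
}

stop_fit <- function(msg) {
  stop(errorCondition(msg, class = c("tendonstrain_fit_error", "error")))
}
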