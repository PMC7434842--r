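# Constitutive model of the free tendon: transversely isotropic hyperelastic
# with an exponential-toe / linear fiber stress and a nearly incompressible
# volumetric penalty.  Six coefficients C1..C6 plus the toe-to-linear
# transition stretch and the bulk penalty.  Units MPa unless stated.

#' Constitutive coefficients of the tendon material
#'
#' `C1` is the isotropic matrix stiffness, `C2` the second-invariant
#' (Mooney-Rivlin) coefficient (0 gives a Neo-Hookean matrix), `C3` scales
#' the exponential fiber stress in the toe region, `C4` is the rate of
#' collagen fiber loading, `C5` the linear-region fiber modulus (Young's
#' modulus scale) and `C6` the linear-region intercept.  `C6` is always
#' recomputed from the stress-continuity condition at the transition stretch
#' `lambda_star` (see [compute_C6()]), so the fiber stress is continuous by
#' construction.  `kappa` is the volumetric penalty (default 1000 C1).
#'
#' @param C1,C2,C3,C4,C5 material coefficients (MPa except dimensionless C4).
#' @param lambda_star toe-to-linear transition stretch (> 1).
#' @param kappa bulk penalty in MPa; must be at least 100 C1.
#' @return Object of class `material_coefficients`.
#' @export
material_coefficients <- function(C1, C2 = 0, C3, C4, C5,
                                  lambda_star = 1.05, kappa = 1000 * C1) {
  stopifnot(C1 > 0, C3 >= 0, C4 > 0, C5 > 0, lambda_star > 1)
  if (kappa < 100 * C1) stop("kappa must be at least 100 * C1")
  obj <- structure(list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
                        C6 = NA_real_, lambda_star = lambda_star,
                        kappa = kappa),
                   class = "material_coefficients")
  obj$C6 <- compute_C6(obj)
  obj
}

#' @export
print.material_coefficients <- function(x, ...) {
  cat("Tendon constitutive coefficients (MPa; C4 dimensionless)\n")
  cat(sprintf("  C1=%.4g C2=%.4g C3=%.4g C4=%.4g C5=%.5g C6=%.5g\n",
              x$C1, x$C2, x$C3, x$C4, x$C5, x$C6))
  cat(sprintf("  lambda* = %.4f, kappa = %.4g MPa (C5 = %.3f GPa)\n",
              x$lambda_star, x$kappa, x$C5 / 1000))
  invisible(x)
}

#' Linear-region intercept from fiber-stress continuity
#'
#' `C6 = C3 (exp(C4 (lambda* - 1)) - 1) - C5 lambda*` so the piecewise fiber
#' stress is continuous at the transition stretch.
#'
#' @param coeffs a [material_coefficients()] (or a bare list with C3, C4,
#'   C5, lambda_star).
#' @export
compute_C6 <- function(coeffs) {
  stopifnot(coeffs$lambda_star > 1)
  coeffs$C3 * (exp(coeffs$C4 * (coeffs$lambda_star - 1)) - 1) -
    coeffs$C5 * coeffs$lambda_star
}

#' Fiber stress derivative term of the strain energy
#'
#' Returns `lambda * dW_fiber/dlambda` in MPa: 0 for `lambda <= 1`, the
#' exponential toe `C3 (exp(C4 (lambda-1)) - 1)` below the transition
#' stretch, and the linear branch `C5 lambda + C6` above it.  Continuous at
#' the transition because `C6` satisfies [compute_C6()].
#'
#' @param lambda fiber stretch (vectorized, > 0).
#' @param coeffs a [material_coefficients()].
#' @export
fiber_stress_derivative <- function(lambda, coeffs) {
  stopifnot(all(lambda > 0))
  out <- numeric(length(lambda))
  toe <- lambda > 1 & lambda < coeffs$lambda_star
  lin <- lambda >= coeffs$lambda_star
  out[toe] <- coeffs$C3 * (exp(coeffs$C4 * (lambda[toe] - 1)) - 1)
  out[lin] <- coeffs$C5 * lambda[lin] + coeffs$C6
  out
}

#' Linear-region fiber modulus from isometric measurements
#'
#' The ratio between tendon stiffness (linear-region slope of tendon force
#' versus strain, from the two highest contraction levels) and the mean
#' free-tendon cross-sectional area.
#'
#' @param isometric_series data frame with `torque` (N m) and `elongation`
#'   (mm); at least 2 loaded rows.
#' @param geometry tendon geometry (uses `csa_profile` in mm^2 and `length`
#'   in mm).
#' @param moment_arm Achilles tendon moment arm in m.
#' @return C5 in GPa.
#' @export
compute_C5 <- function(isometric_series, geometry, moment_arm) {
  s <- as.data.frame(isometric_series)
  s <- s[s$torque > 0, , drop = FALSE]
  if (nrow(s) < 2L) stop("need at least 2 loaded measurements")
  s <- s[order(s$torque), ]
  force <- s$torque / moment_arm
  strain <- s$elongation / geometry$length
  if (any(diff(force) <= 0) || any(diff(strain) <= 0))
    stop("non-increasing force-strain data")
  k <- nrow(s)
  slope <- (force[k] - force[k - 1L]) / (strain[k] - strain[k - 1L])  # N per strain
  (slope / mean(geometry$csa_profile)) / 1000  # MPa -> GPa
}

# conversion utility: engineering fiber strain <-> Green-Lagrange strain
#' Convert engineering fiber strain to Green-Lagrange strain (or back)
#' @param strain strain values.
#' @param to `"green"` or `"engineering"`.
#' @export
convert_strain <- function(strain, to = c("green", "engineering")) {
  to <- match.arg(to)
  if (to == "green") 0.5 * ((1 + strain)^2 - 1) else sqrt(2 * strain + 1) - 1
}
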