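# Nonlinear FE solve of the free tendon under proximal traction:
# total-Lagrangian Newton iterations with adaptive load stepping, distal
# nodes fully constrained, force shared equally over the proximal nodes
# along the longitudinal axis of inertia.

# numeric vector handed to the compiled kernels; the 9th entry is the
# softplus smoothing width of the fiber turn-on (see src/fe_core.cpp)
FIBER_SMOOTH_DELTA <- 1e-3

coeff_vector <- function(coeffs) {
  c(coeffs$C1, coeffs$C2, coeffs$C3, coeffs$C4, coeffs$C5, coeffs$C6,
    coeffs$lambda_star, coeffs$kappa, FIBER_SMOOTH_DELTA)
}

# Incompressible homogeneous uniaxial stretch under axial force (N) on a
# reference area (mm^2): bisection on the axial Cauchy stress
# sigma = 2 C1 (lambda^2 - 1/lambda) + T(lambda), F = sigma * A / lambda.
uniaxial_stretch <- function(coeffs, area, force) {
  if (force <= 0) return(1)
  g <- function(lam)
    (2 * coeffs$C1 * (lam^2 - 1 / lam) +
       fiber_stress_derivative(lam, coeffs)) * area / lam - force
  hi <- 1.05
  while (g(hi) < 0 && hi < 16) hi <- hi * 1.5
  stats::uniroot(g, c(1, hi), tol = 1e-12)$root
}

# Slender-body displacement guess for a cold Newton start: per-layer axial
# stretch from the 1D solution at the local cross-sectional area,
# transverse contraction lambda^(-1/2), axial displacement accumulated
# along the loft, and the layer rotation that balances the untwisting
# torque of the helical fiber tension against the matrix torsional
# stiffness.  This places every Gauss point on the correct branch of the
# fiber law and near the torque-free rotation state, both of which
# otherwise stall Newton.
affine_guess <- function(mesh, coeffs, force) {
  zs <- sort(unique(mesh$nodes[, 3]))
  L <- max(zs) - min(zs)
  csa_fun <- stats::splinefun(mesh$geometry$stations,
                              mesh$geometry$csa_profile, method = "natural")
  lam <- vapply(zs, function(z)
    uniaxial_stretch(coeffs, csa_fun((z - min(zs)) / L), force), numeric(1))
  uz_lvl <- c(0, cumsum(0.5 * (lam[-1] + lam[-length(lam)] - 2) * diff(zs)))
  # torque-free rotation rate: fiber untwisting moment vs matrix torsion
  tau <- mesh$geometry$twist_total * pi / 180 / max(L, 1e-9)
  A <- csa_fun((zs - min(zs)) / L)
  Tf <- fiber_stress_derivative(pmax(lam, 1 + 1e-9), coeffs)
  S <- (Tf / lam^2) * A^2 / (2 * pi)
  psi_rate <- -tau * S / (S + 2 * coeffs$C1 * A^2 / (2 * pi))
  psi <- c(0, cumsum(0.5 * (psi_rate[-1] + psi_rate[-length(psi_rate)]) *
                       diff(zs)))
  li <- match(round(mesh$nodes[, 3], 9), round(zs, 9))
  lr <- lam[li]^-0.5
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  cp <- cos(psi[li]); sp <- sin(psi[li])
  cbind(lr * (cp * x - sp * y) - x, lr * (sp * x + cp * y) - y, uz_lvl[li])
}

#' Solve the tendon FE model at a given proximal force
#'
#' Newton iterations on the total-Lagrangian residual (analytic first
#' Piola-Kirchhoff stress, element tangents by central finite differences of
#' the residual), with load stepping and step halving on non-convergence.
#' Convergence requires the free-DOF residual norm below `tol` relative to
#' the applied load.
#'
#' @param mesh a [build_tendon_mesh()] mesh.
#' @param coeffs [material_coefficients()].
#' @param force total proximal force in N (>= 0), applied evenly over the
#'   proximal face (tributary-area nodal shares of a uniform traction)
#'   along the longitudinal axis of inertia.
#' @param u0 optional displacement warm start (matrix nodes x 3, mm).
#' @param tol relative residual tolerance.
#' @param n_steps initial number of load steps for a cold start.
#' @param max_halvings maximum load-step halvings before giving up.
#' @param maxit Newton iterations per load step.
#' @return Object of class `fe_solution`: nodal displacements `u` (mm),
#'   per-Gauss-point fiber stretch `lambda`, localized strains, `J` range,
#'   `elongation` (mm, mean longitudinal displacement of the proximal node
#'   set), `reaction` (force at the constrained distal nodes), `converged`.
#' @export
solve_fe <- function(mesh, coeffs, force, u0 = NULL, tol = 1e-8,
                     n_steps = NULL, max_halvings = 8L, maxit = 30L,
                     verbose = FALSE) {
  stopifnot(force >= 0)
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  fixed <- as.vector(outer(1:3, 3L * (mesh$distal_nodes - 1L), "+"))
  free <- setdiff(seq_len(ndof), fixed)
  fext <- numeric(ndof)
  wts <- mesh$proximal_weights
  if (is.null(wts)) wts <- rep(1 / length(mesh$proximal_nodes),
                               length(mesh$proximal_nodes))
  for (i in 1:3) {
    fext[3L * (mesh$proximal_nodes - 1L) + i] <- force * wts * mesh$axis[i]
  }
  cvec <- coeff_vector(coeffs)
  fd_h <- 1e-6 * mean(abs(diff(range(mesh$nodes[, 3]))) / max(1L, mesh$n_axial))
  u <- if (is.null(u0)) numeric(ndof) else as.numeric(t(u0))
  fnorm <- max(1, force)

  newton <- function(u, lam) {
    for (it in seq_len(maxit)) {
      asm <- fe_assemble(mesh$nodes, mesh$conn, u, mesh$dNdX, mesh$wdet,
                         mesh$a0, cvec, TRUE, fd_h)
      if (!asm$ok) return(list(ok = FALSE, u = u))
      r <- asm$fint - lam * fext
      rn <- sqrt(sum(r[free]^2))
      if (verbose) cat(sprintf("    it %d rn %.3e\n", it, rn))
      if (rn < tol * fnorm) return(list(ok = TRUE, u = u))
      K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                                dims = c(ndof, ndof))
      K <- (K + Matrix::t(K)) / 2
      du <- numeric(ndof)
      sol <- tryCatch(Matrix::solve(K[free, free], -r[free]),
                      error = function(e) NULL)
      if (is.null(sol)) return(list(ok = FALSE, u = u))
      du[free] <- as.numeric(sol)
      # line search: walk down the step ladder, keep the best residual seen
      best_rn <- Inf
      best_u <- NULL
      step <- 1
      for (bt in 1:9) {
        utry <- u + step * du
        chk <- fe_assemble(mesh$nodes, mesh$conn, utry, mesh$dNdX, mesh$wdet,
                           mesh$a0, cvec, FALSE, fd_h)
        if (chk$ok) {
          rn_try <- sqrt(sum((chk$fint - lam * fext)[free]^2))
          if (rn_try < best_rn) {
            best_rn <- rn_try
            best_u <- utry
          } else if (best_rn < rn) break
        }
        step <- step / 2
      }
      if (best_rn >= rn) return(list(ok = FALSE, u = u))
      u <- best_u
    }
    # final check
    asm <- fe_assemble(mesh$nodes, mesh$conn, u, mesh$dNdX, mesh$wdet,
                       mesh$a0, cvec, FALSE, fd_h)
    ok <- asm$ok && sqrt(sum((asm$fint - lam * fext)[free]^2)) < tol * fnorm
    list(ok = ok, u = u)
  }

  if (force == 0 && is.null(u0)) {
    u <- numeric(ndof)
  } else {
    # cold starts get an affine 1D-uniaxial initial guess (the fiber
    # tangent vanishes in the undeformed state, which otherwise stalls
    # Newton in the toe region) and attempt the full load, falling back to
    # a ramp; warm starts attempt the full load directly.  On failure the
    # current increment is halved (up to max_halvings); after two
    # consecutive successes the increment grows again.
    lam_done <- 0
    if (is.null(u0) && force > 0) {
      # the high-force (linear fiber) regime converges readily from the
      # analytic guess; low-force toe-region states are reached more
      # cheaply by descending continuation from a stiff anchor state
      lam_anchor <- coeffs$lambda_star + 0.06
      f_anchor <- (2 * coeffs$C1 * (lam_anchor^2 - 1 / lam_anchor) +
                     fiber_stress_derivative(lam_anchor, coeffs)) *
        mean(mesh$geometry$csa_profile) / lam_anchor
      if (force >= 0.8 * f_anchor) {
        ug <- as.numeric(t(affine_guess(mesh, coeffs, force)))
        ug[fixed] <- 0
        res <- newton(ug, 1)
        if (res$ok) {
          u <- res$u
          lam_done <- 1
        }
      } else {
        ug <- as.numeric(t(affine_guess(mesh, coeffs, f_anchor)))
        ug[fixed] <- 0
        res <- newton(ug, f_anchor / force)
        if (res$ok) {
          ud <- res$u
          f_cur <- f_anchor
          repeat {
            f_cur <- max(force, 0.65 * f_cur)
            res <- newton(ud, f_cur / force)
            if (!res$ok) break
            ud <- res$u
            if (f_cur <= force * (1 + 1e-12)) {
              u <- ud
              lam_done <- 1
              break
            }
          }
        }
      }
    }
    dstep0 <- min(0.25, max(if (force > 0) 250 / force else 1, 0.08))
    schedule <- if (!is.null(n_steps)) seq_len(n_steps) / n_steps
                else if (!is.null(u0)) 1
                else unique(c(seq(dstep0, 1, by = dstep0), 1))
    halved <- 0L
    i_s <- 1L
    streak <- 0L
    dstep <- NULL
    while (lam_done < 1 - 1e-12) {
      lam_try <- if (is.null(dstep)) schedule[i_s]
                 else min(1, lam_done + dstep)
      if (verbose) cat(sprintf("  load step to %.3f\n", lam_try))
      if (lam_done == 0 && all(u == 0) && force > 0) {
        ug <- as.numeric(t(affine_guess(mesh, coeffs, lam_try * force)))
        ug[fixed] <- 0
        res <- newton(ug, lam_try)
        if (!res$ok) res <- newton(u, lam_try)
      } else {
        res <- newton(u, lam_try)
      }
      if (res$ok) {
        u <- res$u
        lam_done <- lam_try
        if (is.null(dstep)) {
          i_s <- i_s + 1L
        } else {
          streak <- streak + 1L
          if (streak >= 2L) {
            dstep <- 2 * dstep
            streak <- 0L
          }
        }
      } else {
        halved <- halved + 1L
        streak <- 0L
        if (halved > max_halvings)
          stop(sprintf(
            "FE solve failed to converge at %.0f%% of the applied force (%.1f N)",
            100 * lam_try, force))
        dstep <- if (is.null(dstep)) (lam_try - lam_done) / 2 else dstep / 2
      }
    }
  }
  dg <- fe_defgrad(mesh$conn, u, mesh$dNdX, mesh$a0, mesh$wdet)
  um <- matrix(u, nn, 3L, byrow = TRUE)
  elong <- mean(um[mesh$proximal_nodes, , drop = FALSE] %*% mesh$axis)
  asm <- fe_assemble(mesh$nodes, mesh$conn, u, mesh$dNdX, mesh$wdet,
                     mesh$a0, cvec, FALSE, fd_h)
  reac <- matrix(asm$fint, nn, 3L, byrow = TRUE)[mesh$distal_nodes, , drop = FALSE]
  structure(list(u = um, lambda = dg$lambda, strains = dg$lambda - 1,
                 F = dg$F, J = dg$J, J_range = range(dg$J),
                 Jbar = dg$Jbar, Jbar_range = range(dg$Jbar),
                 elongation = elong, force = force,
                 reaction = colSums(reac), converged = TRUE),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("FE solution at %.1f N: elongation %.3f mm, strain %.4f-%.4f, J in [%.4f, %.4f]\n",
              x$force, x$elongation, min(x$strains), max(x$strains),
              x$J_range[1], x$J_range[2]))
  invisible(x)
}

#' Fiber-aligned localized strains of a converged FE solution
#'
#' Strain at each Gauss point is the fiber stretch minus one, with the
#' fiber stretch the norm of the deformation gradient applied to the
#' reference fiber direction (the material coordinate system is aligned
#' with the twisted proximal-distal fiber field).
#'
#' @param solution an `fe_solution`.
#' @return Numeric vector of engineering fiber strains, one per Gauss point.
#' @export
extract_localized_strains <- function(solution) {
  if (!isTRUE(solution$converged)) stop("solution did not converge")
  solution$strains
}

#' Inverse calibration of the constitutive coefficients
#'
#' Optimizes C1, C3 and C4 (C5 fixed, C6 refreshed from continuity at every
#' iterate, kappa kept at 1000 C1) so the FE elongation under the 70%-MVIC
#' tendon force matches the measured elongation.  Derivative-free
#' Nelder-Mead on log-parameters; each candidate is solved warm-started
#' from the previous converged state.
#'
#' @param mesh a `tendon_mesh`.
#' @param coeffs_init starting [material_coefficients()].
#' @param target_elongation measured elongation (mm) at `force`.
#' @param force tendon force (N) at which the elongation was measured
#'   (typically 70% MVIC torque over the moment arm).
#' @param maxit Nelder-Mead iteration cap.
#' @return List of class `material_calibration` with `coefficients`,
#'   `achieved_elongation`, `target`, `objective`, `evals`.
#' @export
calibrate_material <- function(mesh, coeffs_init, target_elongation, force,
                               maxit = 120L) {
  stopifnot(target_elongation > 0, force > 0)
  env <- new.env()
  env$u <- NULL
  env$evals <- 0L
  make_coeffs <- function(p) {
    material_coefficients(C1 = exp(p[1]), C2 = coeffs_init$C2,
                          C3 = exp(p[2]), C4 = exp(p[3]),
                          C5 = coeffs_init$C5,
                          lambda_star = coeffs_init$lambda_star)
  }
  fn <- function(p) {
    cf <- make_coeffs(p)
    env$evals <- env$evals + 1L
    sol <- tryCatch(
      solve_fe(mesh, cf, force, u0 = env$u),
      error = function(e) tryCatch(solve_fe(mesh, cf, force),
                                   error = function(e2) NULL))
    if (is.null(sol)) return(1e6)
    env$u <- sol$u
    (sol$elongation - target_elongation)^2
  }
  p0 <- log(c(coeffs_init$C1, coeffs_init$C3, coeffs_init$C4))
  opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  cf <- make_coeffs(opt$par)
  sol <- solve_fe(mesh, cf, force, u0 = env$u)
  structure(list(coefficients = cf, achieved_elongation = sol$elongation,
                 target = target_elongation, force = force,
                 objective = opt$value, evals = env$evals,
                 converged = opt$convergence == 0L ||
                   abs(sol$elongation - target_elongation) <
                     5e-3 * target_elongation),
            class = "material_calibration")
}

#' @export
print.material_calibration <- function(x, ...) {
  cat(sprintf(
    "Inverse FE calibration: elongation %.4f mm (target %.4f, %.2f%% off) after %d solves\n",
    x$achieved_elongation, x$target,
    100 * abs(x$achieved_elongation - x$target) / x$target, x$evals))
  print(x$coefficients)
  invisible(x)
}

#' Generate the surrogate training table by a force sweep
#'
#' Solves the FE model at forces from 0 to 200% of the MVIC tendon force at
#' 10% intervals (21 levels), warm-starting each level from the previous
#' one, and records the localized strain at every Gauss point plus the
#' global elongation per level.
#'
#' @param mesh a `tendon_mesh`.
#' @param coeffs [material_coefficients()].
#' @param mvic_tendon_force MVIC tendon force in N.
#' @param levels force levels as fractions of MVIC.
#' @return Object of class `strain_table`: `force` (N), `fraction`,
#'   `strains` (levels x Gauss points), `elongation` (mm), `n_gauss`.
#' @export
generate_training_table <- function(mesh, coeffs, mvic_tendon_force,
                                    levels = seq(0, 2, by = 0.1)) {
  stopifnot(mvic_tendon_force > 0, all(diff(levels) > 0), levels[1] >= 0)
  nlev <- length(levels)
  strains <- matrix(0, nlev, mesh$n_gauss)
  elong <- numeric(nlev)
  J_range <- matrix(rep(c(1, 1), each = nlev), nlev, 2L)
  Jbar_range <- J_range
  u <- NULL
  for (k in seq_len(nlev)) {
    f <- levels[k] * mvic_tendon_force
    if (f == 0) next
    sol <- tryCatch(solve_fe(mesh, coeffs, f, u0 = u),
                    error = function(e)
                      stop(sprintf("FE sweep failed at level %.0f%% MVIC: %s",
                                   100 * levels[k], conditionMessage(e))))
    strains[k, ] <- sol$strains
    elong[k] <- sol$elongation
    J_range[k, ] <- sol$J_range
    Jbar_range[k, ] <- sol$Jbar_range
    u <- sol$u
  }
  structure(list(force = levels * mvic_tendon_force, fraction = levels,
                 strains = strains, elongation = elong,
                 mvic_force = mvic_tendon_force, n_gauss = mesh$n_gauss,
                 J_range = J_range, Jbar_range = Jbar_range, u_top = u),
            class = "strain_table")
}

#' @export
print.strain_table <- function(x, ...) {
  cat(sprintf("Strain table: %d force levels x %d Gauss points (0-%.0f%% MVIC, MVIC force %.0f N)\n",
              length(x$force), x$n_gauss, 100 * max(x$fraction), x$mvic_force))
  cat(sprintf("  peak localized strain %.4f, peak elongation %.3f mm\n",
              max(x$strains), max(x$elongation)))
  invisible(x)
}

#' @export
plot.strain_table <- function(x, gp_sample = 64L, ...) {
  idx <- unique(round(seq(1, x$n_gauss, length.out = gp_sample)))
  graphics::matplot(x$force, x$strains[, idx], type = "l", lty = 1,
                    col = grDevices::grey(0.7), xlab = "tendon force (N)",
                    ylab = "fiber strain (-)", ...)
  invisible(x)
}

#' Write / read a strain table as delimited text
#'
#' Tab-separated with a header of Gauss-point ids; full double precision.
#' @param table a `strain_table`.
#' @param path file path.
#' @export
write_strain_table <- function(table, path) {
  df <- data.frame(force = table$force, fraction = table$fraction,
                   elongation = table$elongation)
  gp <- as.data.frame(table$strains)
  names(gp) <- sprintf("gp%04d", seq_len(ncol(gp)))
  utils::write.table(format(cbind(df, gp), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_strain_table
#' @export
read_strain_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  gp_cols <- grep("^gp", names(df))
  structure(list(force = df$force, fraction = df$fraction,
                 strains = unname(as.matrix(df[, gp_cols])),
                 elongation = df$elongation,
                 mvic_force = df$force[length(df$force)] /
                   max(df$fraction[length(df$fraction)], 1e-12),
                 n_gauss = length(gp_cols)),
            class = "strain_table")
}
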