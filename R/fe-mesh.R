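# Hexahedral mesh of the free Achilles tendon: elliptical cross-sections
# lofted along the longitudinal axis, helically twisted fiber directions.

# Map the unit square [-1,1]^2 onto the unit ellipse (elliptical grid
# mapping); the square's boundary lands exactly on the ellipse.
ellipse_map <- function(u, v) {
  cbind(u * sqrt(1 - v^2 / 2), v * sqrt(1 - u^2 / 2))
}

# Discrete area of the mapped unit-circle section for an (n+1)^2 node grid;
# semi-axes are later scaled so the *discrete* section area equals the
# target CSA (the inscribed polygon otherwise under-covers the ellipse).
section_unit_area <- function(n_section) {
  s <- seq(-1, 1, length.out = n_section + 1L)
  g <- expand.grid(u = s, v = s)
  xy <- ellipse_map(g$u, g$v)
  id <- function(iu, iv) (iv - 1L) * (n_section + 1L) + iu
  area <- 0
  for (iu in seq_len(n_section)) for (iv in seq_len(n_section)) {
    q <- rbind(xy[id(iu, iv), ], xy[id(iu + 1L, iv), ],
               xy[id(iu + 1L, iv + 1L), ], xy[id(iu, iv + 1L), ])
    area <- area + 0.5 * abs(sum(q[, 1] * q[c(2:4, 1), 2] -
                                   q[c(2:4, 1), 1] * q[, 2]))
  }
  area
}

#' Build the hexahedral free-tendon mesh
#'
#' Lofts elliptical cross-sections (area and aspect interpolated from the
#' geometry's station profile) along the longitudinal axis into trilinear
#' hexahedra with 2x2x2 Gauss quadrature.  The default 16 longitudinal by
#' 4x4 in-section elements give 256 elements and exactly 2048 Gauss points.
#' Semi-axes are scaled so each discrete section area equals the target
#' cross-sectional area.  Fiber directions are helical: aligned with the
#' longitudinal axis on it, rotated progressively so the twist accumulates
#' linearly to `twist_total` from the distal to the proximal end.
#'
#' @param geometry tendon geometry: `length` (mm), `stations` (fractions of
#'   length), `csa_profile` (mm^2), `ellipse_aspect`, `twist_total` (deg).
#' @param n_axial number of element layers along the tendon.
#' @param n_section number of elements per side of the section grid
#'   (elements per section = n_section^2).
#' @return Object of class `tendon_mesh`.
#' @export
build_tendon_mesh <- function(geometry, n_axial = 16L, n_section = 4L) {
  stopifnot(length(geometry$stations) >= 4L, all(geometry$csa_profile > 0),
            n_axial >= 1L, n_section >= 1L)
  L <- geometry$length
  csa_fun <- stats::splinefun(geometry$stations, geometry$csa_profile,
                              method = "natural")
  asp_fun <- stats::splinefun(geometry$stations, geometry$ellipse_aspect,
                              method = "natural")
  a_unit <- section_unit_area(n_section)
  s1 <- seq(-1, 1, length.out = n_section + 1L)
  sec_xy <- ellipse_map(expand.grid(u = s1, v = s1)$u,
                        expand.grid(u = s1, v = s1)$v)
  npsec <- (n_section + 1L)^2
  nodes <- matrix(0, npsec * (n_axial + 1L), 3L)
  for (l in 0:n_axial) {
    s <- l / n_axial
    csa <- csa_fun(s)
    if (csa <= 0) stop("non-positive cross-sectional area in profile")
    asp <- asp_fun(s)
    a_semi <- sqrt(csa * asp / a_unit)
    b_semi <- a_semi / asp
    rows <- l * npsec + seq_len(npsec)
    nodes[rows, 1] <- sec_xy[, 1] * a_semi
    nodes[rows, 2] <- sec_xy[, 2] * b_semi
    nodes[rows, 3] <- s * L
  }
  id <- function(l, iu, iv) l * npsec + (iv - 1L) * (n_section + 1L) + iu
  conn <- matrix(0L, n_axial * n_section^2, 8L)
  e <- 0L
  for (l in 0:(n_axial - 1L)) for (iv in seq_len(n_section)) {
    for (iu in seq_len(n_section)) {
      e <- e + 1L
      conn[e, ] <- c(id(l, iu, iv), id(l, iu + 1L, iv),
                     id(l, iu + 1L, iv + 1L), id(l, iu, iv + 1L),
                     id(l + 1L, iu, iv), id(l + 1L, iu + 1L, iv),
                     id(l + 1L, iu + 1L, iv + 1L), id(l + 1L, iu, iv + 1L))
    }
  }
  pre <- fe_precompute(nodes, conn)
  # helical reference fiber field: d/ds of a path twisting about the axis
  tau <- geometry$twist_total * pi / 180 / L
  gp <- pre$gp_pos
  fib <- cbind(-gp[, 2] * tau, gp[, 1] * tau, 1)
  fib <- fib / sqrt(rowSums(fib^2))
  a0 <- as.numeric(t(fib))  # per element: 8 gp x 3, row-major per gp
  # longitudinal axis of inertia of the reference mesh
  cn <- sweep(nodes, 2, colMeans(nodes))
  ev <- eigen(crossprod(cn), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  if (axis[3] < 0) axis <- -axis
  proximal_nodes <- which(nodes[, 3] >= L - 1e-9)
  # tributary-area nodal shares of a uniform traction on the proximal face
  wts <- numeric(length(proximal_nodes))
  pid <- function(iu, iv) (iv - 1L) * (n_section + 1L) + iu
  pxy <- nodes[proximal_nodes, 1:2, drop = FALSE]
  for (iu in seq_len(n_section)) for (iv in seq_len(n_section)) {
    q <- c(pid(iu, iv), pid(iu + 1L, iv), pid(iu + 1L, iv + 1L),
           pid(iu, iv + 1L))
    xy <- pxy[q, , drop = FALSE]
    a_q <- 0.5 * abs(sum(xy[, 1] * xy[c(2:4, 1), 2] -
                           xy[c(2:4, 1), 1] * xy[, 2]))
    wts[q] <- wts[q] + a_q / 4
  }
  wts <- wts / sum(wts)
  structure(list(nodes = nodes, conn = conn, dNdX = pre$dNdX,
                 wdet = pre$wdet, gp_pos = gp, fibers = fib, a0 = a0,
                 axis = axis, n_gauss = nrow(gp),
                 distal_nodes = which(nodes[, 3] <= 0 + 1e-9),
                 proximal_nodes = proximal_nodes,
                 proximal_weights = wts,
                 length = L, geometry = geometry,
                 n_axial = n_axial, n_section = n_section),
            class = "tendon_mesh")
}

#' @export
print.tendon_mesh <- function(x, ...) {
  cat(sprintf("Tendon mesh: %d nodes, %d hexahedra, %d Gauss points\n",
              nrow(x$nodes), nrow(x$conn), x$n_gauss))
  cat(sprintf("  length %.1f mm, twist %g deg, volume %.0f mm^3\n",
              x$length, x$geometry$twist_total, sum(mesh_element_volumes(x))))
  invisible(x)
}

#' Element volumes of a tendon mesh (mm^3)
#' @param mesh a `tendon_mesh`.
#' @export
mesh_element_volumes <- function(mesh) {
  rowSums(matrix(mesh$wdet, nrow(mesh$conn), 8L, byrow = TRUE))
}

#' Export mesh and a per-element field to legacy VTK ASCII
#'
#' Writes an unstructured-grid file viewable in ParaView; per-Gauss-point
#' strains are averaged per element and written as cell data.
#'
#' @param mesh a `tendon_mesh`.
#' @param path output file.
#' @param strains optional per-Gauss-point strain vector.
#' @param displacements optional nodal displacement matrix (mm).
#' @export
write_vtk <- function(mesh, path, strains = NULL, displacements = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$conn)
  writeLines(c("# vtk DataFile Version 3.0", "free Achilles tendon", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  utils::write.table(format(mesh$nodes, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  utils::write.table(cbind(8L, mesh$conn - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  if (!is.null(displacements)) {
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS displacement double"), con)
    utils::write.table(format(displacements, digits = 10, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  if (!is.null(strains)) {
    cell <- rowMeans(matrix(strains, ne, 8L, byrow = TRUE))
    writeLines(c(sprintf("CELL_DATA %d", ne),
                 "SCALARS fiber_strain double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(cell, digits = 10, trim = TRUE), con)
  }
  invisible(path)
}

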