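// Total-Lagrangian element kernels for the transversely isotropic
// hyperelastic free-tendon model:
//   W = C1 (I1b - 3) + C2 (I2b - 3) + W_fiber(lambda) + kappa/2 (ln J)^2
// with fiber stress derivative T(lambda) = lambda dW_f/dlambda piecewise
// exponential (toe) / linear, and a nearly incompressible volumetric
// penalty.  Trilinear hexahedra, 2x2x2 Gauss quadrature.  Element tangents
// are consistent finite differences (central) of the analytic residual.
// Units: mm, N, MPa.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GP = 0.5773502691896257;

// shape function derivatives wrt (xi, eta, zeta) at a Gauss point
static void shape_deriv(double xi, double eta, double zeta, double dN[8][3]) {
  const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a) {
    dN[a][0] = 0.125 * sx[a] * (1 + sy[a] * eta) * (1 + sz[a] * zeta);
    dN[a][1] = 0.125 * sy[a] * (1 + sx[a] * xi) * (1 + sz[a] * zeta);
    dN[a][2] = 0.125 * sz[a] * (1 + sx[a] * xi) * (1 + sy[a] * eta);
  }
}

static void shape_val(double xi, double eta, double zeta, double N[8]) {
  const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a)
    N[a] = 0.125 * (1 + sx[a] * xi) * (1 + sy[a] * eta) * (1 + sz[a] * zeta);
}

static inline double det3(const double m[9]) {
  return m[0] * (m[4] * m[8] - m[5] * m[7])
       - m[1] * (m[3] * m[8] - m[5] * m[6])
       + m[2] * (m[3] * m[7] - m[4] * m[6]);
}

static inline bool inv3(const double m[9], double inv[9]) {
  double d = det3(m);
  if (d == 0.0) return false;
  double id = 1.0 / d;
  inv[0] = (m[4] * m[8] - m[5] * m[7]) * id;
  inv[1] = (m[2] * m[7] - m[1] * m[8]) * id;
  inv[2] = (m[1] * m[5] - m[2] * m[4]) * id;
  inv[3] = (m[5] * m[6] - m[3] * m[8]) * id;
  inv[4] = (m[0] * m[8] - m[2] * m[6]) * id;
  inv[5] = (m[2] * m[3] - m[0] * m[5]) * id;
  inv[6] = (m[3] * m[7] - m[4] * m[6]) * id;
  inv[7] = (m[1] * m[6] - m[0] * m[7]) * id;
  inv[8] = (m[0] * m[4] - m[1] * m[3]) * id;
  return true;
}

// fiber stress derivative T(lambda) = lambda dW_f/dlambda.  The toe-region
// turn-on at lambda = 1 is smoothed with a softplus of width c[8] (strain
// units, ~1e-3): T = C3 (exp(C4 softplus(lambda-1)) - 1), which matches the
// exact piecewise law to machine precision a few widths away from 1 but is
// C-infinity, removing the tangent discontinuity that otherwise destroys
// Newton convergence for Gauss points crossing slack.
static inline double fiber_T(double lam, const double* c) {
  if (lam >= c[6]) return c[4] * lam + c[5];
  double x = lam - 1.0;
  double d = c[8];
  double g;
  if (d <= 0.0) {
    if (x <= 0.0) return 0.0;
    g = x;
  } else if (x > 30.0 * d) {
    g = x;
  } else if (x < -30.0 * d) {
    return 0.0;
  } else {
    g = d * std::log1p(std::exp(x / d));
  }
  return c[2] * std::expm1(c[3] * g);
}

// First Piola-Kirchhoff stress; coefficients c = (C1..C6, lambda_star,
// kappa, smoothing width).  The volumetric multiplier klj (per Gauss point)
// is supplied by the caller: the element uses a mean-dilatation (Q1P0)
// treatment, W_vol = kappa/2 (ln Jbar)^2 with Jbar the element volume
// average, which avoids the volumetric locking of fully integrated
// trilinear hexahedra.  Returns false on J <= 0.
static bool piola(const double F[9], const double a0[3], const double* c,
                  double klj, double P[9], double* Jout, double* lamout) {
  double J = det3(F);
  *Jout = J;
  if (J <= 0.0 || !std::isfinite(J)) return false;
  double Fi[9];
  inv3(F, Fi);
  double FiT[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) FiT[3 * i + j] = Fi[3 * j + i];
  double I1 = 0.0;
  for (int k = 0; k < 9; ++k) I1 += F[k] * F[k];
  double Jm23 = std::pow(J, -2.0 / 3.0);
  for (int k = 0; k < 9; ++k)
    P[k] = 2.0 * c[0] * Jm23 * (F[k] - I1 / 3.0 * FiT[k]);
  if (c[1] != 0.0) {
    double C[9] = {0};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k)
          C[3 * i + j] += F[3 * k + i] * F[3 * k + j];
    double trC2 = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) trC2 += C[3 * i + j] * C[3 * j + i];
    double I2 = 0.5 * (I1 * I1 - trC2);
    double FC[9] = {0};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k)
          FC[3 * i + j] += F[3 * i + k] * C[3 * k + j];
    double Jm43 = std::pow(J, -4.0 / 3.0);
    for (int k = 0; k < 9; ++k)
      P[k] += c[1] * Jm43 * (2.0 * I1 * F[k] - 2.0 * FC[k]
                             - 4.0 / 3.0 * I2 * FiT[k]);
  }
  for (int k = 0; k < 9; ++k) P[k] += klj * FiT[k];
  double fa[3] = {0, 0, 0};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) fa[i] += F[3 * i + j] * a0[j];
  double lam = std::sqrt(fa[0] * fa[0] + fa[1] * fa[1] + fa[2] * fa[2]);
  *lamout = lam;
  double T = fiber_T(lam, c);
  if (T != 0.0) {
    double s = T / (lam * lam);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) P[3 * i + j] += s * fa[i] * a0[j];
  }
  return true;
}

// Residual of one element: r (24) for given element displacements ue (24,
// ordered x1,y1,z1,x2,...).  dNdX: 8 gp x 8 nodes x 3, wdet: 8, a0: 8 x 3.
static bool elem_residual(const double* ue, const double* dNdX,
                          const double* wdet, const double* a0,
                          const double* c, double* r,
                          double* minJ, double* maxJ, double* lam_out) {
  for (int k = 0; k < 24; ++k) r[k] = 0.0;
  double Fall[8][9], Jg[8];
  double vol = 0.0, Jbar = 0.0;
  for (int g = 0; g < 8; ++g) {
    const double* dn = dNdX + g * 24;  // 8 nodes x 3
    double* F = Fall[g];
    for (int k = 0; k < 9; ++k) F[k] = 0.0;
    F[0] = F[4] = F[8] = 1.0;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F[3 * i + j] += ue[3 * a + i] * dn[3 * a + j];
    Jg[g] = det3(F);
    if (Jg[g] <= 0.0 || !std::isfinite(Jg[g])) return false;
    vol += wdet[g];
    Jbar += wdet[g] * Jg[g];
  }
  Jbar /= vol;
  double kl = c[7] * std::log(Jbar) / Jbar;
  for (int g = 0; g < 8; ++g) {
    const double* dn = dNdX + g * 24;
    double P[9], J, lam;
    if (!piola(Fall[g], a0 + 3 * g, c, kl * Jg[g], P, &J, &lam)) return false;
    if (minJ && J < *minJ) *minJ = J;
    if (maxJ && J > *maxJ) *maxJ = J;
    if (lam_out) lam_out[g] = lam;
    double w = wdet[g];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        r[3 * a + i] += w * (P[3 * i + 0] * dn[3 * a + 0]
                           + P[3 * i + 1] * dn[3 * a + 1]
                           + P[3 * i + 2] * dn[3 * a + 2]);
  }
  return true;
}

// [[Rcpp::export]]
List fe_precompute(NumericMatrix nodes, IntegerMatrix conn) {
  int ne = conn.nrow();
  NumericVector dNdX(ne * 8 * 8 * 3), wdet(ne * 8);
  NumericMatrix gp_pos(ne * 8, 3);
  double gp1[2] = {-GP, GP};
  for (int e = 0; e < ne; ++e) {
    double X[8][3];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) X[a][i] = nodes(conn(e, a) - 1, i);
    int g = 0;
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx, ++g) {
          double dN[8][3], N[8];
          shape_deriv(gp1[kx], gp1[ky], gp1[kz], dN);
          shape_val(gp1[kx], gp1[ky], gp1[kz], N);
          double Jm[9] = {0};  // dX/dxi
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                Jm[3 * i + j] += X[a][i] * dN[a][j];
          double Jinv[9];
          double dj = det3(Jm);
          if (dj <= 0 || !inv3(Jm, Jinv))
            stop("degenerate element %d", e + 1);
          wdet[e * 8 + g] = dj;  // unit gauss weights
          for (int a = 0; a < 8; ++a)
            for (int j = 0; j < 3; ++j) {
              double v = 0;
              for (int k = 0; k < 3; ++k) v += dN[a][k] * Jinv[3 * k + j];
              dNdX[e * 192 + g * 24 + 3 * a + j] = v;
            }
          for (int i = 0; i < 3; ++i) {
            double p = 0;
            for (int a = 0; a < 8; ++a) p += N[a] * X[a][i];
            gp_pos(e * 8 + g, i) = p;
          }
        }
  }
  return List::create(_["dNdX"] = dNdX, _["wdet"] = wdet,
                      _["gp_pos"] = gp_pos);
}

// [[Rcpp::export]]
List fe_assemble(NumericMatrix nodes, IntegerMatrix conn, NumericVector u,
                 NumericVector dNdX, NumericVector wdet, NumericVector a0,
                 NumericVector coeffs, bool tangent, double fd_h) {
  int ne = conn.nrow(), nn = nodes.nrow();
  const double* c = coeffs.begin();
  NumericVector fint(3 * nn);
  std::vector<int> Ti, Tj;
  std::vector<double> Tx;
  if (tangent) {
    Ti.reserve(ne * 576); Tj.reserve(ne * 576); Tx.reserve(ne * 576);
  }
  double minJ = 1e30, maxJ = -1e30;
  double ue[24], r0[24], rp[24], rm[24], Ke[576];
  bool ok = true;
  for (int e = 0; e < ne && ok; ++e) {
    const double* dn = dNdX.begin() + e * 192;
    const double* wd = wdet.begin() + e * 8;
    const double* fa = a0.begin() + e * 24;
    int idx[24];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        idx[3 * a + i] = 3 * (conn(e, a) - 1) + i;
        ue[3 * a + i] = u[idx[3 * a + i]];
      }
    if (!elem_residual(ue, dn, wd, fa, c, r0, &minJ, &maxJ, nullptr)) {
      ok = false; break;
    }
    for (int k = 0; k < 24; ++k) fint[idx[k]] += r0[k];
    if (tangent) {
      for (int k = 0; k < 24 && ok; ++k) {
        double sv = ue[k];
        ue[k] = sv + fd_h;
        ok = ok && elem_residual(ue, dn, wd, fa, c, rp, nullptr, nullptr, nullptr);
        ue[k] = sv - fd_h;
        ok = ok && elem_residual(ue, dn, wd, fa, c, rm, nullptr, nullptr, nullptr);
        ue[k] = sv;
        if (!ok) break;
        double ih = 0.5 / fd_h;
        for (int l = 0; l < 24; ++l) Ke[24 * l + k] = (rp[l] - rm[l]) * ih;
      }
      if (ok)
        for (int l = 0; l < 24; ++l)
          for (int k = 0; k < 24; ++k) {
            Ti.push_back(idx[l] + 1);
            Tj.push_back(idx[k] + 1);
            Tx.push_back(Ke[24 * l + k]);
          }
    }
  }
  return List::create(_["ok"] = ok, _["fint"] = fint,
                      _["minJ"] = minJ, _["maxJ"] = maxJ,
                      _["i"] = wrap(Ti), _["j"] = wrap(Tj), _["x"] = wrap(Tx));
}

// Deformation gradients, fiber stretches, per-Gauss-point J and
// element-mean Jbar (the quantity the mean-dilatation formulation
// constrains) at every Gauss point / element.
// [[Rcpp::export]]
List fe_defgrad(IntegerMatrix conn, NumericVector u, NumericVector dNdX,
                NumericVector a0, NumericVector wdet) {
  int ne = conn.nrow();
  NumericMatrix Fall(ne * 8, 9);
  NumericVector lam(ne * 8), Jv(ne * 8), Jbar(ne);
  for (int e = 0; e < ne; ++e) {
    double ue[24];
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        ue[3 * a + i] = u[3 * (conn(e, a) - 1) + i];
    for (int g = 0; g < 8; ++g) {
      const double* dn = dNdX.begin() + e * 192 + g * 24;
      double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            F[3 * i + j] += ue[3 * a + i] * dn[3 * a + j];
      const double* av = a0.begin() + e * 24 + 3 * g;
      double fa[3] = {0, 0, 0};
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) fa[i] += F[3 * i + j] * av[j];
      lam[e * 8 + g] = std::sqrt(fa[0] * fa[0] + fa[1] * fa[1] + fa[2] * fa[2]);
      Jv[e * 8 + g] = det3(F);
      for (int k = 0; k < 9; ++k) Fall(e * 8 + g, k) = F[k];
    }
    double vol = 0.0, jb = 0.0;
    for (int g = 0; g < 8; ++g) {
      vol += wdet[e * 8 + g];
      jb += wdet[e * 8 + g] * Jv[e * 8 + g];
    }
    Jbar[e] = jb / vol;
  }
  return List::create(_["F"] = Fall, _["lambda"] = lam, _["J"] = Jv,
                      _["Jbar"] = Jbar);
}
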