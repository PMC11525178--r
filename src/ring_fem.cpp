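#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Plane hyperelastic assembly for 4-node quadrilaterals with incompatible
// (enhanced) bending modes and an F-bar dilatation treatment.
//
// Formulations:
//   form = 0: plane strain, compressible neo-Hookean
//             W = mu/2 (tr C + 1 - 3) - mu ln J + lambda/2 (ln J)^2
//             with F-bar (centroid dilatation) so near-incompressible
//             bending does not volumetric-lock.
//   form = 1: plane stress, incompressible neo-Hookean (nu = 1/2):
//             W = mu/2 (tr C + J^-2 - 3), J = det F (in-plane).
//
// Each element carries four internal (incompatible-mode) parameters
// a = (p1, p2, q1, q2): an enhanced displacement gradient
//   dF_enh = (detJ0c/detJ0) * [ p (-2 xi) grad(xi)c + q (-2 eta) grad(eta)c ]
// in the classical Wilson/Taylor form, which removes the parasitic shear
// that makes bilinear quads lock in bending at high element aspect ratios.
// The internal parameters are condensed out by minimizing the element
// energy (inner Newton); by the envelope theorem the nodal residual is then
// simply the partial gradient at the inner optimum, so the assembled
// residual remains the exact gradient of a well-defined energy and external
// work balances stored energy to solver precision. Element tangents are
// forward finite differences of that residual with one warm-started inner
// correction per perturbation; they are symmetrised during assembly.

static const double GP = 0.5773502691896258; // 1/sqrt(3)
static const double XI[4] = {-GP, GP, GP, -GP};
static const double ETA[4] = {-GP, -GP, GP, GP};

static inline double det2(const double F[4]) { return F[0] * F[3] - F[1] * F[2]; }

// F stored row-major: F[0]=F11 F[1]=F12 F[2]=F21 F[3]=F22
static inline void invT2(const double F[4], double J, double FiT[4]) {
  FiT[0] =  F[3] / J; FiT[1] = -F[2] / J;
  FiT[2] = -F[1] / J; FiT[3] =  F[0] / J;
}

static void dshape(double xi, double eta, double dN[4][2]) {
  dN[0][0] = -0.25 * (1 - eta); dN[0][1] = -0.25 * (1 - xi);
  dN[1][0] =  0.25 * (1 - eta); dN[1][1] = -0.25 * (1 + xi);
  dN[2][0] =  0.25 * (1 + eta); dN[2][1] =  0.25 * (1 + xi);
  dN[3][0] = -0.25 * (1 + eta); dN[3][1] =  0.25 * (1 - xi);
}

struct ElemCtx {
  double dNdX[5][4][2]; // gp 0..3, centroid at 4
  double w[5];          // detJ0 (gauss weights are 1)
  double r1[2], r2[2];  // rows of J0c^{-1}: grad xi, grad eta at centroid
  double fsc[4];        // detJ0c / detJ0(gp)
  double h;             // characteristic element size
};

static bool ctx_setup(const double Xe[4][2], ElemCtx &c) {
  for (int q = 0; q < 5; ++q) {
    double xi = (q < 4) ? XI[q] : 0.0, eta = (q < 4) ? ETA[q] : 0.0;
    double dN[4][2];
    dshape(xi, eta, dN);
    double J0[4] = {0, 0, 0, 0};
    for (int a = 0; a < 4; ++a) {
      J0[0] += Xe[a][0] * dN[a][0]; J0[1] += Xe[a][0] * dN[a][1];
      J0[2] += Xe[a][1] * dN[a][0]; J0[3] += Xe[a][1] * dN[a][1];
    }
    double dJ = det2(J0);
    if (dJ <= 0) return false;
    double Ji[4] = { J0[3] / dJ, -J0[1] / dJ, -J0[2] / dJ, J0[0] / dJ };
    for (int a = 0; a < 4; ++a) {
      c.dNdX[q][a][0] = dN[a][0] * Ji[0] + dN[a][1] * Ji[2];
      c.dNdX[q][a][1] = dN[a][0] * Ji[1] + dN[a][1] * Ji[3];
    }
    c.w[q] = dJ;
    if (q == 4) { c.r1[0] = Ji[0]; c.r1[1] = Ji[1]; c.r2[0] = Ji[2]; c.r2[1] = Ji[3]; }
  }
  for (int q = 0; q < 4; ++q) c.fsc[q] = c.w[4] / c.w[q];
  double hsum = 0;
  for (int a = 0; a < 4; ++a) {
    int b = (a + 1) % 4;
    double dx = Xe[b][0] - Xe[a][0], dy = Xe[b][1] - Xe[a][1];
    hsum += std::sqrt(dx * dx + dy * dy);
  }
  c.h = hsum / 4.0;
  return true;
}

// total deformation gradient at gp q (0..3) or centroid (q = 4)
static void def_grad(const ElemCtx &c, int q, const double ue[4][2],
                     const double ae[4], double F[4]) {
  F[0] = 1; F[1] = 0; F[2] = 0; F[3] = 1;
  for (int a = 0; a < 4; ++a) {
    F[0] += ue[a][0] * c.dNdX[q][a][0];
    F[1] += ue[a][0] * c.dNdX[q][a][1];
    F[2] += ue[a][1] * c.dNdX[q][a][0];
    F[3] += ue[a][1] * c.dNdX[q][a][1];
  }
  if (q < 4) {
    // enhanced gradient: modes (1 - xi^2), (1 - eta^2); zero at the centroid
    double bx = c.fsc[q] * (-2.0 * XI[q]);
    double by = c.fsc[q] * (-2.0 * ETA[q]);
    F[0] += ae[0] * bx * c.r1[0] + ae[2] * by * c.r2[0];
    F[1] += ae[0] * bx * c.r1[1] + ae[2] * by * c.r2[1];
    F[2] += ae[1] * bx * c.r1[0] + ae[3] * by * c.r2[0];
    F[3] += ae[1] * bx * c.r1[1] + ae[3] * by * c.r2[1];
  }
}

// energy, nodal gradient (8) and enhanced-parameter gradient (4);
// fbar toggles the centroid-dilatation treatment (plane strain only)
static bool elem_grad(const ElemCtx &c, const double ue[4][2], const double ae[4],
                      double mu, double lam, int form, bool fbar,
                      double grad[8], double ga[4], double *energy) {
  for (int k = 0; k < 8; ++k) grad[k] = 0;
  for (int k = 0; k < 4; ++k) ga[k] = 0;
  *energy = 0;

  double Fc[4];
  def_grad(c, 4, ue, ae, Fc);
  double Jc = det2(Fc);
  if (Jc <= 0) return false;
  double FciT[4];
  invT2(Fc, Jc, FciT);

  double csum = 0;
  for (int q = 0; q < 4; ++q) {
    double F[4];
    def_grad(c, q, ue, ae, F);
    double J = det2(F);
    if (J <= 0) return false;

    double G[4], W;
    if (form == 0 && !fbar) {
      // plane strain, compressible neo-Hookean, straight integration
      double lnJ = std::log(J);
      double FiT[4];
      invT2(F, J, FiT);
      for (int k = 0; k < 4; ++k)
        G[k] = mu * (F[k] - FiT[k]) + lam * lnJ * FiT[k];
      double trC = F[0] * F[0] + F[1] * F[1] + F[2] * F[2] + F[3] * F[3];
      W = 0.5 * mu * (trC - 2.0) - mu * lnJ + 0.5 * lam * lnJ * lnJ;
    } else if (form == 0) {
      double s = std::sqrt(Jc / J);
      double Fb[4] = { s * F[0], s * F[1], s * F[2], s * F[3] };
      double FbiT[4];
      invT2(Fb, Jc, FbiT);
      double lnJ = std::log(Jc);
      double P[4], T = 0;
      for (int k = 0; k < 4; ++k) {
        P[k] = mu * (Fb[k] - FbiT[k]) + lam * lnJ * FbiT[k];
        T += P[k] * Fb[k];
      }
      double trC = Fb[0] * Fb[0] + Fb[1] * Fb[1] + Fb[2] * Fb[2] + Fb[3] * Fb[3];
      W = 0.5 * mu * (trC - 2.0) - mu * lnJ + 0.5 * lam * lnJ * lnJ;
      double FiT[4];
      invT2(F, J, FiT);
      for (int k = 0; k < 4; ++k) G[k] = s * P[k] - 0.5 * T * FiT[k];
      csum += c.w[q] * 0.5 * T;
    } else {
      double Jm2 = 1.0 / (J * J);
      double FiT[4];
      invT2(F, J, FiT);
      for (int k = 0; k < 4; ++k) G[k] = mu * (F[k] - Jm2 * FiT[k]);
      double trC = F[0] * F[0] + F[1] * F[1] + F[2] * F[2] + F[3] * F[3];
      W = 0.5 * mu * (trC + Jm2 - 3.0);
    }

    *energy += c.w[q] * W;
    for (int a = 0; a < 4; ++a) {
      grad[2 * a]     += c.w[q] * (G[0] * c.dNdX[q][a][0] + G[1] * c.dNdX[q][a][1]);
      grad[2 * a + 1] += c.w[q] * (G[2] * c.dNdX[q][a][0] + G[3] * c.dNdX[q][a][1]);
    }
    double bx = c.fsc[q] * (-2.0 * XI[q]);
    double by = c.fsc[q] * (-2.0 * ETA[q]);
    ga[0] += c.w[q] * bx * (G[0] * c.r1[0] + G[1] * c.r1[1]);
    ga[1] += c.w[q] * bx * (G[2] * c.r1[0] + G[3] * c.r1[1]);
    ga[2] += c.w[q] * by * (G[0] * c.r2[0] + G[1] * c.r2[1]);
    ga[3] += c.w[q] * by * (G[2] * c.r2[0] + G[3] * c.r2[1]);
  }

  if (form == 0 && fbar && csum != 0) {
    for (int a = 0; a < 4; ++a) {
      grad[2 * a]     += csum * (FciT[0] * c.dNdX[4][a][0] + FciT[1] * c.dNdX[4][a][1]);
      grad[2 * a + 1] += csum * (FciT[2] * c.dNdX[4][a][0] + FciT[3] * c.dNdX[4][a][1]);
    }
    // enhanced modes vanish at the centroid: no Fc term for ga
  }
  return true;
}

// analytic material tangent A_{iJkL} for the non-F-bar forms, evaluated
// at F; returns false on inverted state. Both potentials give a symmetric
// Hessian: A = mu I + c1 T (x) T + c2 (T_iL T_kJ), T = F^{-T}.
static bool mat_tangent(const double F[4], double mu, double lam, int form,
                        double A[2][2][2][2]) {
  double J = det2(F);
  if (J <= 0) return false;
  double T[2][2]; // F^{-T}
  {
    double FiT[4];
    invT2(F, J, FiT);
    T[0][0] = FiT[0]; T[0][1] = FiT[1]; T[1][0] = FiT[2]; T[1][1] = FiT[3];
  }
  double c1, c2;
  if (form == 0) {
    double lnJ = std::log(J);
    c1 = lam;
    c2 = mu - lam * lnJ;
  } else {
    double Jm2 = 1.0 / (J * J);
    c1 = 2.0 * mu * Jm2;
    c2 = mu * Jm2;
  }
  for (int i = 0; i < 2; ++i)
    for (int Jj = 0; Jj < 2; ++Jj)
      for (int k = 0; k < 2; ++k)
        for (int L = 0; L < 2; ++L)
          A[i][Jj][k][L] = mu * (i == k) * (Jj == L) +
            c1 * T[i][Jj] * T[k][L] + c2 * T[i][L] * T[k][Jj];
  return true;
}

// generalized dof -> (component, gradient vector at gp q)
// m 0..7: nodal dof, vector = dNdX; m 8..11: enhanced p1,p2,q1,q2
static inline void dof_vec(const ElemCtx &c, int q, int m, int *comp, double v[2]) {
  if (m < 8) {
    *comp = m % 2;
    v[0] = c.dNdX[q][m / 2][0];
    v[1] = c.dNdX[q][m / 2][1];
  } else {
    int k = m - 8;
    *comp = k % 2;
    if (k < 2) {
      double bx = c.fsc[q] * (-2.0 * XI[q]);
      v[0] = bx * c.r1[0]; v[1] = bx * c.r1[1];
    } else {
      double by = c.fsc[q] * (-2.0 * ETA[q]);
      v[0] = by * c.r2[0]; v[1] = by * c.r2[1];
    }
  }
}

// exact 12x12 element Hessian (nodal + enhanced) for the non-F-bar forms
static bool elem_hessian(const ElemCtx &c, const double ue[4][2],
                         const double ae[4], double mu, double lam, int form,
                         double H[12][12]) {
  for (int r = 0; r < 12; ++r)
    for (int k = 0; k < 12; ++k) H[r][k] = 0;
  for (int q = 0; q < 4; ++q) {
    double F[4];
    def_grad(c, q, ue, ae, F);
    double A[2][2][2][2];
    if (!mat_tangent(F, mu, lam, form, A)) return false;
    int cm[12];
    double vm[12][2];
    for (int m = 0; m < 12; ++m) dof_vec(c, q, m, &cm[m], vm[m]);
    for (int r = 0; r < 12; ++r)
      for (int k = r; k < 12; ++k) {
        double s = 0;
        for (int Jj = 0; Jj < 2; ++Jj)
          for (int L = 0; L < 2; ++L)
            s += vm[r][Jj] * A[cm[r]][Jj][cm[k]][L] * vm[k][L];
        H[r][k] += c.w[q] * s;
      }
  }
  for (int r = 0; r < 12; ++r)
    for (int k = 0; k < r; ++k) H[r][k] = H[k][r];
  return true;
}

static bool solve4(double A[4][4], double b[4]) {
  // Gaussian elimination with partial pivoting
  int idx[4] = {0, 1, 2, 3};
  for (int col = 0; col < 4; ++col) {
    int piv = col;
    for (int r = col + 1; r < 4; ++r)
      if (std::fabs(A[idx[r]][col]) > std::fabs(A[idx[piv]][col])) piv = r;
    std::swap(idx[col], idx[piv]);
    double d = A[idx[col]][col];
    if (std::fabs(d) < 1e-300) return false;
    for (int r = col + 1; r < 4; ++r) {
      double f = A[idx[r]][col] / d;
      for (int cc = col; cc < 4; ++cc) A[idx[r]][cc] -= f * A[idx[col]][cc];
      b[idx[r]] -= f * b[idx[col]];
    }
  }
  double x[4];
  for (int col = 3; col >= 0; --col) {
    double s = b[idx[col]];
    for (int cc = col + 1; cc < 4; ++cc) s -= A[idx[col]][cc] * x[cc];
    x[col] = s / A[idx[col]][col];
  }
  for (int k = 0; k < 4; ++k) b[k] = x[k];
  return true;
}

// minimise element energy over the enhanced parameters (inner Newton);
// max_it = 1 gives the warm-started correction used inside FD tangents
static bool inner_solve(const ElemCtx &c, const double ue[4][2], double ae[4],
                        double mu, double lam, int form, bool fbar,
                        int max_it, double tol) {
  double g8[8], ga[4], W;
  double ha = 1e-7 * c.h;
  for (int it = 0; it < max_it; ++it) {
    if (!elem_grad(c, ue, ae, mu, lam, form, fbar, g8, ga, &W)) return false;
    double nrm = std::sqrt(ga[0] * ga[0] + ga[1] * ga[1] + ga[2] * ga[2] + ga[3] * ga[3]);
    if (nrm < tol) return true;
    double H[4][4];
    if (!fbar) {
      double H12[12][12];
      if (!elem_hessian(c, ue, ae, mu, lam, form, H12)) return false;
      for (int r = 0; r < 4; ++r)
        for (int k = 0; k < 4; ++k) H[r][k] = H12[8 + r][8 + k];
    } else {
      double gp[4], g8d[8], Wd;
      for (int k = 0; k < 4; ++k) {
        double ap[4] = { ae[0], ae[1], ae[2], ae[3] };
        ap[k] += ha;
        if (!elem_grad(c, ue, ap, mu, lam, form, fbar, g8d, gp, &Wd)) return false;
        for (int r = 0; r < 4; ++r) H[r][k] = (gp[r] - ga[r]) / ha;
      }
    }
    double rhs[4] = { -ga[0], -ga[1], -ga[2], -ga[3] };
    if (!solve4(H, rhs)) return false;
    // cap the step and backtrack out of element inversion (the lambda ln J
    // term is strongly nonlinear near incompressibility)
    double sn = std::sqrt(rhs[0] * rhs[0] + rhs[1] * rhs[1] +
                          rhs[2] * rhs[2] + rhs[3] * rhs[3]);
    double cap = 0.2 * c.h;
    if (sn > cap) for (int k = 0; k < 4; ++k) rhs[k] *= cap / sn;
    double at[4];
    double step = 1.0;
    bool ok = false;
    for (int ls = 0; ls < 12; ++ls) {
      for (int k = 0; k < 4; ++k) at[k] = ae[k] + step * rhs[k];
      if (elem_grad(c, ue, at, mu, lam, form, fbar, g8, ga, &W)) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) return false;
    for (int k = 0; k < 4; ++k) ae[k] = at[k];
  }
  // accept after max_it corrections (FD-perturbation path)
  return true;
}

// [[Rcpp::export]]
List fem_assemble(NumericMatrix X, IntegerMatrix conn, NumericVector u,
                  NumericMatrix amat, double mu, double lambda, int form,
                  bool tangent, bool enhanced = true, bool fbar = false) {
  const int nn = X.nrow();
  const int ne = conn.nrow();
  NumericVector res(2 * nn);
  double energy = 0;

  IntegerVector ii, jj;
  NumericVector vv;
  if (tangent) {
    ii = IntegerVector(ne * 64);
    jj = IntegerVector(ne * 64);
    vv = NumericVector(ne * 64);
  }

  for (int e = 0; e < ne; ++e) {
    int nd[4];
    double Xe[4][2], ue[4][2], ae[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = conn(e, a) - 1;
      Xe[a][0] = X(nd[a], 0); Xe[a][1] = X(nd[a], 1);
      ue[a][0] = u[2 * nd[a]]; ue[a][1] = u[2 * nd[a] + 1];
      ae[a] = amat(e, a);
    }
    if (!enhanced) ae[0] = ae[1] = ae[2] = ae[3] = 0;

    ElemCtx c;
    if (!ctx_setup(Xe, c))
      stop("degenerate element %d", e + 1);
    double tol_a = 1e-12 * (mu + lambda) * c.h;

    if (enhanced && !inner_solve(c, ue, ae, mu, lambda, form, fbar, 25, tol_a))
      stop("inverted element %d during internal-mode condensation", e + 1);

    double g0[8], ga0[4], Ee;
    if (!elem_grad(c, ue, ae, mu, lambda, form, fbar, g0, ga0, &Ee))
      stop("inverted element %d during assembly", e + 1);
    energy += Ee;
    for (int a = 0; a < 4; ++a) {
      res[2 * nd[a]]     += g0[2 * a];
      res[2 * nd[a] + 1] += g0[2 * a + 1];
    }
    if (enhanced) for (int k = 0; k < 4; ++k) amat(e, k) = ae[k];

    if (tangent) {
      // full 12x12 FD Hessian at (u, a*), then static condensation of the
      // internal modes: Ke = Kuu - Kua Kaa^-1 Kau (consistent EAS tangent)
      double H[12][12];
      if (!fbar) {
        if (!elem_hessian(c, ue, ae, mu, lambda, form, H))
          stop("inverted element %d during tangent", e + 1);
      } else {
        double up[4][2], ap[4], g1[8], ga1[4], Edum;
        double h = 1e-7 * c.h;
        for (int k = 0; k < 12; ++k) {
          for (int a = 0; a < 4; ++a) { up[a][0] = ue[a][0]; up[a][1] = ue[a][1]; }
          for (int a = 0; a < 4; ++a) ap[a] = ae[a];
          if (k < 8) up[k / 2][k % 2] += h; else ap[k - 8] += h;
          if (!elem_grad(c, up, ap, mu, lambda, form, fbar, g1, ga1, &Edum))
            stop("inverted element %d during tangent FD", e + 1);
          for (int r = 0; r < 8; ++r) H[r][k] = (g1[r] - g0[r]) / h;
          for (int r = 0; r < 4; ++r) H[8 + r][k] = (ga1[r] - ga0[r]) / h;
        }
        for (int r = 0; r < 12; ++r)
          for (int k = r + 1; k < 12; ++k) {
            double v = 0.5 * (H[r][k] + H[k][r]);
            H[r][k] = v; H[k][r] = v;
          }
      }
      double Ke[8][8];
      for (int r = 0; r < 8; ++r)
        for (int k = 0; k < 8; ++k) Ke[r][k] = H[r][k];
      if (enhanced) {
        // X = Kaa^{-1} Kau, column by column
        double Xc[4][8];
        for (int col = 0; col < 8; ++col) {
          double A[4][4], b[4];
          for (int r = 0; r < 4; ++r) {
            b[r] = H[8 + r][col];
            for (int k = 0; k < 4; ++k) A[r][k] = H[8 + r][8 + k];
          }
          if (!solve4(A, b))
            stop("singular internal-mode block in element %d", e + 1);
          for (int r = 0; r < 4; ++r) Xc[r][col] = b[r];
        }
        for (int r = 0; r < 8; ++r)
          for (int k = 0; k < 8; ++k)
            for (int m = 0; m < 4; ++m) Ke[r][k] -= H[r][8 + m] * Xc[m][k];
      }
      int base = e * 64, cnt = 0;
      for (int r = 0; r < 8; ++r) {
        int gi = 2 * nd[r / 2] + (r % 2);
        for (int k = 0; k < 8; ++k) {
          int gj = 2 * nd[k / 2] + (k % 2);
          ii[base + cnt] = gi + 1;
          jj[base + cnt] = gj + 1;
          vv[base + cnt] = 0.5 * (Ke[r][k] + Ke[k][r]);
          ++cnt;
        }
      }
    }
  }

  if (tangent)
    return List::create(_["residual"] = res, _["energy"] = energy,
                        _["i"] = ii, _["j"] = jj, _["v"] = vv);
  return List::create(_["residual"] = res, _["energy"] = energy);
}
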