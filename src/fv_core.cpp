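// Finite-volume core for the quasi-static volume conductor problem
// and the Hessian activation-function field.
//
// Grids are column-major (R array layout), spacing in meters inside
// this file. sigma = 0 marks insulator/exterior voxels: they carry no
// unknowns and their faces transmit no flux (natural zero-flux walls).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double harm(double a, double b) {
  // harmonic-mean face conductivity; zero if either side is insulating
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

struct Stencil {
  int n1, n2, n3;
  R_xlen_t n;
  // face conductances (S): Gx between (i,j,k) and (i+1,j,k), etc.
  std::vector<double> Gx, Gy, Gz;
  std::vector<double> diag;     // row diagonal over all cells (0 where not free)
  std::vector<char> free_;      // 1 = unknown
  std::vector<char> fixed_;     // 1 = Dirichlet
};

static void assemble(const NumericVector& sigma, const IntegerVector& dirich,
                     const NumericVector& spacing, Stencil& S) {
  IntegerVector dm = sigma.attr("dim");
  S.n1 = dm[0]; S.n2 = dm[1]; S.n3 = dm[2];
  S.n = (R_xlen_t)S.n1 * S.n2 * S.n3;
  const double h1 = spacing[0], h2 = spacing[1], h3 = spacing[2];
  const double ax = h2 * h3 / h1, ay = h1 * h3 / h2, az = h1 * h2 / h3;
  S.Gx.assign(S.n, 0.0); S.Gy.assign(S.n, 0.0); S.Gz.assign(S.n, 0.0);
  S.diag.assign(S.n, 0.0);
  S.free_.assign(S.n, 0); S.fixed_.assign(S.n, 0);
  const double* sg = REAL(sigma);
  for (R_xlen_t p = 0; p < S.n; ++p) {
    if (sg[p] > 0.0) {
      if (dirich[p] != 0) S.fixed_[p] = 1; else S.free_[p] = 1;
    }
  }
  const R_xlen_t s1 = 1, s2 = S.n1, s3 = (R_xlen_t)S.n1 * S.n2;
  for (int k = 0; k < S.n3; ++k)
    for (int j = 0; j < S.n2; ++j)
      for (int i = 0; i < S.n1; ++i) {
        R_xlen_t p = i + (R_xlen_t)S.n1 * (j + (R_xlen_t)S.n2 * k);
        if (i + 1 < S.n1) S.Gx[p] = harm(sg[p], sg[p + s1]) * ax;
        if (j + 1 < S.n2) S.Gy[p] = harm(sg[p], sg[p + s2]) * ay;
        if (k + 1 < S.n3) S.Gz[p] = harm(sg[p], sg[p + s3]) * az;
      }
  // diagonal = sum of face conductances to conductive neighbours
  for (int k = 0; k < S.n3; ++k)
    for (int j = 0; j < S.n2; ++j)
      for (int i = 0; i < S.n1; ++i) {
        R_xlen_t p = i + (R_xlen_t)S.n1 * (j + (R_xlen_t)S.n2 * k);
        if (!S.free_[p]) continue;
        double d = 0.0;
        if (i + 1 < S.n1) d += S.Gx[p];
        if (i > 0)        d += S.Gx[p - s1];
        if (j + 1 < S.n2) d += S.Gy[p];
        if (j > 0)        d += S.Gy[p - s2];
        if (k + 1 < S.n3) d += S.Gz[p];
        if (k > 0)        d += S.Gz[p - s3];
        S.diag[p] = d;
      }
}

// Compact CSR-like view over free cells only: neighbors split into
// lower (compact index < row, lex order) and upper halves so the same
// structure drives the matvec and the IC(0) triangular sweeps.
struct Compact {
  R_xlen_t nfree;
  std::vector<R_xlen_t> full_of;        // compact -> full index
  std::vector<double> diag;             // A diagonal
  std::vector<int> lo_ptr, up_ptr;      // CSR row pointers (nfree+1)
  std::vector<int> lo_idx, up_idx;      // compact column indices
  std::vector<double> lo_val, up_val;   // face conductances G (A off-diag = -G)
};

static void build_compact(const Stencil& S, Compact& C) {
  std::vector<int> comp(S.n, -1);
  C.full_of.clear();
  for (R_xlen_t p = 0; p < S.n; ++p)
    if (S.free_[p]) { comp[p] = (int)C.full_of.size(); C.full_of.push_back(p); }
  C.nfree = (R_xlen_t)C.full_of.size();
  C.diag.resize(C.nfree);
  C.lo_ptr.assign(C.nfree + 1, 0);
  C.up_ptr.assign(C.nfree + 1, 0);
  const R_xlen_t s1 = 1, s2 = S.n1, s3 = (R_xlen_t)S.n1 * S.n2;
  // count then fill
  std::vector<int> lo_fill, up_fill;
  for (int pass = 0; pass < 2; ++pass) {
    if (pass == 1) {
      for (R_xlen_t r = 0; r < C.nfree; ++r) {
        C.lo_ptr[r + 1] += C.lo_ptr[r];
        C.up_ptr[r + 1] += C.up_ptr[r];
      }
      C.lo_idx.assign(C.lo_ptr[C.nfree], 0); C.lo_val.assign(C.lo_ptr[C.nfree], 0.0);
      C.up_idx.assign(C.up_ptr[C.nfree], 0); C.up_val.assign(C.up_ptr[C.nfree], 0.0);
      lo_fill.assign(C.nfree, 0); up_fill.assign(C.nfree, 0);
    }
    for (R_xlen_t r = 0; r < C.nfree; ++r) {
      R_xlen_t p = C.full_of[r];
      int i = (int)(p % S.n1);
      int j = (int)((p / S.n1) % S.n2);
      int k = (int)(p / ((R_xlen_t)S.n1 * S.n2));
      if (pass == 1) C.diag[r] = S.diag[p];
      struct Nb { R_xlen_t q; double g; };
      Nb nbs[6]; int nn = 0;
      if (i > 0        && S.free_[p - s1]) nbs[nn++] = {p - s1, S.Gx[p - s1]};
      if (j > 0        && S.free_[p - s2]) nbs[nn++] = {p - s2, S.Gy[p - s2]};
      if (k > 0        && S.free_[p - s3]) nbs[nn++] = {p - s3, S.Gz[p - s3]};
      if (i + 1 < S.n1 && S.free_[p + s1]) nbs[nn++] = {p + s1, S.Gx[p]};
      if (j + 1 < S.n2 && S.free_[p + s2]) nbs[nn++] = {p + s2, S.Gy[p]};
      if (k + 1 < S.n3 && S.free_[p + s3]) nbs[nn++] = {p + s3, S.Gz[p]};
      for (int t = 0; t < nn; ++t) {
        bool lower = nbs[t].q < p;
        if (pass == 0) {
          if (lower) C.lo_ptr[r + 1]++; else C.up_ptr[r + 1]++;
        } else {
          int c = comp[nbs[t].q];
          if (lower) {
            int at = C.lo_ptr[r] + lo_fill[(size_t)r]++;
            C.lo_idx[at] = c; C.lo_val[at] = nbs[t].g;
          } else {
            int at = C.up_ptr[r] + up_fill[(size_t)r]++;
            C.up_idx[at] = c; C.up_val[at] = nbs[t].g;
          }
        }
      }
    }
  }
}

static void matvec_c(const Compact& C, const std::vector<double>& x,
                     std::vector<double>& y) {
  for (R_xlen_t r = 0; r < C.nfree; ++r) {
    double v = C.diag[r] * x[r];
    for (int t = C.lo_ptr[r]; t < C.lo_ptr[r + 1]; ++t)
      v -= C.lo_val[t] * x[C.lo_idx[t]];
    for (int t = C.up_ptr[r]; t < C.up_ptr[r + 1]; ++t)
      v -= C.up_val[t] * x[C.up_idx[t]];
    y[r] = v;
  }
}

// Modified IC(0) (Gustafsson diagonal compensation, relaxation omega):
// dropped fill between the upper neighbours of each eliminated row is
// folded back into their diagonals. omega = 0 gives plain IC(0).
static void mic0_factor_c(const Compact& C, double omega,
                          std::vector<double>& d) {
  d.assign(C.nfree, 0.0);
  std::vector<double> compn(C.nfree, 0.0);
  for (R_xlen_t r = 0; r < C.nfree; ++r) {
    double v = C.diag[r] - compn[r];
    for (int t = C.lo_ptr[r]; t < C.lo_ptr[r + 1]; ++t) {
      double g = C.lo_val[t];
      v -= g * g / d[C.lo_idx[t]];
    }
    if (v < 1e-10 * C.diag[r]) v = 1e-10 * C.diag[r];  // breakdown guard
    d[r] = v;
    if (omega > 0.0) {
      int a = C.up_ptr[r], b = C.up_ptr[r + 1];
      for (int t1 = a; t1 < b; ++t1)
        for (int t2 = t1 + 1; t2 < b; ++t2) {
          double f = omega * C.up_val[t1] * C.up_val[t2] / v;
          compn[C.up_idx[t1]] += f;
          compn[C.up_idx[t2]] += f;
        }
    }
  }
}

static void ic0_apply_c(const Compact& C, const std::vector<double>& d,
                        const std::vector<double>& r, std::vector<double>& z) {
  // forward: (D + L) w = r
  for (R_xlen_t i = 0; i < C.nfree; ++i) {
    double v = r[i];
    for (int t = C.lo_ptr[i]; t < C.lo_ptr[i + 1]; ++t)
      v += C.lo_val[t] * z[C.lo_idx[t]];
    z[i] = v / d[i];
  }
  // backward: (D + L^T) z = D w
  for (R_xlen_t i = C.nfree - 1; i >= 0; --i) {
    double v = 0.0;
    for (int t = C.up_ptr[i]; t < C.up_ptr[i + 1]; ++t)
      v += C.up_val[t] * z[C.up_idx[t]];
    z[i] += v / d[i];
  }
}

// [[Rcpp::export]]
List cpp_solve_fv(NumericVector sigma, IntegerVector dirich,
                  NumericVector dvals, NumericVector spacing,
                  double tol, int maxit, Nullable<NumericVector> x0) {
  Stencil S;
  assemble(sigma, dirich, spacing, S);
  const R_xlen_t s1 = 1, s2 = S.n1, s3 = (R_xlen_t)S.n1 * S.n2;

  // rhs from Dirichlet neighbours
  std::vector<double> b(S.n, 0.0), x(S.n, 0.0);
  for (int k = 0; k < S.n3; ++k)
    for (int j = 0; j < S.n2; ++j)
      for (int i = 0; i < S.n1; ++i) {
        R_xlen_t p = i + (R_xlen_t)S.n1 * (j + (R_xlen_t)S.n2 * k);
        if (!S.free_[p]) continue;
        double v = 0.0;
        if (i + 1 < S.n1 && S.fixed_[p + s1]) v += S.Gx[p] * dvals[p + s1];
        if (i > 0        && S.fixed_[p - s1]) v += S.Gx[p - s1] * dvals[p - s1];
        if (j + 1 < S.n2 && S.fixed_[p + s2]) v += S.Gy[p] * dvals[p + s2];
        if (j > 0        && S.fixed_[p - s2]) v += S.Gy[p - s2] * dvals[p - s2];
        if (k + 1 < S.n3 && S.fixed_[p + s3]) v += S.Gz[p] * dvals[p + s3];
        if (k > 0        && S.fixed_[p - s3]) v += S.Gz[p - s3] * dvals[p - s3];
        b[p] = v;
      }
  Compact C;
  build_compact(S, C);
  const R_xlen_t nf = C.nfree;
  std::vector<double> xc(nf, 0.0), bc(nf);
  for (R_xlen_t r = 0; r < nf; ++r) bc[r] = b[C.full_of[r]];
  if (x0.isNotNull()) {
    NumericVector xs(x0);
    for (R_xlen_t r = 0; r < nf; ++r) {
      double v = xs[C.full_of[r]];
      xc[r] = R_finite(v) ? v : 0.0;
    }
  }

  auto dotc = [nf](const std::vector<double>& a, const std::vector<double>& b2) {
    double s = 0.0;
    for (R_xlen_t i = 0; i < nf; ++i) s += a[i] * b2[i];
    return s;
  };

  double bnorm = std::sqrt(dotc(bc, bc));
  int iters = 0;
  double relres = 0.0;
  bool converged = true;
  if (bnorm > 0.0 && nf > 0) {
    std::vector<double> d;
    mic0_factor_c(C, 0.95, d);
    std::vector<double> r(nf), z(nf), pvec(nf), Ap(nf);
    matvec_c(C, xc, Ap);
    for (R_xlen_t i = 0; i < nf; ++i) r[i] = bc[i] - Ap[i];
    ic0_apply_c(C, d, r, z);
    pvec = z;
    double rz = dotc(r, z);
    relres = std::sqrt(dotc(r, r)) / bnorm;
    converged = relres <= tol;
    while (!converged && iters < maxit) {
      matvec_c(C, pvec, Ap);
      double pAp = dotc(pvec, Ap);
      if (pAp <= 0.0) break;  // singular / indefinite guard
      double alpha = rz / pAp;
      for (R_xlen_t i = 0; i < nf; ++i) {
        xc[i] += alpha * pvec[i];
        r[i] -= alpha * Ap[i];
      }
      ++iters;
      relres = std::sqrt(dotc(r, r)) / bnorm;
      if (relres <= tol) { converged = true; break; }
      ic0_apply_c(C, d, r, z);
      double rz_new = dotc(r, z);
      double beta = rz_new / rz;
      rz = rz_new;
      for (R_xlen_t i = 0; i < nf; ++i) pvec[i] = z[i] + beta * pvec[i];
    }
  }

  NumericVector phi(S.n);
  phi.attr("dim") = sigma.attr("dim");
  for (R_xlen_t p = 0; p < S.n; ++p) {
    if (S.fixed_[p]) phi[p] = dvals[p];
    else phi[p] = NA_REAL;  // insulator / excluded
  }
  for (R_xlen_t r = 0; r < nf; ++r) phi[C.full_of[r]] = xc[r];
  return List::create(_["phi"] = phi, _["iterations"] = iters,
                      _["relres"] = relres, _["converged"] = converged);
}

// Net current (A) leaving `region` through faces to conductive cells
// outside it. phi may contain NA at insulator cells (no flux there).
// [[Rcpp::export]]
double cpp_region_flux(NumericVector sigma, NumericVector phi,
                       IntegerVector region, NumericVector spacing) {
  IntegerVector dm = sigma.attr("dim");
  int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  const double h1 = spacing[0], h2 = spacing[1], h3 = spacing[2];
  const double ax = h2 * h3 / h1, ay = h1 * h3 / h2, az = h1 * h2 / h3;
  const double* sg = REAL(sigma);
  const double* ph = REAL(phi);
  double I = 0.0;
  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t p = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (!region[p] || sg[p] <= 0.0) continue;
        if (i + 1 < n1 && !region[p + s1] && sg[p + s1] > 0.0)
          I += harm(sg[p], sg[p + s1]) * ax * (ph[p] - ph[p + s1]);
        if (i > 0 && !region[p - s1] && sg[p - s1] > 0.0)
          I += harm(sg[p], sg[p - s1]) * ax * (ph[p] - ph[p - s1]);
        if (j + 1 < n2 && !region[p + s2] && sg[p + s2] > 0.0)
          I += harm(sg[p], sg[p + s2]) * ay * (ph[p] - ph[p + s2]);
        if (j > 0 && !region[p - s2] && sg[p - s2] > 0.0)
          I += harm(sg[p], sg[p - s2]) * ay * (ph[p] - ph[p - s2]);
        if (k + 1 < n3 && !region[p + s3] && sg[p + s3] > 0.0)
          I += harm(sg[p], sg[p + s3]) * az * (ph[p] - ph[p + s3]);
        if (k > 0 && !region[p - s3] && sg[p - s3] > 0.0)
          I += harm(sg[p], sg[p - s3]) * az * (ph[p] - ph[p - s3]);
      }
  return I;
}

// Algebraically largest eigenvalue of the symmetric 3x3 matrix
// [[a,d,e],[d,b,f],[e,f,c]] (trigonometric closed form).
static inline double sym3_lambda1(double a, double b, double c,
                                  double d, double e, double f) {
  double p1 = d * d + e * e + f * f;
  if (p1 == 0.0) return std::max(a, std::max(b, c));
  double q = (a + b + c) / 3.0;
  double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // r = det(B)/2 with B = (A - qI)/p
  double ba = (a - q) / p, bb = (b - q) / p, bc = (c - q) / p;
  double bd = d / p, be = e / p, bf = f / p;
  double detB = ba * (bb * bc - bf * bf) - bd * (bd * bc - bf * be)
              + be * (bd * bf - bb * be);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  return q + 2.0 * p * std::cos(std::acos(r) / 3.0);
}

// Primary (algebraically largest) Hessian eigenvalue per node via
// second-order central differences on a uniform grid (spacing h, m).
// One-node border and any node whose 19-point stencil touches a
// non-finite value are returned as NA.
// [[Rcpp::export]]
NumericVector cpp_hessian_lambda1(NumericVector phi, double h) {
  IntegerVector dm = phi.attr("dim");
  int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  const double* f = REAL(phi);
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n, NA_REAL);
  out.attr("dim") = phi.attr("dim");
  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;
  const double ih2 = 1.0 / (h * h), iq = 1.0 / (4.0 * h * h);
  for (int k = 1; k < n3 - 1; ++k)
    for (int j = 1; j < n2 - 1; ++j)
      for (int i = 1; i < n1 - 1; ++i) {
        R_xlen_t p = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        double c0 = f[p];
        double xm = f[p - s1], xp = f[p + s1];
        double ym = f[p - s2], yp = f[p + s2];
        double zm = f[p - s3], zp = f[p + s3];
        double xpyp = f[p + s1 + s2], xpym = f[p + s1 - s2];
        double xmyp = f[p - s1 + s2], xmym = f[p - s1 - s2];
        double xpzp = f[p + s1 + s3], xpzm = f[p + s1 - s3];
        double xmzp = f[p - s1 + s3], xmzm = f[p - s1 - s3];
        double ypzp = f[p + s2 + s3], ypzm = f[p + s2 - s3];
        double ymzp = f[p - s2 + s3], ymzm = f[p - s2 - s3];
        double vals[19] = {c0, xm, xp, ym, yp, zm, zp, xpyp, xpym, xmyp, xmym,
                           xpzp, xpzm, xmzp, xmzm, ypzp, ypzm, ymzp, ymzm};
        bool ok = true;
        for (int t = 0; t < 19; ++t) if (!R_finite(vals[t])) { ok = false; break; }
        if (!ok) continue;
        double hxx = (xp - 2.0 * c0 + xm) * ih2;
        double hyy = (yp - 2.0 * c0 + ym) * ih2;
        double hzz = (zp - 2.0 * c0 + zm) * ih2;
        double hxy = (xpyp - xpym - xmyp + xmym) * iq;
        double hxz = (xpzp - xpzm - xmzp + xmzm) * iq;
        double hyz = (ypzp - ypzm - ymzp + ymzm) * iq;
        out[p] = sym3_lambda1(hxx, hyy, hzz, hxy, hxz, hyz);
      }
  return out;
}

// Trilinear resampling of src (column-major, origin/spacing in mm)
// onto a destination grid. Points outside the source hull -> NA.
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector src,
                                     NumericVector src_origin,
                                     NumericVector src_spacing,
                                     IntegerVector dst_dim,
                                     NumericVector dst_origin,
                                     NumericVector dst_spacing) {
  IntegerVector dm = src.attr("dim");
  int m1 = dm[0], m2 = dm[1], m3 = dm[2];
  int n1 = dst_dim[0], n2 = dst_dim[1], n3 = dst_dim[2];
  const double* f = REAL(src);
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  out.attr("dim") = dst_dim;
  const R_xlen_t s1 = 1, s2 = m1, s3 = (R_xlen_t)m1 * m2;
  R_xlen_t q = 0;
  for (int k = 0; k < n3; ++k) {
    double wz = dst_origin[2] + k * dst_spacing[2];
    double gz = (wz - src_origin[2]) / src_spacing[2];
    for (int j = 0; j < n2; ++j) {
      double wy = dst_origin[1] + j * dst_spacing[1];
      double gy = (wy - src_origin[1]) / src_spacing[1];
      for (int i = 0; i < n1; ++i, ++q) {
        double wx = dst_origin[0] + i * dst_spacing[0];
        double gx = (wx - src_origin[0]) / src_spacing[0];
        const double eps = 1e-9;
        if (gx < -eps || gy < -eps || gz < -eps ||
            gx > m1 - 1 + eps || gy > m2 - 1 + eps || gz > m3 - 1 + eps) {
          out[q] = NA_REAL;
          continue;
        }
        double cx = std::min(std::max(gx, 0.0), (double)(m1 - 1));
        double cy = std::min(std::max(gy, 0.0), (double)(m2 - 1));
        double cz = std::min(std::max(gz, 0.0), (double)(m3 - 1));
        int i0 = std::max(0, std::min((int)cx, m1 - 2));
        int j0 = std::max(0, std::min((int)cy, m2 - 2));
        int k0 = std::max(0, std::min((int)cz, m3 - 2));
        R_xlen_t d1 = (m1 > 1) ? s1 : 0;
        R_xlen_t d2 = (m2 > 1) ? s2 : 0;
        R_xlen_t d3 = (m3 > 1) ? s3 : 0;
        double tx = cx - i0, ty = cy - j0, tz = cz - k0;
        R_xlen_t p0 = i0 + (R_xlen_t)m1 * (j0 + (R_xlen_t)m2 * k0);
        double c000 = f[p0],            c100 = f[p0 + d1];
        double c010 = f[p0 + d2],       c110 = f[p0 + d1 + d2];
        double c001 = f[p0 + d3],       c101 = f[p0 + d1 + d3];
        double c011 = f[p0 + d2 + d3],  c111 = f[p0 + d1 + d2 + d3];
        double c00 = c000 * (1 - tx) + c100 * tx;
        double c10 = c010 * (1 - tx) + c110 * tx;
        double c01 = c001 * (1 - tx) + c101 * tx;
        double c11 = c011 * (1 - tx) + c111 * tx;
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[q] = c0 * (1 - tz) + c1 * tz;
      }
    }
  }
  return out;
}
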