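#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 3D Delaunay tessellation (Bowyer-Watson, incremental insertion with
// circumsphere caching) plus point location and barycentric weights.
// Callers are expected to pass points in generic position; the R wrapper
// applies a deterministic sub-voxel jitter to grid-aligned pseudo-points.

namespace {

struct Tet {
  int v[4];
  double cc[3];   // circumcenter
  double r2;      // squared circumradius
  bool alive;
};

// circumsphere of p0..p3; returns false when the tetrahedron is degenerate
bool circumsphere(const double* P, int a, int b, int c, int d,
                  double* cc, double& r2) {
  const double* p0 = P + 3 * a;
  double A[3][3], rhs[3];
  const int idx[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    const double* pi = P + 3 * idx[i];
    double n2 = 0.0;
    for (int j = 0; j < 3; ++j) {
      A[i][j] = 2.0 * (pi[j] - p0[j]);
      n2 += pi[j] * pi[j] - p0[j] * p0[j];
    }
    rhs[i] = n2;
  }
  // Gaussian elimination with partial pivoting on the 3x3 system
  int perm[3] = {0, 1, 2};
  for (int col = 0; col < 3; ++col) {
    int piv = col;
    for (int r = col + 1; r < 3; ++r)
      if (std::fabs(A[r][col]) > std::fabs(A[piv][col])) piv = r;
    if (std::fabs(A[piv][col]) < 1e-300) return false;
    if (piv != col) {
      for (int j = 0; j < 3; ++j) std::swap(A[col][j], A[piv][j]);
      std::swap(rhs[col], rhs[piv]);
      std::swap(perm[col], perm[piv]);
    }
    for (int r = col + 1; r < 3; ++r) {
      double f = A[r][col] / A[col][col];
      for (int j = col; j < 3; ++j) A[r][j] -= f * A[col][j];
      rhs[r] -= f * rhs[col];
    }
  }
  for (int col = 2; col >= 0; --col) {
    double s = rhs[col];
    for (int j = col + 1; j < 3; ++j) s -= A[col][j] * cc[j];
    if (std::fabs(A[col][col]) < 1e-300) return false;
    cc[col] = s / A[col][col];
  }
  r2 = 0.0;
  for (int j = 0; j < 3; ++j) {
    double dj = cc[j] - p0[j];
    r2 += dj * dj;
  }
  return std::isfinite(r2);
}

inline double dist2(const double* p, const double* q) {
  double s = 0.0;
  for (int j = 0; j < 3; ++j) { double d = p[j] - q[j]; s += d * d; }
  return s;
}

struct Facet {
  int a, b, c;  // sorted vertex ids
  bool operator<(const Facet& o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

Facet make_facet(int x, int y, int z) {
  if (x > y) std::swap(x, y);
  if (y > z) std::swap(y, z);
  if (x > y) std::swap(x, y);
  Facet f; f.a = x; f.b = y; f.c = z; return f;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_delaunay")]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");

  // working copy with 4 super-tetrahedron vertices appended
  std::vector<double> P(3 * (n + 4));
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) {
    lo[j] = std::numeric_limits<double>::infinity();
    hi[j] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j);
      if (!std::isfinite(v)) stop("non-finite coordinate");
      P[3 * i + j] = v;
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  double ctr[3], span = 1.0;
  for (int j = 0; j < 3; ++j) {
    ctr[j] = 0.5 * (lo[j] + hi[j]);
    span = std::max(span, hi[j] - lo[j]);
  }
  const double L = 64.0 * span;
  const double sup[4][3] = {
    { 0.0,  0.0,  3.0}, {-2.5, -1.5, -1.0}, { 2.5, -1.5, -1.0}, { 0.0,  2.5, -1.0}
  };
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 3; ++j)
      P[3 * (n + k) + j] = ctr[j] + L * sup[k][j];

  std::vector<Tet> tets;
  tets.reserve(16 * n);
  {
    Tet t0;
    for (int k = 0; k < 4; ++k) t0.v[k] = n + k;
    if (!circumsphere(P.data(), t0.v[0], t0.v[1], t0.v[2], t0.v[3], t0.cc, t0.r2))
      stop("super-tetrahedron construction failed");
    t0.alive = true;
    tets.push_back(t0);
  }

  std::vector<int> bad;
  std::map<Facet, int> fcount;
  for (int i = 0; i < n; ++i) {
    const double* pi = P.data() + 3 * i;
    bad.clear();
    for (int t = 0; t < (int)tets.size(); ++t) {
      if (!tets[t].alive) continue;
      if (dist2(pi, tets[t].cc) < tets[t].r2) bad.push_back(t);
    }
    if (bad.empty())
      stop("point insertion failed (no containing circumsphere); points may be degenerate - jitter them");
    fcount.clear();
    for (int bi : bad) {
      const int* v = tets[bi].v;
      fcount[make_facet(v[0], v[1], v[2])]++;
      fcount[make_facet(v[0], v[1], v[3])]++;
      fcount[make_facet(v[0], v[2], v[3])]++;
      fcount[make_facet(v[1], v[2], v[3])]++;
      tets[bi].alive = false;
    }
    for (std::map<Facet, int>::const_iterator it = fcount.begin();
         it != fcount.end(); ++it) {
      if (it->second != 1) continue;  // interior facet of the cavity
      Tet nt;
      nt.v[0] = it->first.a; nt.v[1] = it->first.b; nt.v[2] = it->first.c; nt.v[3] = i;
      if (!circumsphere(P.data(), nt.v[0], nt.v[1], nt.v[2], nt.v[3], nt.cc, nt.r2))
        stop("degenerate tetrahedron encountered; jitter the input points");
      nt.alive = true;
      tets.push_back(nt);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tets.size(); ++t)
    if (tets[t].alive && tets[t].v[0] < n && tets[t].v[1] < n &&
        tets[t].v[2] < n && tets[t].v[3] < n) ++m;
  IntegerMatrix out(m, 4);
  int r = 0;
  for (size_t t = 0; t < tets.size(); ++t) {
    const Tet& tt = tets[t];
    if (!tt.alive || tt.v[0] >= n || tt.v[1] >= n || tt.v[2] >= n || tt.v[3] >= n)
      continue;
    for (int k = 0; k < 4; ++k) out(r, k) = tt.v[k] + 1;  // 1-based for R
    ++r;
  }
  return out;
}

namespace {

// solve M w = (q, 1) where M columns are the homogeneous simplex vertices;
// returns false if the 4x4 system is numerically singular
bool bary_solve(const double* P, const int* v, const double* q, double* w,
                double detTol) {
  double A[4][5];
  for (int k = 0; k < 4; ++k) {
    const double* p = P + 3 * v[k];
    for (int j = 0; j < 3; ++j) A[j][k] = p[j];
    A[3][k] = 1.0;
  }
  for (int j = 0; j < 3; ++j) A[j][4] = q[j];
  A[3][4] = 1.0;
  double det = 1.0;
  for (int col = 0; col < 4; ++col) {
    int piv = col;
    for (int r = col + 1; r < 4; ++r)
      if (std::fabs(A[r][col]) > std::fabs(A[piv][col])) piv = r;
    if (piv != col) {
      for (int j = 0; j < 5; ++j) std::swap(A[col][j], A[piv][j]);
      det = -det;
    }
    det *= A[col][col];
    if (std::fabs(A[col][col]) < detTol) return false;
    for (int r = col + 1; r < 4; ++r) {
      double f = A[r][col] / A[col][col];
      for (int j = col; j < 5; ++j) A[r][j] -= f * A[col][j];
    }
  }
  for (int col = 3; col >= 0; --col) {
    double s = A[col][4];
    for (int j = col + 1; j < 4; ++j) s -= A[col][j] * w[j];
    w[col] = s / A[col][col];
  }
  return true;
}

}  // namespace

// Locate each query in the tessellation of the (jittered) points and return
// barycentric weights computed from the original coordinates, falling back
// to the jittered coordinates when the original simplex is near-degenerate.
// [[Rcpp::export(name = ".cpp_interp_weights")]]
List cpp_interp_weights(NumericMatrix orig, NumericMatrix jit,
                        IntegerMatrix simplices, NumericMatrix queries,
                        double tol) {
  const int n = orig.nrow(), m = simplices.nrow(), nq = queries.nrow();
  if (jit.nrow() != n) stop("point set size mismatch");
  std::vector<double> PO(3 * n), PJ(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      PO[3 * i + j] = orig(i, j);
      PJ[3 * i + j] = jit(i, j);
    }
  std::vector<int> S(4 * m);
  std::vector<double> bb(6 * m);
  for (int t = 0; t < m; ++t) {
    for (int k = 0; k < 4; ++k) S[4 * t + k] = simplices(t, k) - 1;
    for (int j = 0; j < 3; ++j) {
      double mn = std::numeric_limits<double>::infinity(), mx = -mn;
      for (int k = 0; k < 4; ++k) {
        double v = PJ[3 * S[4 * t + k] + j];
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      bb[6 * t + 2 * j] = mn - tol - 1e-9;
      bb[6 * t + 2 * j + 1] = mx + tol + 1e-9;
    }
  }
  IntegerVector simp(nq);
  IntegerMatrix vidx(nq, 4);
  NumericMatrix W(nq, 4);
  double q[3], w[4];
  const double detTol = 1e-12;
  for (int iq = 0; iq < nq; ++iq) {
    for (int j = 0; j < 3; ++j) q[j] = queries(iq, j);
    int found = -1;
    for (int t = 0; t < m; ++t) {
      bool inbb = true;
      for (int j = 0; j < 3; ++j)
        if (q[j] < bb[6 * t + 2 * j] || q[j] > bb[6 * t + 2 * j + 1]) { inbb = false; break; }
      if (!inbb) continue;
      if (!bary_solve(PJ.data(), &S[4 * t], q, w, detTol)) continue;
      if (w[0] >= -tol && w[1] >= -tol && w[2] >= -tol && w[3] >= -tol) {
        found = t;
        break;
      }
    }
    if (found < 0) {
      simp[iq] = NA_INTEGER;
      for (int k = 0; k < 4; ++k) { vidx(iq, k) = NA_INTEGER; W(iq, k) = NA_REAL; }
      continue;
    }
    // weights from the original coordinates keep the interpolant exact on
    // affine fields; jittered coordinates are only a location device
    double wo[4];
    if (!bary_solve(PO.data(), &S[4 * found], q, wo, detTol))
      for (int k = 0; k < 4; ++k) wo[k] = w[k];
    simp[iq] = found + 1;
    for (int k = 0; k < 4; ++k) {
      vidx(iq, k) = S[4 * found + k] + 1;
      W(iq, k) = wo[k];
    }
  }
  return List::create(_["simplex"] = simp, _["vertices"] = vidx, _["weights"] = W);
}

// nearest point (squared Euclidean), ties broken by lowest index
// [[Rcpp::export(name = ".cpp_nearest")]]
IntegerVector cpp_nearest(NumericMatrix pts, NumericMatrix queries) {
  const int n = pts.nrow(), nq = queries.nrow();
  if (n == 0) stop("empty point set");
  IntegerVector out(nq);
  for (int iq = 0; iq < nq; ++iq) {
    double best = std::numeric_limits<double>::infinity();
    int bi = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < 3; ++j) {
        double d = pts(i, j) - queries(iq, j);
        s += d * d;
      }
      if (i == 0 || s < best - 1e-12 * (1.0 + best)) { best = s; bi = i; }
    }
    out[iq] = bi + 1;
  }
  return out;
}
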