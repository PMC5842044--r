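// Compiled geometry kernels: closest point on a triangulated surface
// (uniform-grid accelerated) and the locally-affine-deformation (LAD)
// iteration loop. Everything here is resolution-critical inner-loop code;
// all user-facing validation happens on the R side.
// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// closest point on a single triangle (Ericson, Real-Time Collision Detection)
// fills out[3] with the foot point and bary[3] with barycentric coords
// ---------------------------------------------------------------------------
static inline void closest_on_triangle(const double* a, const double* b,
                                       const double* c, const double* p,
                                       double* out, double* bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v*ab[i];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w*ac[i];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w*(c[i] - b[i]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

static inline double sqdist3(const double* a, const double* b) {
  double d0 = a[0]-b[0], d1 = a[1]-b[1], d2 = a[2]-b[2];
  return d0*d0 + d1*d1 + d2*d2;
}

// ---------------------------------------------------------------------------
// uniform grid over a triangle mesh
// ---------------------------------------------------------------------------
struct TriGrid {
  arma::mat V;              // vertices (V x 3)
  arma::Mat<int> F;         // faces (F x 3, 0-based)
  double lo[3];
  double cell;
  int n[3];
  std::vector<std::vector<int>> vcell;   // vertex ids per cell
  std::vector<std::vector<int>> tcell;   // triangle ids per cell
  std::vector<std::vector<int>> vtri;    // incident triangles per vertex
  arma::mat tlo, thi;                    // triangle bounding boxes
  std::vector<int> stamp;                // dedupe scratch
  int stamp_id;

  int cidx(int ix, int iy, int iz) const {
    return (iz * n[1] + iy) * n[0] + ix;
  }
  void coord(const double* p, int* ci) const {
    for (int a = 0; a < 3; ++a) {
      int k = (int)std::floor((p[a] - lo[a]) / cell);
      if (k < 0) k = 0;
      if (k >= n[a]) k = n[a] - 1;
      ci[a] = k;
    }
  }
};

TriGrid* as_grid(SEXP ptr) {
  Rcpp::XPtr<TriGrid> xp(ptr);
  return xp.get();
}

// [[Rcpp::export(name = ".cpp_grid_build")]]
SEXP cpp_grid_build(const arma::mat& V, const arma::Mat<int>& F) {
  TriGrid* g = new TriGrid();
  g->V = V;
  g->F = F;
  const int nv = (int)V.n_rows, nf = (int)F.n_rows;
  double hi[3];
  for (int a = 0; a < 3; ++a) {
    g->lo[a] = V.col(a).min();
    hi[a]    = V.col(a).max();
  }
  // mean edge length sets the cell size; clamp grid to <= 64 cells per axis
  double esum = 0.0; int ecount = 0;
  for (int f = 0; f < nf; ++f) {
    for (int e = 0; e < 3; ++e) {
      int i = F(f, e), j = F(f, (e + 1) % 3);
      esum += std::sqrt((V(i,0)-V(j,0))*(V(i,0)-V(j,0)) +
                        (V(i,1)-V(j,1))*(V(i,1)-V(j,1)) +
                        (V(i,2)-V(j,2))*(V(i,2)-V(j,2)));
      ++ecount;
    }
  }
  double medge = ecount > 0 ? esum / ecount : 1.0;
  double maxext = 1e-9;
  for (int a = 0; a < 3; ++a) maxext = std::max(maxext, hi[a] - g->lo[a]);
  double cell = std::max(medge, maxext / 64.0);
  if (!(cell > 0.0) || !std::isfinite(cell)) cell = 1.0;
  g->cell = cell;
  long ncell = 1;
  for (int a = 0; a < 3; ++a) {
    int k = (int)std::floor((hi[a] - g->lo[a]) / cell) + 1;
    if (k < 1) k = 1;
    g->n[a] = k;
    ncell *= k;
  }
  g->vcell.resize(ncell);
  g->tcell.resize(ncell);
  g->stamp.assign(nf, -1);
  g->stamp_id = 0;
  for (int i = 0; i < nv; ++i) {
    double p[3] = { V(i,0), V(i,1), V(i,2) };
    int ci[3];
    g->coord(p, ci);
    g->vcell[g->cidx(ci[0], ci[1], ci[2])].push_back(i);
  }
  g->vtri.resize(nv);
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e) g->vtri[F(f, e)].push_back(f);
  g->tlo.set_size(nf, 3);
  g->thi.set_size(nf, 3);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f,0), i1 = F(f,1), i2 = F(f,2);
    for (int a = 0; a < 3; ++a) {
      double l = std::min(V(i0,a), std::min(V(i1,a), V(i2,a)));
      double h = std::max(V(i0,a), std::max(V(i1,a), V(i2,a)));
      g->tlo(f,a) = l;
      g->thi(f,a) = h;
    }
    double plo[3] = { g->tlo(f,0), g->tlo(f,1), g->tlo(f,2) };
    double phi[3] = { g->thi(f,0), g->thi(f,1), g->thi(f,2) };
    int cl[3], ch[3];
    g->coord(plo, cl);
    g->coord(phi, ch);
    for (int iz = cl[2]; iz <= ch[2]; ++iz)
      for (int iy = cl[1]; iy <= ch[1]; ++iy)
        for (int ix = cl[0]; ix <= ch[0]; ++ix)
          g->tcell[g->cidx(ix, iy, iz)].push_back(f);
  }
  Rcpp::XPtr<TriGrid> xp(g, true);
  return xp;
}

// nearest vertex to q; returns index, sets best squared distance
static int grid_nearest_vertex(TriGrid* g, const double* q, double& best2) {
  double cq[3];
  for (int a = 0; a < 3; ++a) {
    cq[a] = q[a];
    double hi = g->lo[a] + g->n[a] * g->cell;
    if (cq[a] < g->lo[a]) cq[a] = g->lo[a];
    if (cq[a] > hi) cq[a] = hi;
  }
  double dq = std::sqrt(sqdist3(q, cq));
  int c0[3];
  g->coord(q, c0);
  best2 = std::numeric_limits<double>::infinity();
  int best = -1;
  int smax = std::max(g->n[0], std::max(g->n[1], g->n[2]));
  for (int s = 0; s <= smax; ++s) {
    double ring_lb = (s - 1) * g->cell - dq;
    if (best >= 0 && ring_lb > 0 && ring_lb * ring_lb > best2) break;
    int xlo = std::max(0, c0[0]-s), xhi = std::min(g->n[0]-1, c0[0]+s);
    int ylo = std::max(0, c0[1]-s), yhi = std::min(g->n[1]-1, c0[1]+s);
    int zlo = std::max(0, c0[2]-s), zhi = std::min(g->n[2]-1, c0[2]+s);
    for (int iz = zlo; iz <= zhi; ++iz)
      for (int iy = ylo; iy <= yhi; ++iy)
        for (int ix = xlo; ix <= xhi; ++ix) {
          // only the shell at Chebyshev distance s
          int cd = std::max(std::abs(ix-c0[0]),
                   std::max(std::abs(iy-c0[1]), std::abs(iz-c0[2])));
          if (cd != s) continue;
          const std::vector<int>& ids = g->vcell[g->cidx(ix,iy,iz)];
          for (size_t u = 0; u < ids.size(); ++u) {
            int i = ids[u];
            double p[3] = { g->V(i,0), g->V(i,1), g->V(i,2) };
            double d2 = sqdist3(q, p);
            if (d2 < best2) { best2 = d2; best = i; }
          }
        }
  }
  return best;
}

// closest point on the surface to q
static void grid_closest_one(TriGrid* g, const double* q,
                             int& face, double* bary, double* foot,
                             double& dist) {
  double best2;
  int bv = grid_nearest_vertex(g, q, best2);
  face = -1;
  // seed with the nearest vertex's one-ring: nearly always contains the true
  // foot point, making the subsequent pruned sweep cheap even for far queries
  ++g->stamp_id;
  if (bv >= 0) {
    double out0[3], bc0[3];
    const std::vector<int>& ring = g->vtri[bv];
    for (size_t u = 0; u < ring.size(); ++u) {
      int f = ring[u];
      g->stamp[f] = g->stamp_id;
      int i0 = g->F(f,0), i1 = g->F(f,1), i2 = g->F(f,2);
      double A[3] = { g->V(i0,0), g->V(i0,1), g->V(i0,2) };
      double B[3] = { g->V(i1,0), g->V(i1,1), g->V(i1,2) };
      double C[3] = { g->V(i2,0), g->V(i2,1), g->V(i2,2) };
      closest_on_triangle(A, B, C, q, out0, bc0);
      double d2 = sqdist3(q, out0);
      if (d2 < best2 || face < 0) {
        best2 = d2;
        face = f;
        for (int a = 0; a < 3; ++a) { foot[a] = out0[a]; bary[a] = bc0[a]; }
      }
    }
  }
  double r = std::sqrt(best2) * (1.0 + 1e-12) + 1e-12;
  double qlo[3], qhi[3];
  for (int a = 0; a < 3; ++a) { qlo[a] = q[a] - r; qhi[a] = q[a] + r; }
  int cl[3], ch[3];
  g->coord(qlo, cl);
  g->coord(qhi, ch);
  double out[3], bc[3];
  for (int iz = cl[2]; iz <= ch[2]; ++iz)
    for (int iy = cl[1]; iy <= ch[1]; ++iy)
      for (int ix = cl[0]; ix <= ch[0]; ++ix) {
        // reject whole cells farther than the current best
        double clb = 0.0;
        int ci[3] = { ix, iy, iz };
        for (int a = 0; a < 3; ++a) {
          double lo = g->lo[a] + ci[a] * g->cell;
          double d = 0.0;
          if (q[a] < lo) d = lo - q[a];
          else if (q[a] > lo + g->cell) d = q[a] - (lo + g->cell);
          clb += d * d;
        }
        if (clb >= best2) continue;
        const std::vector<int>& ids = g->tcell[g->cidx(ix,iy,iz)];
        for (size_t u = 0; u < ids.size(); ++u) {
          int f = ids[u];
          if (g->stamp[f] == g->stamp_id) continue;
          g->stamp[f] = g->stamp_id;
          // quick reject on the triangle's bounding box
          double lb = 0.0;
          for (int a = 0; a < 3; ++a) {
            double d = 0.0;
            if (q[a] < g->tlo(f,a)) d = g->tlo(f,a) - q[a];
            else if (q[a] > g->thi(f,a)) d = q[a] - g->thi(f,a);
            lb += d*d;
          }
          if (lb >= best2) continue;
          int i0 = g->F(f,0), i1 = g->F(f,1), i2 = g->F(f,2);
          double A[3] = { g->V(i0,0), g->V(i0,1), g->V(i0,2) };
          double B[3] = { g->V(i1,0), g->V(i1,1), g->V(i1,2) };
          double C[3] = { g->V(i2,0), g->V(i2,1), g->V(i2,2) };
          closest_on_triangle(A, B, C, q, out, bc);
          double d2 = sqdist3(q, out);
          if (d2 < best2 || face < 0) {
            best2 = d2;
            face = f;
            for (int a = 0; a < 3; ++a) { foot[a] = out[a]; bary[a] = bc[a]; }
          }
        }
      }
  if (face < 0) {
    // fell through (nearest vertex isolated in its cell range): brute force
    double bb = std::numeric_limits<double>::infinity();
    for (int f = 0; f < (int)g->F.n_rows; ++f) {
      int i0 = g->F(f,0), i1 = g->F(f,1), i2 = g->F(f,2);
      double A[3] = { g->V(i0,0), g->V(i0,1), g->V(i0,2) };
      double B[3] = { g->V(i1,0), g->V(i1,1), g->V(i1,2) };
      double C[3] = { g->V(i2,0), g->V(i2,1), g->V(i2,2) };
      closest_on_triangle(A, B, C, q, out, bc);
      double d2 = sqdist3(q, out);
      if (d2 < bb) {
        bb = d2;
        face = f;
        for (int a = 0; a < 3; ++a) { foot[a] = out[a]; bary[a] = bc[a]; }
      }
    }
    best2 = bb;
  }
  dist = std::sqrt(best2);
  (void)bv;
}

// [[Rcpp::export(name = ".cpp_grid_closest")]]
List cpp_grid_closest(SEXP ptr, const arma::mat& Q) {
  TriGrid* g = as_grid(ptr);
  const int n = (int)Q.n_rows;
  IntegerVector face(n);
  NumericMatrix bary(n, 3), foot(n, 3);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = { Q(i,0), Q(i,1), Q(i,2) };
    int f;
    double bc[3], ft[3], d;
    grid_closest_one(g, q, f, bc, ft, d);
    face[i] = f + 1;  // 1-based for R
    for (int a = 0; a < 3; ++a) { bary(i,a) = bc[a]; foot(i,a) = ft[a]; }
    dist[i] = d;
  }
  return List::create(_["face"] = face, _["bary"] = bary,
                      _["point"] = foot, _["distance"] = dist);
}

// all target vertices within `radius` of q (used by texture-driven pairing)
static void grid_vertices_within(TriGrid* g, const double* q, double radius,
                                 std::vector<int>& out) {
  out.clear();
  double qlo[3], qhi[3];
  for (int a = 0; a < 3; ++a) { qlo[a] = q[a] - radius; qhi[a] = q[a] + radius; }
  int cl[3], ch[3];
  g->coord(qlo, cl);
  g->coord(qhi, ch);
  double r2 = radius * radius;
  for (int iz = cl[2]; iz <= ch[2]; ++iz)
    for (int iy = cl[1]; iy <= ch[1]; ++iy)
      for (int ix = cl[0]; ix <= ch[0]; ++ix) {
        const std::vector<int>& ids = g->vcell[g->cidx(ix,iy,iz)];
        for (size_t u = 0; u < ids.size(); ++u) {
          int i = ids[u];
          double p[3] = { g->V(i,0), g->V(i,1), g->V(i,2) };
          if (sqdist3(q, p) <= r2) out.push_back(i);
        }
      }
}

// cyclic Jacobi eigendecomposition of a symmetric 3x3 matrix A:
// A = V diag(e) V', eigenvalues descending
static void eig_sym3(const double A[3][3], double V[3][3], double e[3]) {
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) { a[i][j] = A[i][j]; V[i][j] = (i == j); }
  for (int sweep = 0; sweep < 30; ++sweep) {
    double off = a[0][1]*a[0][1] + a[0][2]*a[0][2] + a[1][2]*a[1][2];
    if (off < 1e-30) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double tsign = theta >= 0 ? 1.0 : -1.0;
        double tt = tsign / (std::fabs(theta) + std::sqrt(theta*theta + 1.0));
        double c = 1.0 / std::sqrt(tt*tt + 1.0), s = tt * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c*akp - s*akq;
          a[k][q] = s*akp + c*akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c*apk - s*aqk;
          a[q][k] = s*apk + c*aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c*vkp - s*vkq;
          V[k][q] = s*vkp + c*vkq;
        }
      }
  }
  for (int i = 0; i < 3; ++i) e[i] = a[i][i];
  // sort descending
  int ord[3] = {0, 1, 2};
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (e[ord[j]] > e[ord[i]]) std::swap(ord[i], ord[j]);
  double e2[3], V2[3][3];
  for (int j = 0; j < 3; ++j) {
    e2[j] = e[ord[j]];
    for (int i = 0; i < 3; ++i) V2[i][j] = V[i][ord[j]];
  }
  for (int j = 0; j < 3; ++j) e[j] = e2[j];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) V[i][j] = V2[i][j];
}

// weighted Kabsch fit mapping points X[idx] onto P[idx]; returns false and a
// pure translation when the neighbourhood is (near-)collinear.
// R, t are written as row-major double arrays.
static bool kabsch_fit(const double* Xp, const double* Pp, int nv,
                       const std::vector<int>& idx, const double* w,
                       double R[3][3], double t[3]) {
  const int m = (int)idx.size();
  double W = 0.0, xc[3] = {0, 0, 0}, pc[3] = {0, 0, 0};
  // X, P are column-major nv x 3
  for (int u = 0; u < m; ++u) {
    int i = idx[u];
    double wi = w[u];
    W += wi;
    for (int a = 0; a < 3; ++a) {
      xc[a] += wi * Xp[i + a*nv];
      pc[a] += wi * Pp[i + a*nv];
    }
  }
  for (int a = 0; a < 3; ++a) { xc[a] /= W; pc[a] /= W; }
  double H[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
  for (int u = 0; u < m; ++u) {
    int i = idx[u];
    double wi = w[u];
    double dx[3], dp[3];
    for (int a = 0; a < 3; ++a) {
      dx[a] = Xp[i + a*nv] - xc[a];
      dp[a] = Pp[i + a*nv] - pc[a];
    }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        H[a][b] += wi * dx[a] * dp[b];
  }
  // svd via eigendecomposition of H'H: H = U S V', H'H = V S^2 V'
  double HtH[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += H[k][a] * H[k][b];
      HtH[a][b] = s;
    }
  double V[3][3], e[3];
  eig_sym3(HtH, V, e);
  double s0 = std::sqrt(std::max(e[0], 0.0));
  double s1 = std::sqrt(std::max(e[1], 0.0));
  if (m < 3 || s0 <= 0.0 || s1 < 1e-9 * s0) {
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) R[a][b] = (a == b);
    for (int a = 0; a < 3; ++a) t[a] = pc[a] - xc[a];
    return false;
  }
  // U = H V S^{-1}; guard the smallest singular value by orthogonality
  double U[3][3];
  for (int j = 0; j < 2; ++j) {
    double sj = std::sqrt(std::max(e[j], 1e-300));
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += H[i][k] * V[k][j];
      U[i][j] = s / sj;
    }
  }
  // third columns by cross product: U and V become proper rotations, which
  // absorbs any reflection into the signed third singular value; the
  // det-constrained optimum is then simply R = V U'
  U[0][2] = U[1][0]*U[2][1] - U[2][0]*U[1][1];
  U[1][2] = U[2][0]*U[0][1] - U[0][0]*U[2][1];
  U[2][2] = U[0][0]*U[1][1] - U[1][0]*U[0][1];
  V[0][2] = V[1][0]*V[2][1] - V[2][0]*V[1][1];
  V[1][2] = V[2][0]*V[0][1] - V[0][0]*V[2][1];
  V[2][2] = V[0][0]*V[1][1] - V[1][0]*V[0][1];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      R[a][b] = V[a][0]*U[b][0] + V[a][1]*U[b][1] + V[a][2]*U[b][2];
  for (int a = 0; a < 3; ++a)
    t[a] = pc[a] - (R[a][0]*xc[0] + R[a][1]*xc[1] + R[a][2]*xc[2]);
  return true;
}

// LAD iteration loop.  X0: current canonical vertex positions (after global
// similarity alignment); nbrs/wts: frozen canonical neighbourhoods and
// proximity weights; tex_mode = 0 for closest-point pairing, 1 for
// texture-similarity pairing within `search` mm.
// [[Rcpp::export(name = ".cpp_lad_run")]]
List cpp_lad_run(SEXP ptr, const arma::mat& X0, const List& nbrs,
                 const List& wts, int max_iter, double tol, int tex_mode,
                 const arma::vec& tex1, const arma::vec& tex2, double search) {
  TriGrid* g = as_grid(ptr);
  const int nv = (int)X0.n_rows;
  arma::mat X = X0;
  arma::mat P(nv, 3);
  std::vector<double> Rk(nv * 9), tk(nv * 3);
  std::vector<bool> okk(nv);
  std::vector<std::vector<int>> nb(nv);
  std::vector<std::vector<double>> wb(nv);
  for (int k = 0; k < nv; ++k) {
    IntegerVector id = nbrs[k];
    NumericVector wv = wts[k];
    nb[k].resize(id.size());
    for (int u = 0; u < id.size(); ++u) nb[k][u] = id[u] - 1;  // to 0-based
    wb[k].assign(wv.begin(), wv.end());
  }
  IntegerVector pair_vertex(nv, -1);
  int n_fallback = 0, n_empty = 0, it = 0;
  bool converged = false;
  std::vector<int> cand;
  double prev_rms_tex = -1.0;
  for (it = 1; it <= max_iter; ++it) {
    double sum_tex2 = 0.0;
    // (1) pairing
    for (int k = 0; k < nv; ++k) {
      double q[3] = { X(k,0), X(k,1), X(k,2) };
      if (tex_mode == 1) {
        grid_vertices_within(g, q, search, cand);
        int bestv = -1;
        double bestd = 0.0, bestt = std::numeric_limits<double>::infinity();
        for (size_t u = 0; u < cand.size(); ++u) {
          int v = cand[u];
          double dt = std::fabs(tex2[v] - tex1[k]);
          double p[3] = { g->V(v,0), g->V(v,1), g->V(v,2) };
          double d2 = sqdist3(q, p);
          if (dt < bestt - 1e-12 ||
              (std::fabs(dt - bestt) <= 1e-12 && d2 < bestd)) {
            bestt = dt; bestd = d2; bestv = v;
          }
        }
        if (bestv >= 0) {
          pair_vertex[k] = bestv;
          sum_tex2 += bestt * bestt;
          for (int a = 0; a < 3; ++a) P(k,a) = g->V(bestv,a);
          continue;
        }
        ++n_empty;  // no candidate in range: fall back to closest point
      }
      int f; double bc[3], ft[3], d;
      grid_closest_one(g, q, f, bc, ft, d);
      pair_vertex[k] = -1;
      for (int a = 0; a < 3; ++a) P(k,a) = ft[a];
    }
    // (2) local rigid fits
    const double* Xp = X.memptr();
    const double* Pp = P.memptr();
    for (int k = 0; k < nv; ++k) {
      double Rl[3][3], tl[3];
      okk[k] = kabsch_fit(Xp, Pp, nv, nb[k], wb[k].data(), Rl, tl);
      if (!okk[k]) ++n_fallback;
      for (int a = 0; a < 3; ++a) {
        for (int b = 0; b < 3; ++b) Rk[k*9 + a*3 + b] = Rl[a][b];
        tk[k*3 + a] = tl[a];
      }
    }
    // (3) proximity-weighted blend of neighbour transforms applied to x_k
    double delta = 0.0;
    arma::mat Xn(nv, 3);
    double* Xnp = Xn.memptr();
    for (int k = 0; k < nv; ++k) {
      const std::vector<int>& id = nb[k];
      const std::vector<double>& w = wb[k];
      double acc[3] = {0, 0, 0}, W = 0.0;
      double xk[3] = { Xp[k], Xp[k + nv], Xp[k + 2*nv] };
      for (size_t u = 0; u < id.size(); ++u) {
        int j = id[u];
        const double* Rj = &Rk[j*9];
        const double* tj = &tk[j*3];
        double wu = w[u];
        for (int a = 0; a < 3; ++a)
          acc[a] += wu * (Rj[a*3]*xk[0] + Rj[a*3+1]*xk[1] + Rj[a*3+2]*xk[2] + tj[a]);
        W += wu;
      }
      double dd = 0;
      for (int a = 0; a < 3; ++a) {
        acc[a] /= W;
        dd += (acc[a] - xk[a]) * (acc[a] - xk[a]);
        Xnp[k + a*nv] = acc[a];
      }
      delta += std::sqrt(dd);
    }
    X = Xn;
    delta /= nv;
    if (delta < tol) { converged = true; break; }
    if (tex_mode == 1) {
      // texture pairing hops between discrete vertices and rarely meets the
      // geometric tolerance; stop once the paired-texture mismatch plateaus
      double rms_tex = std::sqrt(sum_tex2 / nv);
      if (it >= 5 && prev_rms_tex > 0.0 &&
          (prev_rms_tex - rms_tex) < 1e-3 * prev_rms_tex) {
        converged = true;
        break;
      }
      prev_rms_tex = rms_tex;
    }
  }
  return List::create(_["X"] = X, _["iterations"] = std::min(it, max_iter),
                      _["converged"] = converged,
                      _["pair_vertex"] = pair_vertex,
                      _["n_fallback"] = n_fallback,
                      _["n_empty_search"] = n_empty);
}
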