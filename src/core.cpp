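#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 2D separable convolution with reflect (edge-repeating) border handling.
// Used for the 9x9 uniform background template and the 5x5 Gaussian; both
// kernels are symmetric outer products, so separable passes equal the full
// 2D convolution exactly (up to fp rounding).
// ---------------------------------------------------------------------------

static inline int reflect_idx(int i, int n) {
  // scipy-style 'reflect': (d c b a | a b c d | d c b a)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv2_sep(NumericMatrix x, NumericVector k) {
  int nr = x.nrow(), nc = x.ncol(), m = k.size(), h = m / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (first index)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = 0; t < m; ++t) s += k[t] * x(reflect_idx(i + t - h, nr), j);
      tmp(i, j) = s;
    }
  // along columns (second index)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = 0; t < m; ++t) s += k[t] * tmp(i, reflect_idx(j + t - h, nc));
      out(i, j) = s;
    }
  return out;
}

// ---------------------------------------------------------------------------
// 3D helpers: linear index <-> (i,j,k), 26-neighborhood offsets
// ---------------------------------------------------------------------------

struct Dim3 { int n1, n2, n3; };

static inline long lin(const Dim3& d, int i, int j, int k) {
  return (long)i + (long)d.n1 * ((long)j + (long)d.n2 * (long)k);
}

// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  Dim3 d = {dim[0], dim[1], dim[2]};
  long n = (long)d.n1 * d.n2 * d.n3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int i = (int)(v % d.n1), j = (int)((v / d.n1) % d.n2), k = (int)(v / ((long)d.n1 * d.n2));
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          for (int dk = -1; dk <= 1; ++dk) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
            long w = lin(d, ii, jj, kk);
            if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Priority-flood watershed restricted to one component.
// comp_idx, seed_idx: 0-based linear indices; returns a label (1..n_seeds)
// for every voxel in comp_idx, in the same order.
// [[Rcpp::export]]
IntegerVector cpp_watershed_flood(NumericVector intensity, IntegerVector dim,
                                  IntegerVector comp_idx, IntegerVector seed_idx) {
  Dim3 d = {dim[0], dim[1], dim[2]};
  std::map<long, int> pos;   // linear index -> position in comp_idx
  for (int t = 0; t < comp_idx.size(); ++t) pos[(long)comp_idx[t]] = t;
  std::vector<int> assign(comp_idx.size(), 0);
  typedef std::pair<double, std::pair<long, int> > QE; // (intensity, (idx, label))
  std::priority_queue<QE> q;
  for (int s = 0; s < seed_idx.size(); ++s) {
    long v = (long)seed_idx[s];
    q.push(QE(intensity[v], std::make_pair(v, s + 1)));
  }
  while (!q.empty()) {
    QE e = q.top(); q.pop();
    long v = e.second.first;
    int labv = e.second.second;
    int p = pos[v];
    if (assign[p] != 0) continue;
    assign[p] = labv;
    int i = (int)(v % d.n1), j = (int)((v / d.n1) % d.n2), k = (int)(v / ((long)d.n1 * d.n2));
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
          long w = lin(d, ii, jj, kk);
          std::map<long, int>::iterator it = pos.find(w);
          if (it != pos.end() && assign[it->second] == 0)
            q.push(QE(intensity[w], std::make_pair(w, labv)));
        }
  }
  return IntegerVector(assign.begin(), assign.end());
}

// ---------------------------------------------------------------------------
// Tube rasterization: voxels whose center lies within `radius` (voxel units)
// of the polyline are raised to `value`. pts are 0-based voxel coordinates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_rasterize_tube(NumericVector vol, IntegerVector dim,
                                 NumericMatrix pts, double radius, double value) {
  Dim3 d = {dim[0], dim[1], dim[2]};
  NumericVector out = clone(vol);
  double r2 = radius * radius;
  for (int s = 0; s + 1 < pts.nrow(); ++s) {
    double a1 = pts(s, 0), a2 = pts(s, 1), a3 = pts(s, 2);
    double b1 = pts(s + 1, 0), b2 = pts(s + 1, 1), b3 = pts(s + 1, 2);
    // NaN rows separate independent polylines
    if (ISNAN(a1) || ISNAN(b1)) continue;
    double u1 = b1 - a1, u2 = b2 - a2, u3 = b3 - a3;
    double L2 = u1 * u1 + u2 * u2 + u3 * u3;
    int lo1 = (int)std::floor(std::min(a1, b1) - radius), hi1 = (int)std::ceil(std::max(a1, b1) + radius);
    int lo2 = (int)std::floor(std::min(a2, b2) - radius), hi2 = (int)std::ceil(std::max(a2, b2) + radius);
    int lo3 = (int)std::floor(std::min(a3, b3) - radius), hi3 = (int)std::ceil(std::max(a3, b3) + radius);
    lo1 = std::max(lo1, 0); lo2 = std::max(lo2, 0); lo3 = std::max(lo3, 0);
    hi1 = std::min(hi1, d.n1 - 1); hi2 = std::min(hi2, d.n2 - 1); hi3 = std::min(hi3, d.n3 - 1);
    for (int k = lo3; k <= hi3; ++k)
      for (int j = lo2; j <= hi2; ++j)
        for (int i = lo1; i <= hi1; ++i) {
          double p1 = i - a1, p2 = j - a2, p3 = k - a3;
          double t = L2 > 0 ? (p1 * u1 + p2 * u2 + p3 * u3) / L2 : 0.0;
          if (t < 0) t = 0; if (t > 1) t = 1;
          double q1 = p1 - t * u1, q2 = p2 - t * u2, q3 = p3 - t * u3;
          if (q1 * q1 + q2 * q2 + q3 * q3 <= r2) {
            long v = lin(d, i, j, k);
            if (out[v] < value) out[v] = value;
          }
        }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Multistencils fast marching: solves |grad T| * F = 1 with T = 0 on seeds.
// Four orthogonal stencils (axes + the three in-plane diagonal rotations),
// second-order upwind differences where both upwind neighbors along a
// stencil direction are finalized, first-order otherwise. Cells with F <= 0
// are obstacles and keep T = +Inf.
// ---------------------------------------------------------------------------

struct StDir { int o1, o2, o3; double h; };

// [[Rcpp::export]]
NumericVector cpp_msfm(NumericVector speed, IntegerVector dim, IntegerVector seeds,
                       bool second_order = true, bool cross_stencils = true,
                       double init_radius = 4.0) {
  Dim3 d = {dim[0], dim[1], dim[2]};
  long n = (long)d.n1 * d.n2 * d.n3;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector T(n, INF);
  std::vector<char> frozen(n, 0);

  static const double SQ2 = std::sqrt(2.0);
  std::vector< std::vector<StDir> > stencils;
  {
    std::vector<StDir> s0;
    StDir a = {1,0,0,1.0}, b = {0,1,0,1.0}, c = {0,0,1,1.0};
    s0.push_back(a); s0.push_back(b); s0.push_back(c);
    stencils.push_back(s0);
    if (cross_stencils) {
      StDir s1a = {1,1,0,SQ2}, s1b = {1,-1,0,SQ2}, s1c = {0,0,1,1.0};
      StDir s2a = {1,0,1,SQ2}, s2b = {1,0,-1,SQ2}, s2c = {0,1,0,1.0};
      StDir s3a = {0,1,1,SQ2}, s3b = {0,1,-1,SQ2}, s3c = {1,0,0,1.0};
      std::vector<StDir> s1, s2, s3;
      s1.push_back(s1a); s1.push_back(s1b); s1.push_back(s1c);
      s2.push_back(s2a); s2.push_back(s2b); s2.push_back(s2c);
      s3.push_back(s3a); s3.push_back(s3b); s3.push_back(s3c);
      stencils.push_back(s1); stencils.push_back(s2); stencils.push_back(s3);
    }
  }

  // update offsets: +/- d and +/- 2d for every stencil direction
  std::vector<int> off1, off2, off3;
  for (size_t s = 0; s < stencils.size(); ++s)
    for (size_t j = 0; j < stencils[s].size(); ++j)
      for (int sgn = -1; sgn <= 1; sgn += 2)
        for (int mul = 1; mul <= 2; ++mul) {
          int o1 = sgn * mul * stencils[s][j].o1;
          int o2 = sgn * mul * stencils[s][j].o2;
          int o3 = sgn * mul * stencils[s][j].o3;
          bool dup = false;
          for (size_t t = 0; t < off1.size(); ++t)
            if (off1[t] == o1 && off2[t] == o2 && off3[t] == o3) { dup = true; break; }
          if (!dup) { off1.push_back(o1); off2.push_back(o2); off3.push_back(o3); }
        }

  typedef std::pair<double, long> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;

  // solve the upwind quadratic at cell (i,j,k); returns trial T or INF
  struct Solver {
    const Dim3& d; const NumericVector& T; const std::vector<char>& frozen;
    const NumericVector& speed; const std::vector< std::vector<StDir> >& stencils;
    bool second_order;
    Solver(const Dim3& d_, const NumericVector& T_, const std::vector<char>& f_,
           const NumericVector& sp_, const std::vector< std::vector<StDir> >& st_, bool so)
      : d(d_), T(T_), frozen(f_), speed(sp_), stencils(st_), second_order(so) {}
    double solve(int i, int j, int k) const {
      long v = lin(d, i, j, k);
      double F = speed[v];
      if (F <= 0) return std::numeric_limits<double>::infinity();
      double slo = 1.0 / F, best = std::numeric_limits<double>::infinity();
      for (size_t s = 0; s < stencils.size(); ++s) {
        double alpha[3], tval[3];
        int m = 0;
        for (size_t q = 0; q < stencils[s].size(); ++q) {
          const StDir& dd = stencils[s][q];
          double t1 = std::numeric_limits<double>::infinity();
          int sgn_used = 0;
          for (int sgn = -1; sgn <= 1; sgn += 2) {
            int ii = i + sgn * dd.o1, jj = j + sgn * dd.o2, kk = k + sgn * dd.o3;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
            long w = lin(d, ii, jj, kk);
            if (frozen[w] && T[w] < t1) { t1 = T[w]; sgn_used = sgn; }
          }
          if (!R_finite(t1)) continue;
          double a = 1.0 / dd.h, tv = t1;
          if (second_order) {
            int ii = i + 2 * sgn_used * dd.o1, jj = j + 2 * sgn_used * dd.o2, kk = k + 2 * sgn_used * dd.o3;
            if (ii >= 0 && jj >= 0 && kk >= 0 && ii < d.n1 && jj < d.n2 && kk < d.n3) {
              long w2 = lin(d, ii, jj, kk);
              if (frozen[w2] && T[w2] <= t1) {
                a = 3.0 / (2.0 * dd.h);
                tv = (4.0 * t1 - T[w2]) / 3.0;
              }
            }
          }
          alpha[m] = a; tval[m] = tv; ++m;
        }
        while (m > 0) {
          double A = 0, B = 0, C = -slo * slo, tmax = -1;
          int imax = 0;
          for (int q = 0; q < m; ++q) {
            A += alpha[q] * alpha[q];
            B += -2.0 * alpha[q] * alpha[q] * tval[q];
            C += alpha[q] * alpha[q] * tval[q] * tval[q];
            if (tval[q] > tmax) { tmax = tval[q]; imax = q; }
          }
          double disc = B * B - 4.0 * A * C;
          if (disc >= 0) {
            double root = (-B + std::sqrt(disc)) / (2.0 * A);
            if (root >= tmax) { if (root < best) best = root; break; }
          }
          // causality violated: drop the largest-t direction and retry
          alpha[imax] = alpha[m - 1]; tval[imax] = tval[m - 1]; --m;
        }
      }
      return best;
    }
  };
  Solver sol(d, T, frozen, speed, stencils, second_order);

  for (int s = 0; s < seeds.size(); ++s) {
    long v = (long)seeds[s];
    T[v] = 0.0;
    frozen[v] = 1;
  }
  // Exact-style initialization in a small ball around each seed: straight-ray
  // arrival time with the mean slowness of the endpoints. Second-order
  // differences are inaccurate across the non-smooth source point; seeding
  // the first few rings analytically removes that error at its origin.
  std::vector<long> init_cells;
  if (init_radius > 0) {
    int R = (int)std::floor(init_radius);
    for (int s = 0; s < seeds.size(); ++s) {
      long v = (long)seeds[s];
      double Fs = speed[v];
      if (Fs <= 0) continue;
      int i = (int)(v % d.n1), j = (int)((v / d.n1) % d.n2), k = (int)(v / ((long)d.n1 * d.n2));
      for (int di = -R; di <= R; ++di)
        for (int dj = -R; dj <= R; ++dj)
          for (int dk = -R; dk <= R; ++dk) {
            double dist = std::sqrt((double)(di * di + dj * dj + dk * dk));
            if (dist == 0.0 || dist > init_radius) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
            long w = lin(d, ii, jj, kk);
            if (frozen[w]) continue;
            double Fw = speed[w];
            if (Fw <= 0) continue;
            double tv = dist * 0.5 * (1.0 / Fs + 1.0 / Fw);
            if (tv < T[w]) {
              if (!R_finite(T[w])) init_cells.push_back(w);
              T[w] = tv;
            }
          }
    }
    for (size_t t = 0; t < init_cells.size(); ++t) frozen[init_cells[t]] = 1;
  }
  // initial narrow band: update every neighbor of every frozen cell
  std::vector<long> frozen0;
  for (int s = 0; s < seeds.size(); ++s) frozen0.push_back((long)seeds[s]);
  for (size_t t = 0; t < init_cells.size(); ++t) frozen0.push_back(init_cells[t]);
  for (size_t f = 0; f < frozen0.size(); ++f) {
    long v = frozen0[f];
    int i = (int)(v % d.n1), j = (int)((v / d.n1) % d.n2), k = (int)(v / ((long)d.n1 * d.n2));
    for (size_t t = 0; t < off1.size(); ++t) {
      int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
      long w = lin(d, ii, jj, kk);
      if (frozen[w]) continue;
      double tn = sol.solve(ii, jj, kk);
      if (tn < T[w]) { T[w] = tn; heap.push(QE(tn, w)); }
    }
  }

  while (!heap.empty()) {
    QE e = heap.top(); heap.pop();
    long v = e.second;
    if (frozen[v]) continue;
    if (e.first > T[v]) continue;  // stale entry
    frozen[v] = 1;
    int i = (int)(v % d.n1), j = (int)((v / d.n1) % d.n2), k = (int)(v / ((long)d.n1 * d.n2));
    for (size_t t = 0; t < off1.size(); ++t) {
      int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
      long w = lin(d, ii, jj, kk);
      if (frozen[w]) continue;
      double tn = sol.solve(ii, jj, kk);
      if (tn < T[w]) { T[w] = tn; heap.push(QE(tn, w)); }
    }
  }

  T.attr("dim") = dim;
  return T;
}

// ---------------------------------------------------------------------------
// Back-tracking: gradient descent on T from a start point (0-based continuous
// cell coordinates, integer values = cell centers) until a seed cell is
// entered, max_steps is hit, or no downhill progress can be made.
// Gradient: per-cell central differences (one-sided at borders / next to
// non-finite T), trilinearly interpolated.
// ---------------------------------------------------------------------------

static inline double tsafe(const NumericVector& T, const Dim3& d, int i, int j, int k,
                           double big) {
  if (i < 0 || j < 0 || k < 0 || i >= d.n1 || j >= d.n2 || k >= d.n3) return big;
  double v = T[lin(d, i, j, k)];
  return R_finite(v) ? v : big;
}

static void cell_grad(const NumericVector& T, const Dim3& d, int i, int j, int k,
                      double big, double g[3]) {
  double c = tsafe(T, d, i, j, k, big);
  int off[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
  for (int a = 0; a < 3; ++a) {
    double p = tsafe(T, d, i + off[a][0], j + off[a][1], k + off[a][2], big);
    double m = tsafe(T, d, i - off[a][0], j - off[a][1], k - off[a][2], big);
    bool pf = p < big, mf = m < big;
    if (pf && mf) g[a] = (p - m) / 2.0;
    else if (pf) g[a] = p - c;
    else if (mf) g[a] = c - m;
    else g[a] = 0.0;
  }
}

static double interp_T(const NumericVector& T, const Dim3& d, const double p[3], double big) {
  int i0 = (int)std::floor(p[0]), j0 = (int)std::floor(p[1]), k0 = (int)std::floor(p[2]);
  double f1 = p[0] - i0, f2 = p[1] - j0, f3 = p[2] - k0;
  double s = 0.0;
  for (int a = 0; a <= 1; ++a)
    for (int b = 0; b <= 1; ++b)
      for (int c = 0; c <= 1; ++c) {
        double w = (a ? f1 : 1 - f1) * (b ? f2 : 1 - f2) * (c ? f3 : 1 - f3);
        if (w > 0) s += w * tsafe(T, d, i0 + a, j0 + b, k0 + c, big);
      }
  return s;
}

static void interp_grad(const NumericVector& T, const Dim3& d, const double p[3],
                        double big, double g[3]) {
  int i0 = (int)std::floor(p[0]), j0 = (int)std::floor(p[1]), k0 = (int)std::floor(p[2]);
  double f1 = p[0] - i0, f2 = p[1] - j0, f3 = p[2] - k0;
  g[0] = g[1] = g[2] = 0.0;
  double gc[3];
  for (int a = 0; a <= 1; ++a)
    for (int b = 0; b <= 1; ++b)
      for (int c = 0; c <= 1; ++c) {
        double w = (a ? f1 : 1 - f1) * (b ? f2 : 1 - f2) * (c ? f3 : 1 - f3);
        if (w <= 0) continue;
        int ii = std::min(std::max(i0 + a, 0), d.n1 - 1);
        int jj = std::min(std::max(j0 + b, 0), d.n2 - 1);
        int kk = std::min(std::max(k0 + c, 0), d.n3 - 1);
        cell_grad(T, d, ii, jj, kk, big, gc);
        g[0] += w * gc[0]; g[1] += w * gc[1]; g[2] += w * gc[2];
      }
}

// [[Rcpp::export]]
List cpp_backtrack(NumericVector T, IntegerVector dim, LogicalVector seed_mask,
                   NumericVector start, double step_size, int max_steps) {
  Dim3 d = {dim[0], dim[1], dim[2]};
  double big = 0.0;
  for (long v = 0; v < T.size(); ++v)
    if (R_finite(T[v]) && T[v] > big) big = T[v];
  big = 2.0 * big + 1.0;

  std::vector<double> P1, P2, P3;
  double p[3] = {start[0], start[1], start[2]};
  for (int a = 0; a < 3; ++a) {
    double hi = (a == 0 ? d.n1 : (a == 1 ? d.n2 : d.n3)) - 1.0;
    if (p[a] < 0) p[a] = 0; if (p[a] > hi) p[a] = hi;
  }
  P1.push_back(p[0]); P2.push_back(p[1]); P3.push_back(p[2]);
  bool reached = false;
  long cell = lin(d, (int)std::lround(p[0]), (int)std::lround(p[1]), (int)std::lround(p[2]));
  if (seed_mask[cell]) reached = true;
  long start_cell = lin(d, (int)std::lround(p[0]), (int)std::lround(p[1]), (int)std::lround(p[2]));
  if (!reached && !R_finite(T[start_cell])) {
    // unreachable pocket: no descent possible
  } else if (!reached) {
    double tcur = interp_T(T, d, p, big);
    for (int s = 0; s < max_steps && !reached; ++s) {
      double g[3];
      interp_grad(T, d, p, big, g);
      double nrm = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
      bool moved = false;
      double q[3];
      if (nrm >= 1e-12) {
        q[0] = p[0] - step_size * g[0] / nrm;
        q[1] = p[1] - step_size * g[1] / nrm;
        q[2] = p[2] - step_size * g[2] / nrm;
        for (int a = 0; a < 3; ++a) {
          double hi = (a == 0 ? d.n1 : (a == 1 ? d.n2 : d.n3)) - 1.0;
          if (q[a] < 0) q[a] = 0;
          if (q[a] > hi) q[a] = hi;
        }
        double tnew = interp_T(T, d, q, big);
        if (tnew < tcur - 1e-15) { tcur = tnew; moved = true; }
      }
      if (!moved) {
        // Trilinear interpolation across strong speed contrasts can make the
        // smooth gradient step non-decreasing; fall back to discrete
        // steepest descent, which strictly decreases: by upwind construction
        // every finite non-seed cell has a smaller-T 26-neighbor.
        int ci = (int)std::lround(p[0]), cj = (int)std::lround(p[1]),
            ck = (int)std::lround(p[2]);
        double tc = tsafe(T, d, ci, cj, ck, big), tbest = tc;
        int bi = ci, bj = cj, bk = ck;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj)
            for (int dk = -1; dk <= 1; ++dk) {
              if (!di && !dj && !dk) continue;
              int ii = ci + di, jj = cj + dj, kk = ck + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
              double tn = tsafe(T, d, ii, jj, kk, big);
              if (tn < tbest) { tbest = tn; bi = ii; bj = jj; bk = kk; }
            }
        if (tbest >= tc) break;  // no downhill progress anywhere
        q[0] = bi; q[1] = bj; q[2] = bk;
        tcur = tbest;
        moved = true;
      }
      p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
      P1.push_back(p[0]); P2.push_back(p[1]); P3.push_back(p[2]);
      cell = lin(d, (int)std::lround(p[0]), (int)std::lround(p[1]), (int)std::lround(p[2]));
      if (seed_mask[cell]) reached = true;
    }
  }
  int np = (int)P1.size();
  NumericMatrix pts(np, 3);
  for (int t = 0; t < np; ++t) { pts(t, 0) = P1[t]; pts(t, 1) = P2[t]; pts(t, 2) = P3[t]; }
  return List::create(_["points"] = pts, _["reached_seed"] = reached);
}
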