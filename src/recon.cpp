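// List-mode TOF-MLEM reconstruction: exact Siddon/Amanatides-Woo ray
// traversal, Gaussian TOF weighting truncated at +-3 sigma, Monte Carlo
// sensitivity image, separable Gaussian post-filter.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double C_MM_NS = 299.792458;

struct Grid {
  double ox, oy, oz, v;
  int nx, ny, nz;
};

// Exact radiological path of the segment p1->p2 through the grid.
// Appends (flat voxel index, intersection length, distance-from-p1 of the
// segment midpoint) to the buffers; returns the number of voxels.
static int traverse(const Grid& g, const double* p1, const double* p2,
                    int* vox, double* len, double* mid) {
  double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0) return 0;
  double u[3] = {d[0] / L, d[1] / L, d[2] / L};
  double o[3] = {g.ox, g.oy, g.oz};
  int n[3] = {g.nx, g.ny, g.nz};
  double tmin = 0, tmax = L;
  for (int c = 0; c < 3; ++c) {
    double lo = o[c], hi = o[c] + n[c] * g.v;
    if (std::fabs(u[c]) < 1e-12) {
      if (p1[c] < lo || p1[c] > hi) return 0;
    } else {
      double ta = (lo - p1[c]) / u[c], tb = (hi - p1[c]) / u[c];
      if (ta > tb) std::swap(ta, tb);
      if (ta > tmin) tmin = ta;
      if (tb < tmax) tmax = tb;
    }
  }
  if (tmax <= tmin + 1e-12) return 0;
  double t = tmin;
  double ps[3];
  for (int c = 0; c < 3; ++c) ps[c] = p1[c] + (t + 1e-9) * u[c];
  int idx[3], step[3];
  double tnext[3], tdelta[3];
  for (int c = 0; c < 3; ++c) {
    idx[c] = (int)std::floor((ps[c] - o[c]) / g.v);
    if (idx[c] < 0) idx[c] = 0;
    if (idx[c] >= n[c]) idx[c] = n[c] - 1;
    if (std::fabs(u[c]) < 1e-12) {
      step[c] = 0; tnext[c] = 1e30; tdelta[c] = 1e30;
    } else {
      step[c] = u[c] > 0 ? 1 : -1;
      double bound = o[c] + (idx[c] + (u[c] > 0 ? 1 : 0)) * g.v;
      tnext[c] = (bound - p1[c]) / u[c];
      tdelta[c] = g.v / std::fabs(u[c]);
    }
  }
  int k = 0;
  while (t < tmax - 1e-12) {
    int ax = 0;
    if (tnext[1] < tnext[ax]) ax = 1;
    if (tnext[2] < tnext[ax]) ax = 2;
    double texit = std::min(tnext[ax], tmax);
    double seg = texit - t;
    if (seg > 1e-12) {
      vox[k] = idx[0] + g.nx * (idx[1] + g.ny * idx[2]);
      len[k] = seg;
      mid[k] = 0.5 * (t + texit);
      ++k;
    }
    t = texit;
    if (texit >= tmax - 1e-12) break;
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= n[ax]) break;
    tnext[ax] += tdelta[ax];
  }
  return k;
}

static Grid make_grid(NumericVector origin, double voxel, IntegerVector dim) {
  Grid g;
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.v = voxel; g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  return g;
}

// [[Rcpp::export]]
List cpp_ray_trace(NumericVector p1, NumericVector p2, NumericVector origin,
                   double voxel, IntegerVector dim) {
  Grid g = make_grid(origin, voxel, dim);
  int cap = g.nx + g.ny + g.nz + 3;
  std::vector<int> vox(cap);
  std::vector<double> len(cap), mid(cap);
  double a[3] = {p1[0], p1[1], p1[2]}, b[3] = {p2[0], p2[1], p2[2]};
  int k = traverse(g, a, b, vox.data(), len.data(), mid.data());
  return List::create(_["voxel"] = IntegerVector(vox.begin(), vox.begin() + k),
                      _["length"] = NumericVector(len.begin(), len.begin() + k),
                      _["mid"] = NumericVector(mid.begin(), mid.begin() + k));
}

// TOF weight of each traversed voxel. dt convention: dt = t1 - t2 (ns), so
// the most likely annihilation point sits at L/2 + c*dt/2 from endpoint 1.
static inline double tof_center(double L, double dt_ns) {
  return L / 2 + C_MM_NS * dt_ns / 2;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector x, NumericMatrix e1,
                                  NumericMatrix e2, NumericVector dt_ns,
                                  NumericVector origin, double voxel,
                                  IntegerVector dim, double sigma_tof) {
  Grid g = make_grid(origin, voxel, dim);
  int cap = g.nx + g.ny + g.nz + 3;
  std::vector<int> vox(cap);
  std::vector<double> len(cap), mid(cap);
  int n = e1.nrow();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double a[3] = {e1(i, 0), e1(i, 1), e1(i, 2)};
    double b[3] = {e2(i, 0), e2(i, 1), e2(i, 2)};
    int k = traverse(g, a, b, vox.data(), len.data(), mid.data());
    double L = std::sqrt((a[0]-b[0])*(a[0]-b[0]) + (a[1]-b[1])*(a[1]-b[1]) +
                         (a[2]-b[2])*(a[2]-b[2]));
    double ctr = tof_center(L, dt_ns[i]);
    double acc = 0;
    for (int j = 0; j < k; ++j) {
      double w = len[j];
      if (sigma_tof > 0) {
        double z = (mid[j] - ctr) / sigma_tof;
        if (std::fabs(z) > 3) continue;
        w *= std::exp(-0.5 * z * z);
      }
      acc += w * x[vox[j]];
    }
    y[i] = acc;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector y, NumericMatrix e1,
                               NumericMatrix e2, NumericVector dt_ns,
                               NumericVector origin, double voxel,
                               IntegerVector dim, double sigma_tof) {
  Grid g = make_grid(origin, voxel, dim);
  int cap = g.nx + g.ny + g.nz + 3;
  std::vector<int> vox(cap);
  std::vector<double> len(cap), mid(cap);
  int n = e1.nrow();
  NumericVector x((R_xlen_t)g.nx * g.ny * g.nz);
  for (int i = 0; i < n; ++i) {
    double a[3] = {e1(i, 0), e1(i, 1), e1(i, 2)};
    double b[3] = {e2(i, 0), e2(i, 1), e2(i, 2)};
    int k = traverse(g, a, b, vox.data(), len.data(), mid.data());
    double L = std::sqrt((a[0]-b[0])*(a[0]-b[0]) + (a[1]-b[1])*(a[1]-b[1]) +
                         (a[2]-b[2])*(a[2]-b[2]));
    double ctr = tof_center(L, dt_ns[i]);
    for (int j = 0; j < k; ++j) {
      double w = len[j];
      if (sigma_tof > 0) {
        double z = (mid[j] - ctr) / sigma_tof;
        if (std::fabs(z) > 3) continue;
        w *= std::exp(-0.5 * z * z);
      }
      x[vox[j]] += w * y[i];
    }
  }
  return x;
}

// List-mode MLEM. Each event may be modelled by `kray` rays sampling the
// crystal aperture (rows i*kray .. i*kray+kray-1 of e1/e2); the event's
// system-matrix row is the average of its rays, so the aperture footprint
// is part of the forward model (a desk-scale stand-in for a
// distance-driven projector) rather than a blur on the data.
// [[Rcpp::export]]
NumericVector cpp_mlem(NumericMatrix e1, NumericMatrix e2, NumericVector dt_ns,
                       NumericVector origin, double voxel, IntegerVector dim,
                       int n_iter, double sigma_tof, NumericVector sens,
                       int kray = 1) {
  Grid g = make_grid(origin, voxel, dim);
  R_xlen_t nv = (R_xlen_t)g.nx * g.ny * g.nz;
  int cap = g.nx + g.ny + g.nz + 3;
  int n = e1.nrow() / kray;
  std::vector<int> vox((size_t)cap * kray);
  std::vector<double> len((size_t)cap * kray), mid(cap);
  std::vector<int> nk(kray);
  NumericVector x(nv);
  for (R_xlen_t j = 0; j < nv; ++j) x[j] = sens[j] > 0 ? 1.0 : 0.0;
  std::vector<double> acc(nv);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double q = 0;
      for (int r = 0; r < kray; ++r) {
        int row = i * kray + r;
        double a[3] = {e1(row, 0), e1(row, 1), e1(row, 2)};
        double b[3] = {e2(row, 0), e2(row, 1), e2(row, 2)};
        int k = traverse(g, a, b, vox.data() + (size_t)r * cap,
                         len.data() + (size_t)r * cap, mid.data());
        nk[r] = k;
        double L = std::sqrt((a[0]-b[0])*(a[0]-b[0]) + (a[1]-b[1])*(a[1]-b[1]) +
                             (a[2]-b[2])*(a[2]-b[2]));
        double ctr = tof_center(L, dt_ns[i]);
        int*    v = vox.data() + (size_t)r * cap;
        double* w = len.data() + (size_t)r * cap;
        for (int j = 0; j < k; ++j) {
          double ww = w[j];
          if (sigma_tof > 0) {
            double z = (mid[j] - ctr) / sigma_tof;
            if (std::fabs(z) > 3) { w[j] = 0; continue; }
            ww *= std::exp(-0.5 * z * z);
          }
          w[j] = ww;       // reuse buffer: effective weight
          q += ww * x[v[j]];
        }
      }
      if (q <= 0) continue;
      double inv = 1.0 / q;   // the 1/kray factors cancel in a_ij / q
      for (int r = 0; r < kray; ++r) {
        int*    v = vox.data() + (size_t)r * cap;
        double* w = len.data() + (size_t)r * cap;
        for (int j = 0; j < nk[r]; ++j)
          if (w[j] > 0) acc[v[j]] += w[j] * inv;
      }
    }
    for (R_xlen_t j = 0; j < nv; ++j)
      x[j] = sens[j] > 0 ? x[j] * acc[j] / sens[j] : 0.0;
    Rcpp::checkUserInterrupt();
  }
  return x;
}

// Monte Carlo sensitivity image: back-projection of uniformly sampled
// admissible crystal pairs. mode 0: flat panel (groups must differ);
// mode 1: ring (circular sector difference >= min_diff over n_groups).
// Endpoints are jittered uniformly over the crystal aperture (basis
// vectors ub/vb, half-width `half`), matching the projector's LOR model.
// [[Rcpp::export]]
NumericVector cpp_sensitivity(NumericMatrix centers, IntegerVector group,
                              NumericMatrix ub, NumericMatrix vb, double half,
                              int mode, int n_groups, int min_diff,
                              double n_samples, NumericVector origin,
                              double voxel, IntegerVector dim) {
  Grid g = make_grid(origin, voxel, dim);
  R_xlen_t nv = (R_xlen_t)g.nx * g.ny * g.nz;
  int cap = g.nx + g.ny + g.nz + 3;
  std::vector<int> vox(cap);
  std::vector<double> len(cap), mid(cap);
  NumericVector sens(nv);
  int n = centers.nrow();
  RNGScope scope;
  for (double s = 0; s < n_samples; ++s) {
    int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
    int j, tries = 0;
    for (;;) {
      j = (int)(unif_rand() * n); if (j >= n) j = n - 1;
      if (mode == 0) { if (group[i] != group[j]) break; }
      else {
        int d = std::abs(group[i] - group[j]);
        d = std::min(d, n_groups - d);
        if (d >= min_diff) break;
      }
      if (++tries > 1000) break;
    }
    if (tries > 1000) continue;
    double u1 = half * (2 * unif_rand() - 1), v1 = half * (2 * unif_rand() - 1);
    double u2 = half * (2 * unif_rand() - 1), v2 = half * (2 * unif_rand() - 1);
    double a[3], b[3];
    for (int c = 0; c < 3; ++c) {
      a[c] = centers(i, c) + u1 * ub(i, c) + v1 * vb(i, c);
      b[c] = centers(j, c) + u2 * ub(j, c) + v2 * vb(j, c);
    }
    int k = traverse(g, a, b, vox.data(), len.data(), mid.data());
    for (int q = 0; q < k; ++q) sens[vox[q]] += len[q];
  }
  for (R_xlen_t j = 0; j < nv; ++j) sens[j] /= n_samples;
  return sens;
}

// separable Gaussian convolution, zero-padded, kernel normalized to 1
// [[Rcpp::export]]
NumericVector cpp_gauss_filter3(NumericVector img, IntegerVector dim,
                                double sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  if (sigma_vox <= 0) return clone(img);
  int r = (int)std::ceil(4 * sigma_vox);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    s += ker[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) ker[i] /= s;
  std::vector<double> a(img.begin(), img.end()), b(nv);
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    std::fill(b.begin(), b.end(), 0.0);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int c[3] = {x, y, z};
          R_xlen_t base = x + stride[1] * y + stride[2] * z;
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = c[ax] + t;
            if (q < 0 || q >= n[ax]) continue;
            acc += ker[t + r] * a[base + (R_xlen_t)(q - c[ax]) * stride[ax]];
          }
          b[base] = acc;
        }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}
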