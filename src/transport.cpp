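// Monte Carlo photon transport: analytic phantoms (Woodcock delta-tracking
// with Klein-Nishina Compton sampling) and crystal detectors (flat panels,
// reference ring). Uses R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- cross-section tables ------------------------------------------------

struct XS {
  int nmat, ne;
  std::vector<double> loge, logmu, pef; // logmu: nmat x ne, -inf for mu=0
  XS(const NumericMatrix& mu, const NumericMatrix& pe, const NumericVector& e)
      : nmat(mu.nrow()), ne(mu.ncol()), loge(ne), logmu(nmat * ne), pef(nmat * ne) {
    for (int j = 0; j < ne; ++j) loge[j] = std::log(e[j]);
    for (int i = 0; i < nmat; ++i)
      for (int j = 0; j < ne; ++j) {
        logmu[i * ne + j] = mu(i, j) > 0 ? std::log(mu(i, j)) : -1e30;
        pef[i * ne + j] = pe(i, j);
      }
  }
  // log-log interpolated linear attenuation (1/mm); energy clamped
  double mu(int mat, double ekeV) const {
    double le = std::log(std::min(std::max(ekeV, 50.0), 511.0));
    int j = 0;
    while (j < ne - 2 && loge[j + 1] < le) ++j;
    double f = (le - loge[j]) / (loge[j + 1] - loge[j]);
    double lm = logmu[mat * ne + j] * (1 - f) + logmu[mat * ne + j + 1] * f;
    return lm < -1e29 ? 0.0 : std::exp(lm);
  }
  double pe_frac(int mat, double ekeV) const {
    double le = std::log(std::min(std::max(ekeV, 50.0), 511.0));
    int j = 0;
    while (j < ne - 2 && loge[j + 1] < le) ++j;
    double f = (le - loge[j]) / (loge[j + 1] - loge[j]);
    return pef[mat * ne + j] * (1 - f) + pef[mat * ne + j + 1] * f;
  }
};

// ---- phantom primitives --------------------------------------------------

struct Phantom {
  int k;
  std::vector<double> P; // k x 12 row-major: type,c3,d3,a3,conc,mat
  int bg_mat;
  double rbound;
  Phantom(const NumericMatrix& pm, int bg, double rb)
      : k(pm.nrow()), P(k * 12), bg_mat(bg), rbound(rb) {
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < 12; ++j) P[i * 12 + j] = pm(i, j);
  }
  bool inside(int i, const double* p) const {
    const double* r = &P[i * 12];
    double w0 = p[0] - r[1], w1 = p[1] - r[2], w2 = p[2] - r[3];
    int type = (int)r[0];
    if (type == 1) return w0 * w0 + w1 * w1 + w2 * w2 <= r[4] * r[4];
    if (type == 2) {
      double h = w0 * r[7] + w1 * r[8] + w2 * r[9];
      if (std::fabs(h) > r[5]) return false;
      double r2 = w0 * w0 + w1 * w1 + w2 * w2 - h * h;
      return r2 <= r[4] * r[4];
    }
    return std::fabs(w0) <= r[4] && std::fabs(w1) <= r[5] && std::fabs(w2) <= r[6];
  }
  // material at a point: last containing primitive wins; background inside
  // the bounding sphere; vacuum (mat -1) outside it
  int material(const double* p) const {
    for (int i = k - 1; i >= 0; --i)
      if (inside(i, p)) return (int)P[i * 12 + 11] - 1; // to 0-based
    if (p[0] * p[0] + p[1] * p[1] + p[2] * p[2] <= rbound * rbound)
      return bg_mat - 1;
    return -1;
  }
};

// ---- sampling helpers ----------------------------------------------------

// Kahn's rejection method for the Klein-Nishina distribution.
// Returns x = E/E'; cos(theta) follows from the Compton relation.
static double sample_kn_x(double ekeV) {
  double a = ekeV / 511.0;
  for (;;) {
    double r1 = unif_rand(), r2 = unif_rand(), r3 = unif_rand();
    if (r1 <= (2 * a + 1) / (2 * a + 9)) {
      double x = 1 + 2 * a * r2;
      if (r3 <= 4 * (1 / x - 1 / (x * x))) return x;
    } else {
      double x = (2 * a + 1) / (2 * a * r2 + 1);
      double ct = 1 - (x - 1) / a;
      if (r3 <= 0.5 * (ct * ct + 1 / x)) return x;
    }
  }
}

// rotate unit vector d by polar angle with cosine ct, uniform azimuth
static void rotate_dir(double* d, double ct) {
  double st = std::sqrt(std::max(0.0, 1 - ct * ct));
  double phi = 2 * M_PI * unif_rand();
  double e1[3], e2[3];
  if (std::fabs(d[2]) < 0.9) { e1[0] = -d[1]; e1[1] = d[0]; e1[2] = 0; }
  else { e1[0] = 1; e1[1] = 0; e1[2] = 0; }
  double dp = e1[0] * d[0] + e1[1] * d[1] + e1[2] * d[2];
  for (int i = 0; i < 3; ++i) e1[i] -= dp * d[i];
  double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int i = 0; i < 3; ++i) e1[i] /= n1;
  e2[0] = d[1] * e1[2] - d[2] * e1[1];
  e2[1] = d[2] * e1[0] - d[0] * e1[2];
  e2[2] = d[0] * e1[1] - d[1] * e1[0];
  double c = std::cos(phi), s = std::sin(phi);
  for (int i = 0; i < 3; ++i)
    d[i] = ct * d[i] + st * (c * e1[i] + s * e2[i]);
}

// ---- phantom transport ---------------------------------------------------

// [[Rcpp::export]]
List cpp_transport_phantom(NumericMatrix pos, NumericMatrix dir,
                           NumericVector energy, NumericMatrix prim,
                           int bg_mat, double rbound,
                           NumericMatrix mu_tab, NumericMatrix pe_tab,
                           NumericVector energies,
                           double e_cutoff, int max_scatter) {
  XS xs(mu_tab, pe_tab, energies);
  Phantom ph(prim, bg_mat, rbound);
  // materials present, for the majorant
  std::vector<int> mats;
  for (int i = 0; i < ph.k; ++i) mats.push_back((int)ph.P[i * 12 + 11] - 1);
  mats.push_back(bg_mat - 1);
  int n = pos.nrow();
  IntegerVector status(n), nscat(n);
  NumericMatrix opos(n, 3), odir(n, 3);
  NumericVector oen(n), opath(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double lastp[3] = {p[0], p[1], p[2]};
    double E = energy[i], path = 0, lastpath = 0;
    int ns = 0, st = 1; // 1 escaped, 0 absorbed
    for (;;) {
      double mumax = 0;
      for (size_t m = 0; m < mats.size(); ++m)
        mumax = std::max(mumax, xs.mu(mats[m], E));
      if (mumax <= 0) break; // pure vacuum: escapes unscathed
      bool done = false;
      for (;;) {
        double s = -std::log(unif_rand()) / mumax;
        for (int c = 0; c < 3; ++c) p[c] += s * d[c];
        path += s;
        double r2 = p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
        double pd = p[0] * d[0] + p[1] * d[1] + p[2] * d[2];
        if (r2 > rbound * rbound && pd > 0) { done = true; break; }
        int mat = ph.material(p);
        double mu = mat >= 0 ? xs.mu(mat, E) : 0.0;
        if (mu <= 0) continue;
        if (unif_rand() * mumax >= mu) continue; // virtual collision
        // real collision
        if (unif_rand() < xs.pe_frac(mat, E)) { st = 0; done = true; break; }
        double x = sample_kn_x(E);
        double ct = 1 - (x - 1) * 511.0 / E;
        E /= x;
        rotate_dir(d, ct);
        ++ns;
        for (int c = 0; c < 3; ++c) lastp[c] = p[c];
        lastpath = path;
        if (E < e_cutoff || ns > max_scatter) { st = 0; done = true; break; }
        break; // re-enter outer loop to refresh the majorant
      }
      if (done) break;
    }
    status[i] = st;
    nscat[i] = ns;
    oen[i] = E;
    opath[i] = lastpath;
    for (int c = 0; c < 3; ++c) { opos(i, c) = lastp[c]; odir(i, c) = d[c]; }
  }
  return List::create(_["status"] = status, _["pos"] = opos, _["dir"] = odir,
                      _["energy"] = oen, _["nscatter"] = nscat,
                      _["path"] = opath);
}

// ---- detector transport: flat panels ------------------------------------

// slab index axis/sign layout: 0:+X 1:-X 2:+Y 3:-Y
static bool slab_entry(int panel, const double* p, const double* d,
                       double sep2, double ext2, double clen,
                       double margin, double& t0) {
  double lo[3], hi[3];
  int ax = panel < 2 ? 0 : 1;
  double sgn = (panel % 2 == 0) ? 1.0 : -1.0;
  if (sgn > 0) { lo[ax] = sep2; hi[ax] = sep2 + clen; }
  else { lo[ax] = -sep2 - clen; hi[ax] = -sep2; }
  int oth = 1 - ax;
  lo[oth] = -ext2 - margin; hi[oth] = ext2 + margin;
  lo[2] = -ext2 - margin; hi[2] = ext2 + margin;
  double tmin = -1e30, tmax = 1e30;
  for (int c = 0; c < 3; ++c) {
    if (std::fabs(d[c]) < 1e-12) {
      if (p[c] < lo[c] || p[c] > hi[c]) return false;
    } else {
      double ta = (lo[c] - p[c]) / d[c], tb = (hi[c] - p[c]) / d[c];
      if (ta > tb) std::swap(ta, tb);
      tmin = std::max(tmin, ta); tmax = std::min(tmax, tb);
    }
  }
  if (tmax < std::max(tmin, 1e-9)) return false;
  t0 = std::max(tmin, 0.0);
  return true;
}

struct PanelGeom {
  int n_panels, n_side, per_panel;
  double sep2, ext2, pitch, cs, clen;
  // crystal test at point p inside slab of `panel`; returns flat 1-based id
  // or 0 if in a gap
  int crystal_at(int panel, const double* p) const {
    int ax = panel < 2 ? 0 : 1;
    double u = (ax == 0) ? p[1] : p[0]; // u axis: y for +-X, x for +-Y
    double v = p[2];
    if (std::fabs(u) > ext2 || std::fabs(v) > ext2) return 0;
    int col = (int)std::floor((u + ext2) / pitch);
    int row = (int)std::floor((v + ext2) / pitch);
    if (col < 0) col = 0; if (col >= n_side) col = n_side - 1;
    if (row < 0) row = 0; if (row >= n_side) row = n_side - 1;
    double uc = -ext2 + (col + 0.5) * pitch, vc = -ext2 + (row + 0.5) * pitch;
    if (std::fabs(u - uc) > cs / 2 || std::fabs(v - vc) > cs / 2) return 0;
    return panel * per_panel + row * n_side + col + 1;
  }
};

// [[Rcpp::export]]
List cpp_transport_panels(NumericMatrix pos, NumericMatrix dir,
                          NumericVector energy,
                          int n_panels, double separation, double extent,
                          double pitch, double cs, double clen,
                          NumericMatrix mu_tab, NumericMatrix pe_tab,
                          NumericVector energies, int lyso_mat,
                          double e_cutoff, int max_scatter) {
  XS xs(mu_tab, pe_tab, energies);
  PanelGeom g;
  g.n_panels = n_panels; g.sep2 = separation / 2; g.ext2 = extent / 2;
  g.pitch = pitch; g.cs = cs; g.clen = clen;
  g.n_side = (int)std::lround(extent / pitch);
  g.per_panel = g.n_side * g.n_side;
  int lm = lyso_mat - 1;
  int n = pos.nrow();
  std::vector<int> o_photon, o_crystal;
  std::vector<double> o_edep, o_path;
  NumericVector escaped(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double E = energy[i], path = 0;
    int ns = 0;
    bool alive = true;
    while (alive) {
      // find nearest slab ahead
      double tbest = 1e30; int pbest = -1;
      for (int pl = 0; pl < n_panels; ++pl) {
        double t0;
        if (slab_entry(pl, p, d, g.sep2, g.ext2, g.clen, 0.0, t0) && t0 < tbest) {
          tbest = t0; pbest = pl;
        }
      }
      if (pbest < 0) { escaped[i] = E; break; }
      for (int c = 0; c < 3; ++c) p[c] += (tbest + 1e-6) * d[c];
      path += tbest + 1e-6;
      int panel = pbest;
      double mumax = xs.mu(lm, E);
      // Woodcock inside this slab (gaps between sparse crystals are vacuum)
      for (;;) {
        double s = -std::log(unif_rand()) / mumax;
        for (int c = 0; c < 3; ++c) p[c] += s * d[c];
        path += s;
        // still inside slab?
        int ax = panel < 2 ? 0 : 1;
        double sgn = (panel % 2 == 0) ? 1.0 : -1.0;
        double depth = sgn * p[ax];
        if (depth < g.sep2 || depth > g.sep2 + g.clen ||
            std::fabs(p[1 - ax]) > g.ext2 || std::fabs(p[2]) > g.ext2)
          break; // left the slab; outer loop looks for the next one
        int cry = g.crystal_at(panel, p);
        if (cry == 0) continue;          // vacuum gap: virtual
        // in crystal: mu(x) == mumax, every tentative collision is real
        if (unif_rand() < xs.pe_frac(lm, E)) {
          o_photon.push_back(i); o_crystal.push_back(cry);
          o_edep.push_back(E); o_path.push_back(path);
          alive = false; break;
        }
        double x = sample_kn_x(E);
        double ct = 1 - (x - 1) * 511.0 / E;
        double Enew = E / x, edep = E - Enew;
        ++ns;
        if (Enew < e_cutoff || ns > max_scatter) {
          // absorb the remainder locally
          o_photon.push_back(i); o_crystal.push_back(cry);
          o_edep.push_back(edep + Enew); o_path.push_back(path);
          alive = false; break;
        }
        o_photon.push_back(i); o_crystal.push_back(cry);
        o_edep.push_back(edep); o_path.push_back(path);
        E = Enew;
        rotate_dir(d, ct);
        mumax = xs.mu(lm, E);
      }
      if (!alive) break;
    }
    if (alive && o_photon.empty()) {} // no-op; escaped already recorded above
  }
  return List::create(_["photon"] = IntegerVector(o_photon.begin(), o_photon.end()),
                      _["crystal"] = IntegerVector(o_crystal.begin(), o_crystal.end()),
                      _["edep"] = NumericVector(o_edep.begin(), o_edep.end()),
                      _["path"] = NumericVector(o_path.begin(), o_path.end()),
                      _["escaped_energy"] = escaped);
}

// does the line through p with direction +-d geometrically reach two
// detector slabs (with a safety margin for non-colinearity)?
// [[Rcpp::export]]
LogicalVector cpp_line_hits_panels(NumericMatrix pos, NumericMatrix dir,
                                   int n_panels, double separation,
                                   double extent, double clen, double margin) {
  int n = pos.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    bool fwd = false, bwd = false;
    double t0;
    for (int pl = 0; pl < n_panels && !fwd; ++pl)
      fwd = slab_entry(pl, p, d, separation / 2, extent / 2, clen, margin, t0);
    double dn[3] = {-d[0], -d[1], -d[2]};
    for (int pl = 0; pl < n_panels && !bwd; ++pl)
      bwd = slab_entry(pl, p, dn, separation / 2, extent / 2, clen, margin, t0);
    out[i] = fwd && bwd;
  }
  return out;
}

// ---- detector transport: reference ring ----------------------------------

struct RingGeom {
  double r_inner, clen, cs, axial_pitch, axial_fov, dphi;
  int nt, na;
  int crystal_at(const double* p) const {
    double phi = std::atan2(p[1], p[0]);
    if (phi < 0) phi += 2 * M_PI;
    int kt0 = (int)std::floor(phi / dphi);
    double rc = r_inner + clen / 2;
    for (int dk = -1; dk <= 1; ++dk) {
      int kt = ((kt0 + dk) % nt + nt) % nt;
      double phic = (kt + 0.5) * dphi;
      double cx = rc * std::cos(phic), cy = rc * std::sin(phic);
      double w1 = (p[0] - cx) * std::cos(phic) + (p[1] - cy) * std::sin(phic);
      double w2 = -(p[0] - cx) * std::sin(phic) + (p[1] - cy) * std::cos(phic);
      if (std::fabs(w1) > clen / 2 || std::fabs(w2) > cs / 2) continue;
      int ka = (int)std::floor((p[2] + axial_fov / 2) / axial_pitch);
      if (ka < 0 || ka >= na) continue;
      double zc = -axial_fov / 2 + (ka + 0.5) * axial_pitch;
      if (std::fabs(p[2] - zc) > cs / 2) continue;
      return kt * na + ka + 1;
    }
    return 0;
  }
};

// entry of ray into the region {r <= Ro, |z| <= z2}
static bool ring_entry(const double* p, const double* d, double Ro, double z2,
                       double& t0) {
  double tmin = 0, tmax = 1e30;
  if (std::fabs(d[2]) < 1e-12) {
    if (std::fabs(p[2]) > z2) return false;
  } else {
    double ta = (-z2 - p[2]) / d[2], tb = (z2 - p[2]) / d[2];
    if (ta > tb) std::swap(ta, tb);
    tmin = std::max(tmin, ta); tmax = std::min(tmax, tb);
  }
  double a = d[0] * d[0] + d[1] * d[1];
  double b = 2 * (p[0] * d[0] + p[1] * d[1]);
  double c = p[0] * p[0] + p[1] * p[1] - Ro * Ro;
  if (a < 1e-12) { if (c > 0) return false; }
  else {
    double disc = b * b - 4 * a * c;
    if (disc <= 0) return false;
    double sq = std::sqrt(disc);
    double ta = (-b - sq) / (2 * a), tb = (-b + sq) / (2 * a);
    tmin = std::max(tmin, ta); tmax = std::min(tmax, tb);
  }
  if (tmax < std::max(tmin, 1e-9)) return false;
  t0 = std::max(tmin, 0.0);
  return true;
}

// [[Rcpp::export]]
List cpp_transport_ring(NumericMatrix pos, NumericMatrix dir,
                        NumericVector energy,
                        double r_inner, double clen, double cs,
                        int nt, int na, double axial_fov,
                        NumericMatrix mu_tab, NumericMatrix pe_tab,
                        NumericVector energies, int lyso_mat,
                        double e_cutoff, int max_scatter) {
  XS xs(mu_tab, pe_tab, energies);
  RingGeom g;
  g.r_inner = r_inner; g.clen = clen; g.cs = cs; g.nt = nt; g.na = na;
  g.axial_fov = axial_fov; g.axial_pitch = axial_fov / na;
  g.dphi = 2 * M_PI / nt;
  double Ro = r_inner + clen, z2 = axial_fov / 2;
  int lm = lyso_mat - 1;
  int n = pos.nrow();
  std::vector<int> o_photon, o_crystal;
  std::vector<double> o_edep, o_path;
  NumericVector escaped(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double E = energy[i], path = 0;
    int ns = 0;
    bool alive = true;
    while (alive) {
      double t0;
      if (!ring_entry(p, d, Ro, z2, t0)) { escaped[i] = E; break; }
      for (int c = 0; c < 3; ++c) p[c] += (t0 + 1e-6) * d[c];
      path += t0 + 1e-6;
      double mumax = xs.mu(lm, E);
      for (;;) {
        double s = -std::log(unif_rand()) / mumax;
        for (int c = 0; c < 3; ++c) p[c] += s * d[c];
        path += s;
        double r2 = p[0] * p[0] + p[1] * p[1];
        if (r2 > Ro * Ro || std::fabs(p[2]) > z2) break; // left the region
        int cry = g.crystal_at(p);
        if (cry == 0) continue; // bore or inter-crystal gap: virtual
        if (unif_rand() < xs.pe_frac(lm, E)) {
          o_photon.push_back(i); o_crystal.push_back(cry);
          o_edep.push_back(E); o_path.push_back(path);
          alive = false; break;
        }
        double x = sample_kn_x(E);
        double ct = 1 - (x - 1) * 511.0 / E;
        double Enew = E / x, edep = E - Enew;
        ++ns;
        if (Enew < e_cutoff || ns > max_scatter) {
          o_photon.push_back(i); o_crystal.push_back(cry);
          o_edep.push_back(edep + Enew); o_path.push_back(path);
          alive = false; break;
        }
        o_photon.push_back(i); o_crystal.push_back(cry);
        o_edep.push_back(edep); o_path.push_back(path);
        E = Enew;
        rotate_dir(d, ct);
        mumax = xs.mu(lm, E);
      }
      if (!alive) break;
      // if we fell out of the region moving outward with no chance to
      // re-enter, ring_entry() will fail and record the escape
    }
  }
  return List::create(_["photon"] = IntegerVector(o_photon.begin(), o_photon.end()),
                      _["crystal"] = IntegerVector(o_crystal.begin(), o_crystal.end()),
                      _["edep"] = NumericVector(o_edep.begin(), o_edep.end()),
                      _["path"] = NumericVector(o_path.begin(), o_path.end()),
                      _["escaped_energy"] = escaped);
}

// [[Rcpp::export]]
LogicalVector cpp_line_hits_ring(NumericMatrix pos, NumericMatrix dir,
                                 double r_inner, double clen,
                                 double axial_fov, double margin) {
  int n = pos.nrow();
  LogicalVector out(n);
  double Ro = r_inner + clen, z2 = axial_fov / 2 + margin;
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double dn[3] = {-d[0], -d[1], -d[2]};
    double t0;
    out[i] = ring_entry(p, d, Ro, z2, t0) && ring_entry(p, dn, Ro, z2, t0);
  }
  return out;
}

// ---- emission sampler -----------------------------------------------------

// Draw n emission points with probability proportional to the local
// activity concentration: pick a primitive by concentration x gross
// volume, sample uniformly inside it, reject points covered by a later
// (overriding) primitive. `w` carries the cumulative selection weights.
// [[Rcpp::export]]
NumericMatrix cpp_sample_emission(int n, NumericMatrix prim, NumericVector cumw) {
  Phantom ph(prim, 1, 1e9);
  int k = ph.k;
  NumericMatrix out(n, 3);
  RNGScope scope;
  double wtot = cumw[k - 1];
  for (int r = 0; r < n; ++r) {
    for (;;) {
      double u = unif_rand() * wtot;
      int i = 0;
      while (i < k - 1 && cumw[i] < u) ++i;
      const double* P = &ph.P[i * 12];
      double p[3];
      int type = (int)P[0];
      if (type == 1) {
        double rr = P[4] * std::cbrt(unif_rand());
        double z = 2 * unif_rand() - 1, phi = 2 * M_PI * unif_rand();
        double s = std::sqrt(1 - z * z);
        p[0] = P[1] + rr * s * std::cos(phi);
        p[1] = P[2] + rr * s * std::sin(phi);
        p[2] = P[3] + rr * z;
      } else if (type == 2) {
        double rr = P[4] * std::sqrt(unif_rand());
        double phi = 2 * M_PI * unif_rand();
        double h = P[5] * (2 * unif_rand() - 1);
        // frame with e3 = axis
        double a0 = P[7], a1 = P[8], a2 = P[9];
        double e1[3];
        if (std::fabs(a2) < 0.9) { e1[0] = -a1; e1[1] = a0; e1[2] = 0; }
        else { e1[0] = 1; e1[1] = 0; e1[2] = 0; }
        double dp = e1[0] * a0 + e1[1] * a1 + e1[2] * a2;
        e1[0] -= dp * a0; e1[1] -= dp * a1; e1[2] -= dp * a2;
        double n1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
        e1[0] /= n1; e1[1] /= n1; e1[2] /= n1;
        double e2[3] = {a1 * e1[2] - a2 * e1[1], a2 * e1[0] - a0 * e1[2],
                        a0 * e1[1] - a1 * e1[0]};
        double c = rr * std::cos(phi), s = rr * std::sin(phi);
        p[0] = P[1] + c * e1[0] + s * e2[0] + h * a0;
        p[1] = P[2] + c * e1[1] + s * e2[1] + h * a1;
        p[2] = P[3] + c * e1[2] + s * e2[2] + h * a2;
      } else {
        p[0] = P[1] + P[4] * (2 * unif_rand() - 1);
        p[1] = P[2] + P[5] * (2 * unif_rand() - 1);
        p[2] = P[3] + P[6] * (2 * unif_rand() - 1);
      }
      bool covered = false;
      for (int j = i + 1; j < k && !covered; ++j)
        covered = ph.inside(j, p);
      if (covered) continue;
      out(r, 0) = p[0]; out(r, 1) = p[1]; out(r, 2) = p[2];
      break;
    }
  }
  return out;
}

// ---- voxelizer ------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_voxelize(NumericMatrix prim, NumericVector origin,
                           double voxel, IntegerVector dim, int ss) {
  Phantom ph(prim, 1, 1e9);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double step = voxel / ss, off = step / 2;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int a = 0; a < ss; ++a)
          for (int b = 0; b < ss; ++b)
            for (int c = 0; c < ss; ++c) {
              double p[3] = {origin[0] + i * voxel + off + a * step,
                             origin[1] + j * voxel + off + b * step,
                             origin[2] + k * voxel + off + c * step};
              for (int q = ph.k - 1; q >= 0; --q)
                if (ph.inside(q, p)) { acc += ph.P[q * 12 + 10]; break; }
            }
        // column-major order matches R arrays: index i + nx*(j + ny*k)
        out[(R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = acc / (ss * ss * ss);
        (void)idx;
      }
  return out;
}
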