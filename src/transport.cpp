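// Photon transport and projection kernels.
//
// Conventions (shared with the R layer):
//  * right-handed frame, isocenter at origin, rotation axis = z
//  * at gantry angle 0 the source sits on +y; detector u axis = +x, v = +z
//  * voxel grids are column-major (x fastest), origin = corner of voxel (0,0,0)
//  * cross-section tables live on a uniform energy grid (keV), mass
//    attenuation coefficients in cm^2/g; linear attenuation = rho * (mu/rho)
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double ELECTRON_REST_KEV = 510.998928;

// ---------------------------------------------------------------------------
// counter-based RNG: splitmix64 seeded xoshiro128+, one stream per history
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed into state
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      t = t ^ (t >> 31);
      if (i == 0) s0 = t; else s1 = t;
    }
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  inline double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

static inline uint64_t mix_seed(uint64_t base, uint64_t k) {
  uint64_t z = base * 0x9e3779b97f4a7c15ULL + k;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// ---------------------------------------------------------------------------
// cross-section lookup (linear interpolation on the uniform energy grid)
// ---------------------------------------------------------------------------
struct XsTable {
  const double *photo, *incoh, *coh, *total; // nE x nmat, column-major
  int nE, nmat;
  double E0, dE;
  inline double at(const double *tab, double E, int m) const {
    double f = (E - E0) / dE;
    if (f <= 0.0) f = 0.0;
    if (f >= nE - 1) f = nE - 1 - 1e-9;
    int i = (int)f;
    double w = f - i;
    const double *col = tab + (size_t)m * nE;
    return col[i] * (1.0 - w) + col[i + 1] * w;
  }
};

// phantom on a regular grid
struct Grid {
  const double *rho;   // g/cm3
  const int *mat;      // 0-based material index
  int nx, ny, nz;
  double dx, dy, dz;   // cm
  double ox, oy, oz;   // corner, cm
  inline size_t idx(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
  }
};

// clip segment p + t*d, t in [t0,t1], to the grid AABB; returns false if miss
static bool clip_aabb(const Grid &g, const double p[3], const double d[3],
                      double &t0, double &t1) {
  double lo[3] = {g.ox, g.oy, g.oz};
  double hi[3] = {g.ox + g.nx * g.dx, g.oy + g.ny * g.dy, g.oz + g.nz * g.dz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      if (p[a] < lo[a] || p[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - p[a]) / d[a], tb = (hi[a] - p[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 >= t1) return false;
    }
  }
  return true;
}

// Siddon-style traversal accumulating rho-weighted path length per material
static void ray_rho_path(const Grid &g, const double p0[3], const double p1[3],
                         std::vector<double> &rho_path) {
  std::fill(rho_path.begin(), rho_path.end(), 0.0);
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (len <= 0) return;
  double t0 = 0.0, t1 = 1.0;
  if (!clip_aabb(g, p0, d, t0, t1)) return;
  // entry point, voxel indices
  double eps = 1e-12;
  double t = t0 + eps;
  double px = p0[0] + t * d[0], py = p0[1] + t * d[1], pz = p0[2] + t * d[2];
  int i = (int)std::floor((px - g.ox) / g.dx);
  int j = (int)std::floor((py - g.oy) / g.dy);
  int k = (int)std::floor((pz - g.oz) / g.dz);
  if (i < 0) i = 0; if (i >= g.nx) i = g.nx - 1;
  if (j < 0) j = 0; if (j >= g.ny) j = g.ny - 1;
  if (k < 0) k = 0; if (k >= g.nz) k = g.nz - 1;
  int si = d[0] > 0 ? 1 : -1, sj = d[1] > 0 ? 1 : -1, sk = d[2] > 0 ? 1 : -1;
  double inf = std::numeric_limits<double>::infinity();
  double tdx = std::fabs(d[0]) > 1e-14 ? g.dx / std::fabs(d[0]) : inf;
  double tdy = std::fabs(d[1]) > 1e-14 ? g.dy / std::fabs(d[1]) : inf;
  double tdz = std::fabs(d[2]) > 1e-14 ? g.dz / std::fabs(d[2]) : inf;
  // parametric t of next crossing along each axis
  double tx = std::fabs(d[0]) > 1e-14
      ? ((g.ox + (i + (si > 0 ? 1 : 0)) * g.dx) - p0[0]) / d[0] : inf;
  double ty = std::fabs(d[1]) > 1e-14
      ? ((g.oy + (j + (sj > 0 ? 1 : 0)) * g.dy) - p0[1]) / d[1] : inf;
  double tz = std::fabs(d[2]) > 1e-14
      ? ((g.oz + (k + (sk > 0 ? 1 : 0)) * g.dz) - p0[2]) / d[2] : inf;
  double tc = t0;
  while (tc < t1 - eps) {
    double tn = std::min(std::min(tx, ty), std::min(tz, t1));
    double seg = (tn - tc) * len;
    if (seg > 0) {
      size_t v = g.idx(i, j, k);
      rho_path[g.mat[v]] += seg * g.rho[v];
    }
    tc = tn;
    if (tx <= ty && tx <= tz) { i += si; tx += tdx; if (i < 0 || i >= g.nx) break; }
    else if (ty <= tz)        { j += sj; ty += tdy; if (j < 0 || j >= g.ny) break; }
    else                      { k += sk; tz += tdz; if (k < 0 || k >= g.nz) break; }
  }
}

static inline double tau_from_path(const XsTable &xs,
                                   const std::vector<double> &rho_path,
                                   double E) {
  double tau = 0.0;
  for (int m = 0; m < xs.nmat; ++m)
    if (rho_path[m] > 0) tau += rho_path[m] * xs.at(xs.total, E, m);
  return tau;
}

// ---------------------------------------------------------------------------
// detector description for a single projection angle
// ---------------------------------------------------------------------------
struct Det {
  double src[3];
  double corner[3];     // physical position of pixel (0,0) corner
  double uhat[3], vhat[3], nhat[3]; // nhat points from detector towards source
  double du, dv;        // pixel pitch, cm
  int nu, nv;
  inline void pixel_center(int iu, int iv, double out[3]) const {
    for (int a = 0; a < 3; ++a)
      out[a] = corner[a] + (iu + 0.5) * du * uhat[a] + (iv + 0.5) * dv * vhat[a];
  }
  inline void point(double fu, double fv, double out[3]) const {
    for (int a = 0; a < 3; ++a)
      out[a] = corner[a] + fu * du * uhat[a] + fv * dv * vhat[a];
  }
};

static Det make_det(NumericVector src, NumericVector corner, NumericVector uhat,
                    NumericVector vhat, double du, double dv, int nu, int nv) {
  Det d;
  for (int a = 0; a < 3; ++a) {
    d.src[a] = src[a]; d.corner[a] = corner[a];
    d.uhat[a] = uhat[a]; d.vhat[a] = vhat[a];
  }
  // normal = uhat x vhat, oriented towards the source
  d.nhat[0] = d.uhat[1] * d.vhat[2] - d.uhat[2] * d.vhat[1];
  d.nhat[1] = d.uhat[2] * d.vhat[0] - d.uhat[0] * d.vhat[2];
  d.nhat[2] = d.uhat[0] * d.vhat[1] - d.uhat[1] * d.vhat[0];
  double dot = 0;
  for (int a = 0; a < 3; ++a) dot += d.nhat[a] * (d.src[a] - d.corner[a]);
  if (dot < 0) for (int a = 0; a < 3; ++a) d.nhat[a] = -d.nhat[a];
  d.du = du; d.dv = dv; d.nu = nu; d.nv = nv;
  return d;
}

static Grid make_grid(NumericVector rho, IntegerVector mat, IntegerVector dims,
                      NumericVector voxel, NumericVector origin) {
  Grid g;
  g.rho = rho.begin(); g.mat = mat.begin();
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.dx = voxel[0]; g.dy = voxel[1]; g.dz = voxel[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  return g;
}

static XsTable make_xs(NumericMatrix photo, NumericMatrix incoh,
                       NumericMatrix coh, NumericMatrix total,
                       double E0, double dE) {
  XsTable xs;
  xs.photo = photo.begin(); xs.incoh = incoh.begin();
  xs.coh = coh.begin(); xs.total = total.begin();
  xs.nE = total.nrow(); xs.nmat = total.ncol();
  xs.E0 = E0; xs.dE = dE;
  return xs;
}

// geometric factor for a detector point: cos(theta) * A_det / r^2, and r
static inline double geom_factor(const Det &d, const double pos[3],
                                 const double pt[3], double &r) {
  double dir[3] = {pt[0] - pos[0], pt[1] - pos[1], pt[2] - pos[2]};
  r = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  double c = -(dir[0] * d.nhat[0] + dir[1] * d.nhat[1] + dir[2] * d.nhat[2]) / r;
  if (c < 0) c = -c;
  double A = d.nu * d.du * d.nv * d.dv;
  return c * A / (r * r);
}

// ---------------------------------------------------------------------------
// deterministic primary + blank (Siddon ray tracing)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_project_siddon(NumericVector rho, IntegerVector mat, IntegerVector dims,
                        NumericVector voxel, NumericVector origin,
                        NumericMatrix xs_photo, NumericMatrix xs_incoh,
                        NumericMatrix xs_coh, NumericMatrix xs_total,
                        double E0, double dE,
                        NumericVector spec_E, NumericVector spec_w,
                        NumericVector src, NumericVector corner,
                        NumericVector uhat, NumericVector vhat,
                        double du, double dv, int nu, int nv, int n_sub) {
  Grid g = make_grid(rho, mat, dims, voxel, origin);
  XsTable xs = make_xs(xs_photo, xs_incoh, xs_coh, xs_total, E0, dE);
  Det det = make_det(src, corner, uhat, vhat, du, dv, nu, nv);
  int nE = spec_E.size();
  NumericMatrix primary(nu, nv), blank(nu, nv);
  std::vector<double> rp(xs.nmat);
  double pixA = du * dv, detA = nu * du * nv * dv;
  for (int iv = 0; iv < nv; ++iv) {
    for (int iu = 0; iu < nu; ++iu) {
      double P = 0.0, B = 0.0;
      for (int s = 0; s < n_sub * n_sub; ++s) {
        double fu = iu + ((s % n_sub) + 0.5) / n_sub;
        double fv = iv + ((s / n_sub) + 0.5) / n_sub;
        double pt[3];
        det.point(fu, fv, pt);
        double r;
        double gf = geom_factor(det, det.src, pt, r); // cos * A_det / r^2
        ray_rho_path(g, det.src, pt, rp);
        for (int e = 0; e < nE; ++e) {
          double b = spec_w[e] * spec_E[e] * gf * pixA / detA;
          B += b;
          P += b * std::exp(-tau_from_path(xs, rp, spec_E[e]));
        }
      }
      primary(iu, iv) = P / (n_sub * n_sub);
      blank(iu, iv) = B / (n_sub * n_sub);
    }
  }
  return List::create(_["primary"] = primary, _["blank"] = blank);
}

// ---------------------------------------------------------------------------
// Compton (free-electron Klein-Nishina) helpers
// ---------------------------------------------------------------------------
static inline double kn_total(double E) { // per electron, units of 2*pi*re^2
  double k = E / ELECTRON_REST_KEV;
  double a = (1.0 + k) / (k * k) *
             (2.0 * (1.0 + k) / (1.0 + 2.0 * k) - std::log(1.0 + 2.0 * k) / k);
  double b = std::log(1.0 + 2.0 * k) / (2.0 * k);
  double c = (1.0 + 3.0 * k) / ((1.0 + 2.0 * k) * (1.0 + 2.0 * k));
  return a + b - c;
}

// angular pdf over solid angle for KN scattering, integrates to 1 over sphere
static inline double kn_pdf_omega(double E, double cth) {
  double k = E / ELECTRON_REST_KEV;
  double eps = 1.0 / (1.0 + k * (1.0 - cth)); // E'/E
  double s2 = 1.0 - cth * cth;
  double dsdo = 0.5 * eps * eps * (eps + 1.0 / eps - s2); // units re^2
  return dsdo / (2.0 * M_PI * kn_total(E));
}

// Kahn-style sampling of the scattered-photon energy fraction eps = E'/E
static inline double kn_sample_eps(Rng &rng, double E) {
  double k = E / ELECTRON_REST_KEV;
  double e0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = std::log(1.0 / e0), a2 = 0.5 * (1.0 - e0 * e0);
  for (int it = 0; it < 10000; ++it) {
    double eps;
    if (rng.unif() < a1 / (a1 + a2)) eps = e0 * std::exp(a1 * rng.unif());
    else eps = std::sqrt(e0 * e0 + (1.0 - e0 * e0) * rng.unif());
    double t = (1.0 - eps) / (k * eps);
    double cth = 1.0 - t;
    double s2 = 1.0 - cth * cth;
    if (rng.unif() <= 1.0 - eps * s2 / (1.0 + eps * eps)) return eps;
  }
  return 1.0;
}

// ---------------------------------------------------------------------------
// Rayleigh: normalized squared form factor per material on an x grid (A^-1)
// ---------------------------------------------------------------------------
struct FfTable {
  const double *x, *ff2; // ff2: nx x nmat
  int nx, nmat;
  inline double at(double xx, int m) const {
    const double *col = ff2 + (size_t)m * nx;
    if (xx <= x[0]) return col[0];
    if (xx >= x[nx - 1]) return col[nx - 1];
    int lo = 0, hi = nx - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (x[mid] <= xx) lo = mid; else hi = mid; }
    double w = (xx - x[lo]) / (x[hi] - x[lo]);
    return col[lo] * (1.0 - w) + col[hi] * w;
  }
};

static inline double mom_transfer(double E, double cth) { // sin(th/2)/lambda, A^-1
  double s = std::sqrt(std::max(0.0, 0.5 * (1.0 - cth)));
  return E / 12.398420 * s;
}

// angular density f(c) over cos(theta) in [-1,1]: (1+c^2)/2 * FF2 / norm
static double rayleigh_norm(const FfTable &ff, double E, int m) {
  const int N = 128;
  double h = 2.0 / N, sum = 0.0;
  for (int i = 0; i <= N; ++i) {
    double c = -1.0 + i * h;
    double f = 0.5 * (1.0 + c * c) * ff.at(mom_transfer(E, c), m);
    sum += (i == 0 || i == N) ? 0.5 * f : f;
  }
  return sum * h;
}

// ---------------------------------------------------------------------------
// direction utilities
// ---------------------------------------------------------------------------
static inline void rotate_direction(const double d[3], double cth, double phi,
                                    double out[3]) {
  // rotate unit vector d by polar angle acos(cth), azimuth phi
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double a[3], b[3];
  if (std::fabs(d[2]) < 0.99) { a[0] = -d[1]; a[1] = d[0]; a[2] = 0.0; }
  else { a[0] = 0.0; a[1] = -d[2]; a[2] = d[1]; }
  double an = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
  for (int i = 0; i < 3; ++i) a[i] /= an;
  b[0] = d[1] * a[2] - d[2] * a[1];
  b[1] = d[2] * a[0] - d[0] * a[2];
  b[2] = d[0] * a[1] - d[1] * a[0];
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int i = 0; i < 3; ++i)
    out[i] = cth * d[i] + sth * (cp * a[i] + sp * b[i]);
}

// ---------------------------------------------------------------------------
// Monte Carlo projection: primary (forced at the sampled entry pixel) and
// scatter via forced detection at each interaction; splitting + Russian
// roulette; Woodcock delta tracking; optional isotropic path stretching.
// ---------------------------------------------------------------------------
struct Photon {
  double pos[3], dir[3];
  double E, w;
  int ninter; // interactions undergone so far
};

// [[Rcpp::export]]
List cpp_simulate_projection(NumericVector rho, IntegerVector mat,
                             IntegerVector dims, NumericVector voxel,
                             NumericVector origin,
                             NumericMatrix xs_photo, NumericMatrix xs_incoh,
                             NumericMatrix xs_coh, NumericMatrix xs_total,
                             double E0, double dE,
                             NumericVector ffx, NumericMatrix ff2,
                             NumericVector spec_E, NumericVector spec_w,
                             NumericVector src, NumericVector corner,
                             NumericVector uhat, NumericVector vhat,
                             double du, double dv, int nu, int nv,
                             int n_hist, int n_split, int rr_factor,
                             double path_stretch, bool coherent,
                             double cutoff, double seed_d, int n_batch) {
  Grid g = make_grid(rho, mat, dims, voxel, origin);
  XsTable xs = make_xs(xs_photo, xs_incoh, xs_coh, xs_total, E0, dE);
  Det det = make_det(src, corner, uhat, vhat, du, dv, nu, nv);
  FfTable ff; ff.x = ffx.begin(); ff.ff2 = ff2.begin();
  ff.nx = ffx.size(); ff.nmat = ff2.ncol();
  uint64_t seed = (uint64_t)seed_d;
  int nE = spec_E.size();
  // cumulative spectrum weights
  std::vector<double> cw(nE);
  double acc = 0;
  for (int e = 0; e < nE; ++e) { acc += spec_w[e]; cw[e] = acc; }
  for (int e = 0; e < nE; ++e) cw[e] /= acc;
  // per-material max density (for the Woodcock majorant)
  std::vector<double> rho_max(xs.nmat, 0.0);
  size_t nvox = (size_t)g.nx * g.ny * g.nz;
  for (size_t v = 0; v < nvox; ++v)
    if (rho[v] > rho_max[mat[v]]) rho_max[mat[v]] = rho[v];
  // Rayleigh normalization on a coarse energy grid per material
  int nEc = 29;
  double Ec0 = xs.E0, dEc = (xs.E0 + (xs.nE - 1) * xs.dE - Ec0) / (nEc - 1);
  std::vector<double> rnorm((size_t)nEc * xs.nmat);
  if (coherent)
    for (int m = 0; m < xs.nmat; ++m)
      for (int e = 0; e < nEc; ++e)
        rnorm[(size_t)m * nEc + e] = rayleigh_norm(ff, Ec0 + e * dEc, m);
  auto rnorm_at = [&](double E, int m) {
    double f = (E - Ec0) / dEc;
    if (f < 0) f = 0; if (f > nEc - 1) f = nEc - 1;
    int i = (int)f; if (i > nEc - 2) i = nEc - 2;
    double w = f - i;
    return rnorm[(size_t)m * nEc + i] * (1 - w) + rnorm[(size_t)m * nEc + i + 1] * w;
  };

  size_t npix = (size_t)nu * nv;
  std::vector<double> bat_p((size_t)n_batch * npix, 0.0);
  std::vector<double> bat_s((size_t)n_batch * npix, 0.0);
  double tot_sum = 0.0, tot_sumsq = 0.0; // per-history scatter totals
  double wmin = R_PosInf, wmax = 0.0;    // scored weight / w0, per FD score
  long n_scored = 0;
  bool energy_increase = false;
  std::vector<double> rp(xs.nmat);
  double detA = nu * du * nv * dv;

  for (int h = 0; h < n_hist; ++h) {
    Rng rng(mix_seed(seed, (uint64_t)h));
    int b = h % n_batch;
    // source energy
    double u0 = rng.unif();
    int e = 0; while (e < nE - 1 && cw[e] < u0) ++e;
    double E = spec_E[e];
    // aim point uniform over the detector
    double fu = rng.unif() * nu, fv = rng.unif() * nv;
    double pt[3]; det.point(fu, fv, pt);
    double r;
    double w0 = geom_factor(det, det.src, pt, r); // cos * A_det / r^2
    // forced primary score at the entry pixel
    ray_rho_path(g, det.src, pt, rp);
    double tau0 = tau_from_path(xs, rp, E);
    int pu = (int)fu, pv = (int)fv;
    if (pu >= nu) pu = nu - 1; if (pv >= nv) pv = nv - 1;
    bat_p[(size_t)b * npix + pu + (size_t)nu * pv] += w0 * E * std::exp(-tau0);

    // analog transport for scatter
    double hist_scatter = 0.0;
    std::vector<Photon> stack;
    Photon p0;
    for (int a = 0; a < 3; ++a) {
      p0.pos[a] = det.src[a];
      p0.dir[a] = (pt[a] - det.src[a]) / r;
    }
    p0.E = E; p0.w = w0; p0.ninter = 0;
    stack.push_back(p0);
    while (!stack.empty()) {
      Photon ph = stack.back();
      stack.pop_back();
      bool alive = true;
      while (alive) {
        // Woodcock majorant at current energy
        double mu_max = 0.0;
        for (int m = 0; m < xs.nmat; ++m) {
          double mm = rho_max[m] * xs.at(xs.total, ph.E, m);
          if (mm > mu_max) mu_max = mm;
        }
        if (mu_max <= 0) break;
        // advance to the grid if outside it
        double t0 = 0.0, t1 = 1e30;
        if (!clip_aabb(g, ph.pos, ph.dir, t0, t1)) break;
        if (t0 > 0) { for (int a = 0; a < 3; ++a) ph.pos[a] += t0 * ph.dir[a]; t1 -= t0; }
        double mu_s = mu_max / (1.0 + path_stretch);
        double s = -std::log(rng.unif()) / mu_s;
        if (path_stretch > 0)
          ph.w *= (1.0 + path_stretch) *
                  std::exp(-mu_max * s * path_stretch / (1.0 + path_stretch));
        if (s >= t1) break; // escapes the grid
        for (int a = 0; a < 3; ++a) ph.pos[a] += s * ph.dir[a];
        int ix = (int)std::floor((ph.pos[0] - g.ox) / g.dx);
        int iy = (int)std::floor((ph.pos[1] - g.oy) / g.dy);
        int iz = (int)std::floor((ph.pos[2] - g.oz) / g.dz);
        if (ix < 0 || ix >= g.nx || iy < 0 || iy >= g.ny || iz < 0 || iz >= g.nz)
          break;
        size_t v = g.idx(ix, iy, iz);
        int m = g.mat[v];
        double mu_loc = g.rho[v] * xs.at(xs.total, ph.E, m);
        if (rng.unif() * mu_max >= mu_loc) continue; // fictitious interaction
        // real interaction: choose channel
        double xp = xs.at(xs.photo, ph.E, m);
        double xi = xs.at(xs.incoh, ph.E, m);
        double xc = coherent ? xs.at(xs.coh, ph.E, m) : 0.0;
        double xt = xp + xi + xc;
        double uch = rng.unif() * xt;
        if (uch < xp) { alive = false; break; } // photoelectric absorption
        bool compton = (uch < xp + xi);
        int msplit = (ph.ninter == 0) ? n_split : rr_factor;
        // forced detection: msplit sampled detector points
        for (int jj = 0; jj < msplit; ++jj) {
          double gu = rng.unif() * nu, gv = rng.unif() * nv;
          double q[3]; det.point(gu, gv, q);
          double rr2;
          double gf = geom_factor(det, ph.pos, q, rr2);
          double dq[3] = {(q[0] - ph.pos[0]) / rr2, (q[1] - ph.pos[1]) / rr2,
                          (q[2] - ph.pos[2]) / rr2};
          double cth = ph.dir[0] * dq[0] + ph.dir[1] * dq[1] + ph.dir[2] * dq[2];
          double Eout, pdf;
          if (compton) {
            double k = ph.E / ELECTRON_REST_KEV;
            Eout = ph.E / (1.0 + k * (1.0 - cth));
            pdf = kn_pdf_omega(ph.E, cth);
          } else {
            Eout = ph.E;
            pdf = 0.5 * (1.0 + cth * cth) *
                  ff.at(mom_transfer(ph.E, cth), m) /
                  (2.0 * M_PI * rnorm_at(ph.E, m));
          }
          if (Eout < cutoff) continue;
          ray_rho_path(g, ph.pos, q, rp);
          double tau = tau_from_path(xs, rp, Eout);
          double wsc = ph.w / msplit;
          double contrib = wsc * pdf * gf * Eout * std::exp(-tau);
          int qu = (int)gu, qv = (int)gv;
          if (qu >= nu) qu = nu - 1; if (qv >= nv) qv = nv - 1;
          bat_s[(size_t)b * npix + qu + (size_t)nu * qv] += contrib;
          hist_scatter += contrib;
          double wrel = wsc / w0;
          if (wrel < wmin) wmin = wrel;
          if (wrel > wmax) wmax = wrel;
          ++n_scored;
        }
        // continuation daughters with Russian roulette
        for (int jj = 0; jj < msplit; ++jj) {
          if (rng.unif() * rr_factor >= 1.0) continue;
          double cth, Eout;
          if (compton) {
            double eps = kn_sample_eps(rng, ph.E);
            double k = ph.E / ELECTRON_REST_KEV;
            cth = 1.0 - (1.0 / eps - 1.0) / k;
            Eout = eps * ph.E;
          } else {
            // rejection against the Thomson shape times FF^2
            int it = 0; cth = 1.0;
            for (; it < 2000; ++it) {
              double c = 2.0 * rng.unif() - 1.0;
              if (rng.unif() > 0.5 * (1.0 + c * c)) continue;
              if (rng.unif() <= ff.at(mom_transfer(ph.E, c), m)) { cth = c; break; }
            }
            Eout = ph.E;
          }
          if (Eout > ph.E + 1e-9) energy_increase = true;
          if (Eout < cutoff) continue;
          Photon d2;
          double nd[3];
          rotate_direction(ph.dir, cth, 2.0 * M_PI * rng.unif(), nd);
          for (int a = 0; a < 3; ++a) { d2.pos[a] = ph.pos[a]; d2.dir[a] = nd[a]; }
          d2.E = Eout;
          d2.w = ph.w * (double)rr_factor / msplit;
          d2.ninter = ph.ninter + 1;
          stack.push_back(d2);
        }
        alive = false; // parent consumed by the split
      }
    }
    tot_sum += hist_scatter;
    tot_sumsq += hist_scatter * hist_scatter;
  }

  // combine batches into mean and relative standard error
  NumericMatrix prim(nu, nv), prim_rel(nu, nv), scat(nu, nv), scat_rel(nu, nv);
  std::vector<int> bn(n_batch, 0);
  for (int h = 0; h < n_hist; ++h) bn[h % n_batch]++;
  for (size_t px = 0; px < npix; ++px) {
    double mp = 0, ms = 0;
    std::vector<double> pb(n_batch), sb(n_batch);
    for (int b2 = 0; b2 < n_batch; ++b2) {
      pb[b2] = bat_p[(size_t)b2 * npix + px] / bn[b2];
      sb[b2] = bat_s[(size_t)b2 * npix + px] / bn[b2];
      mp += pb[b2]; ms += sb[b2];
    }
    mp /= n_batch; ms /= n_batch;
    double vp = 0, vs = 0;
    for (int b2 = 0; b2 < n_batch; ++b2) {
      vp += (pb[b2] - mp) * (pb[b2] - mp);
      vs += (sb[b2] - ms) * (sb[b2] - ms);
    }
    vp /= (double)n_batch * (n_batch - 1);
    vs /= (double)n_batch * (n_batch - 1);
    prim[px] = mp; scat[px] = ms;
    prim_rel[px] = mp > 0 ? std::sqrt(vp) / mp : 0.0;
    scat_rel[px] = ms > 0 ? std::sqrt(vs) / ms : 0.0;
  }
  double tmean = tot_sum / n_hist;
  double tvar = (tot_sumsq - n_hist * tmean * tmean) / ((double)n_hist - 1);
  double tse = std::sqrt(std::max(0.0, tvar) / n_hist);
  return List::create(
      _["primary"] = prim, _["primary_rel"] = prim_rel,
      _["scatter"] = scat, _["scatter_rel"] = scat_rel,
      _["total_scatter_mean"] = tmean, _["total_scatter_se"] = tse,
      _["n_scored"] = (double)n_scored,
      _["scored_wrel_min"] = wmin, _["scored_wrel_max"] = wmax,
      _["energy_increase"] = energy_increase);
}

// ---------------------------------------------------------------------------
// Woodcock free-path sampler sharing the engine's RNG (for distribution tests)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_woodcock_free_paths(int n, double mu_max, double seed_d) {
  if (mu_max <= 0) stop("mu_max must be positive");
  NumericVector out(n);
  Rng rng(mix_seed((uint64_t)seed_d, 0x5eedULL));
  for (int i = 0; i < n; ++i) out[i] = -std::log(rng.unif()) / mu_max;
  return out;
}

// ---------------------------------------------------------------------------
// FDK: row filtering with the Shepp-Logan kernel and voxel backprojection
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_fdk_filter(NumericVector proj, int nu, int nv, int na,
                             double du) {
  // proj laid out (u, v, angle); returns du * (h_SL conv rows)
  NumericVector out((R_xlen_t)nu * nv * na);
  std::vector<double> h(2 * nu - 1);
  for (int n = -(nu - 1); n <= nu - 1; ++n)
    h[n + nu - 1] = -2.0 / (M_PI * M_PI * du * du * (4.0 * n * n - 1.0));
  for (int a = 0; a < na; ++a) {
    for (int v = 0; v < nv; ++v) {
      const double *row = proj.begin() + (size_t)a * nu * nv + (size_t)v * nu;
      double *orow = out.begin() + (size_t)a * nu * nv + (size_t)v * nu;
      for (int u = 0; u < nu; ++u) {
        double s = 0;
        for (int up = 0; up < nu; ++up) s += h[u - up + nu - 1] * row[up];
        orow[u] = s * du;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector filt, int nu, int nv, int na,
                                  NumericVector angles_rad, double sad,
                                  double du, double dv,
                                  IntegerVector dims, NumericVector voxel,
                                  NumericVector origin, double dlambda) {
  // filt laid out (u, v, angle); u,v are virtual-detector coords with pitch
  // du,dv (cm at the isocenter plane), pixel centers at (i+0.5-n/2)*pitch
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  for (int a = 0; a < na; ++a) {
    double lam = angles_rad[a];
    double sl = std::sin(lam), cl = std::cos(lam);
    // source at SAD*(-sl, cl, 0); chat = (sl,-cl,0); uhat=(cl,sl,0); vhat=z
    const double *F = filt.begin() + (size_t)a * nu * nv;
    for (int k = 0; k < nz; ++k) {
      double z = origin[2] + (k + 0.5) * voxel[2];
      for (int j = 0; j < ny; ++j) {
        double y = origin[1] + (j + 0.5) * voxel[1];
        for (int i = 0; i < nx; ++i) {
          double x = origin[0] + (i + 0.5) * voxel[0];
          double dx = x + sad * sl, dy = y - sad * cl, dz2 = z;
          double U = dx * sl - dy * cl;
          if (U <= 1e-6) continue;
          double uu = sad * (dx * cl + dy * sl) / U;
          double vv = sad * dz2 / U;
          double fu = uu / du + 0.5 * nu - 0.5;
          double fv = vv / dv + 0.5 * nv - 0.5;
          if (fu < 0 || fu > nu - 1 || fv < 0 || fv > nv - 1) continue;
          int iu = (int)fu, ivx = (int)fv;
          if (iu > nu - 2) iu = nu - 2;
          if (ivx > nv - 2) ivx = nv - 2;
          double wu = fu - iu, wv = fv - ivx;
          double q = (1 - wu) * (1 - wv) * F[iu + (size_t)nu * ivx] +
                     wu * (1 - wv) * F[iu + 1 + (size_t)nu * ivx] +
                     (1 - wu) * wv * F[iu + (size_t)nu * (ivx + 1)] +
                     wu * wv * F[iu + 1 + (size_t)nu * (ivx + 1)];
          vol[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] +=
              dlambda * sad * sad / (U * U) * q;
        }
      }
    }
  }
  return vol;
}

// ---------------------------------------------------------------------------
// small image utilities
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_conv2_same(NumericMatrix img, NumericMatrix kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = kernel.nrow(), kc = kernel.ncol();
  int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0, wsum = 0;
      for (int b = 0; b < kc; ++b) {
        int jj = j + b - hc;
        if (jj < 0 || jj >= nc) continue;
        for (int a = 0; a < kr; ++a) {
          int ii = i + a - hr;
          if (ii < 0 || ii >= nr) continue;
          s += kernel(a, b) * img(ii, jj);
          wsum += kernel(a, b);
        }
      }
      // renormalize at borders so constants are preserved
      double ktot = 0;
      for (int b = 0; b < kc; ++b) for (int a = 0; a < kr; ++a) ktot += kernel(a, b);
      out(i, j) = (wsum != 0.0) ? s * (ktot / wsum) : s;
    }
  return out;
}

static inline double cubic_w(double t) { // Catmull-Rom
  double at = std::fabs(t);
  if (at <= 1.0) return 1.0 - 2.5 * at * at + 1.5 * at * at * at;
  if (at < 2.0) return 2.0 - 4.0 * at + 2.5 * at * at - 0.5 * at * at * at;
  return 0.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_bicubic(NumericMatrix img, int nr2, int nc2) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr2, nc2);
  for (int j2 = 0; j2 < nc2; ++j2) {
    double fj = (j2 + 0.5) * nc / (double)nc2 - 0.5;
    int j0 = (int)std::floor(fj);
    for (int i2 = 0; i2 < nr2; ++i2) {
      double fi = (i2 + 0.5) * nr / (double)nr2 - 0.5;
      int i0 = (int)std::floor(fi);
      double s = 0, wsum = 0;
      for (int b = -1; b <= 2; ++b) {
        int jj = j0 + b;
        if (jj < 0) jj = 0; if (jj >= nc) jj = nc - 1;
        double wj = cubic_w(fj - (j0 + b));
        for (int a = -1; a <= 2; ++a) {
          int ii = i0 + a;
          if (ii < 0) ii = 0; if (ii >= nr) ii = nr - 1;
          double wi = cubic_w(fi - (i0 + a));
          s += wi * wj * img(ii, jj);
          wsum += wi * wj;
        }
      }
      out(i2, j2) = s / wsum;
    }
  }
  return out;
}
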