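// Core numerics: Klein-Nishina kinematics and sampling, tabulated attenuation,
// Monte-Carlo photon transport (water phantom + 4-layer Si/CdTe camera),
// Voigt angular kernel, cone backprojection and list-mode ML-EM.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double MEC2 = 511.0;
static const double EPS_T = 1e-9;

// ---------------------------------------------------------------- kinematics

static inline double kn_ratio(double E0, double costh) {
  return 1.0 / (1.0 + (E0 / MEC2) * (1.0 - costh));
}

// differential cross-section in units of r_e^2 per steradian
static inline double kn_pdf_dimless(double E0, double costh) {
  double r = kn_ratio(E0, costh);
  double sin2 = 1.0 - costh * costh;
  return 0.5 * r * r * (r + 1.0 / r - sin2);
}

// closed-form total cross-section, same r_e^2 = 1 units
static double kn_total_dimless(double E0) {
  double a = E0 / MEC2;
  double l = std::log(1.0 + 2.0 * a);
  return 2.0 * M_PI * ((1.0 + a) / (a * a) *
                         (2.0 * (1.0 + a) / (1.0 + 2.0 * a) - l / a) +
                       l / (2.0 * a) -
                       (1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a)));
}

// rejection sampler for cos(theta); envelope is the forward maximum (= 1)
static double sample_costh(double E0) {
  for (;;) {
    double c = 2.0 * unif_rand() - 1.0;
    if (unif_rand() < kn_pdf_dimless(E0, c)) return c;
  }
}

// [[Rcpp::export]]
NumericVector cpp_sample_scatter_angle(int n, double E0) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::acos(sample_costh(E0));
  return out;
}

// [[Rcpp::export]]
double cpp_kn_total_dimless(double E0) { return kn_total_dimless(E0); }

// ------------------------------------------------------------- Voigt kernel

// Humlicek (1982) w4 rational approximation of the Faddeeva function w(z),
// evaluated for y >= 0.
static std::complex<double> faddeeva_w(double x, double y) {
  std::complex<double> t(y, -x);
  double s = std::fabs(x) + y;
  if (s >= 15.0) {
    return t * 0.5641896 / (0.5 + t * t);
  } else if (s >= 5.5) {
    std::complex<double> u = t * t;
    return t * (1.410474 + u * 0.5641896) / (0.75 + u * (3.0 + u));
  } else if (y >= 0.195 * std::fabs(x) - 0.176) {
    return (16.4955 + t * (20.20933 + t * (11.96482 +
            t * (3.778987 + t * 0.5642236)))) /
           (16.4955 + t * (38.82363 + t * (39.27121 +
            t * (21.69274 + t * (6.699398 + t)))));
  } else {
    std::complex<double> u = t * t;
    std::complex<double> num = t * (36183.31 - u * (3321.9905 -
      u * (1540.787 - u * (219.0313 - u * (35.76683 -
      u * (1.320522 - u * 0.56419))))));
    std::complex<double> den = 32066.6 - u * (24322.84 - u * (9022.228 -
      u * (2186.181 - u * (364.2191 - u * (61.57037 -
      u * (1.841439 - u))))));
    return std::exp(u) - num / den;
  }
}

// unit-area Voigt profile; the pure-Gaussian and pure-Lorentzian limits are
// evaluated exactly rather than through the Faddeeva approximation
static inline double voigt_density(double x, double sigma, double gamma) {
  if (sigma <= 0.0) {
    return gamma / (M_PI * (x * x + gamma * gamma));
  }
  if (gamma <= 0.0) {
    double z = x / sigma;
    return std::exp(-0.5 * z * z) / (sigma * std::sqrt(2.0 * M_PI));
  }
  double inv = 1.0 / (sigma * M_SQRT2);
  std::complex<double> w = faddeeva_w(x * inv, gamma * inv);
  return w.real() * inv / std::sqrt(M_PI);
}

// [[Rcpp::export]]
NumericVector cpp_voigt(NumericVector x, double sigma, double gamma) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = voigt_density(x[i], sigma, gamma);
  return out;
}

// -------------------------------------------------------------- attenuation

struct AttTable {
  std::vector<double> le, lpe, lc;
  void init(const NumericMatrix& m) {
    int n = m.nrow();
    le.resize(n); lpe.resize(n); lc.resize(n);
    for (int i = 0; i < n; ++i) {
      le[i] = std::log(m(i, 0));
      lpe[i] = std::log(m(i, 1));
      lc[i] = std::log(m(i, 2));
    }
  }
  // log-log interpolation, clamped at the grid ends
  void mu(double E, double& pe, double& c) const {
    double x = std::log(E);
    int n = (int)le.size();
    if (x <= le[0]) { pe = std::exp(lpe[0]); c = std::exp(lc[0]); return; }
    if (x >= le[n - 1]) { pe = std::exp(lpe[n - 1]); c = std::exp(lc[n - 1]); return; }
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (le[mid] <= x) lo = mid; else hi = mid; }
    double f = (x - le[lo]) / (le[lo + 1] - le[lo]);
    pe = std::exp(lpe[lo] + f * (lpe[lo + 1] - lpe[lo]));
    c = std::exp(lc[lo] + f * (lc[lo + 1] - lc[lo]));
  }
};

// [[Rcpp::export]]
NumericVector cpp_attenuation(NumericMatrix table, NumericVector E) {
  AttTable t; t.init(table);
  int n = E.size();
  NumericVector out(2 * n);
  for (int i = 0; i < n; ++i) {
    double pe, c; t.mu(E[i], pe, c);
    out[i] = pe; out[n + i] = c;
  }
  return out;
}

// ----------------------------------------------------------------- geometry

static inline void rotate_about(const double* d, double costh, double phi,
                                double* out) {
  double sinth = std::sqrt(std::max(0.0, 1.0 - costh * costh));
  // orthonormal basis (u, v, d)
  double ux, uy, uz;
  if (std::fabs(d[2]) < 0.999) { ux = -d[1]; uy = d[0]; uz = 0.0; } // z x d
  else { ux = 0.0; uy = -d[2]; uz = d[1]; }                        // x x d
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= un; uy /= un; uz /= un;
  double vx = d[1] * uz - d[2] * uy;
  double vy = d[2] * ux - d[0] * uz;
  double vz = d[0] * uy - d[1] * ux;
  double cp = std::cos(phi), sp = std::sin(phi);
  out[0] = sinth * (cp * ux + sp * vx) + costh * d[0];
  out[1] = sinth * (cp * uy + sp * vy) + costh * d[1];
  out[2] = sinth * (cp * uz + sp * vz) + costh * d[2];
}

// slab intersection of ray (p, d) with an axis-aligned box; returns false if missed
static bool box_intersect(const double* p, const double* d,
                          double xlo, double xhi, double ylo, double yhi,
                          double zlo, double zhi, double& t0, double& t1) {
  t0 = -1e300; t1 = 1e300;
  const double lo[3] = { xlo, ylo, zlo }, hi[3] = { xhi, yhi, zhi };
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-300) {
      if (p[k] < lo[k] || p[k] > hi[k]) return false;
    } else {
      double a = (lo[k] - p[k]) / d[k], b = (hi[k] - p[k]) / d[k];
      if (a > b) std::swap(a, b);
      if (a > t0) t0 = a;
      if (b < t1) t1 = b;
      if (t0 > t1) return false;
    }
  }
  return true;
}

// ---------------------------------------------------------------- simulator

struct Layer { double xh, yh, zt, zb; int mat; }; // mat: 0 = Si, 1 = CdTe

struct CamResult {
  // per-layer interaction counts and deposits; a valid two-hit event has
  // exactly one interaction in the Si layer and one in a single CdTe layer
  int count[4];
  double edep[4];
  double cx[4], cy[4], cz[4];
  int n_inter;
  int first_layer;
  bool terminated_pe;
};

static void camera_transport(double px, double py, double pz,
                             double dx, double dy, double dz, double E,
                             const std::vector<Layer>& L,
                             const AttTable& si, const AttTable& cdte,
                             double fluor_prob, CamResult& res) {
  for (int i = 0; i < 4; ++i) {
    res.count[i] = 0; res.edep[i] = 0;
    res.cx[i] = res.cy[i] = res.cz[i] = 0;
  }
  res.n_inter = 0; res.first_layer = -1; res.terminated_pe = false;
  double p[3] = { px, py, pz }, d[3] = { dx, dy, dz };
  for (int guard = 0; guard < 64; ++guard) {
    // nearest layer intersection ahead of the current position
    double best0 = 1e300, best1 = 0; int bi = -1;
    for (size_t i = 0; i < L.size(); ++i) {
      double t0, t1;
      if (!box_intersect(p, d, -L[i].xh, L[i].xh, -L[i].yh, L[i].yh,
                         L[i].zb, L[i].zt, t0, t1)) continue;
      if (t1 <= EPS_T) continue;
      if (t0 < EPS_T) t0 = 0.0;
      if (t0 < best0) { best0 = t0; best1 = t1; bi = (int)i; }
    }
    if (bi < 0) return; // escaped the stack
    for (int k = 0; k < 3; ++k) p[k] += d[k] * best0;
    double chord = best1 - best0;
    const AttTable& M = (L[bi].mat == 0) ? si : cdte;
    double mpe, mc; M.mu(E, mpe, mc);
    double mut = mpe + mc;
    double s = -std::log(unif_rand()) / mut;
    if (s >= chord) { // crossed without interacting
      for (int k = 0; k < 3; ++k) p[k] += d[k] * (chord + EPS_T);
      continue;
    }
    for (int k = 0; k < 3; ++k) p[k] += d[k] * s;
    if (unif_rand() < mpe / mut) { // photoelectric: full local deposit
      double edep = E;
      if (bi == 1 && fluor_prob > 0.0 && E > 40.0 &&
          unif_rand() < fluor_prob) {
        // minimal Cd/Te K-alpha escape from the top CdTe layer into the Si
        double ka = (unif_rand() < 0.5) ? 23.2 : 27.5;
        edep = E - ka;
        double zsi = 0.5 * (L[0].zt + L[0].zb);
        if (res.first_layer < 0) res.first_layer = bi;
        res.count[0]++; res.n_inter++;
        res.edep[0] += ka;
        res.cx[0] = p[0]; res.cy[0] = p[1]; res.cz[0] = zsi;
      }
      if (res.first_layer < 0) res.first_layer = bi;
      res.count[bi]++; res.n_inter++;
      res.edep[bi] += edep;
      res.cx[bi] = p[0]; res.cy[bi] = p[1]; res.cz[bi] = p[2];
      res.terminated_pe = true;
      return;
    }
    // Compton scatter in the detector
    double cth = sample_costh(E);
    double Ep = E * kn_ratio(E, cth);
    if (res.first_layer < 0) res.first_layer = bi;
    res.count[bi]++; res.n_inter++;
    res.edep[bi] += E - Ep;
    res.cx[bi] = p[0]; res.cy[bi] = p[1]; res.cz[bi] = p[2];
    if (res.n_inter > 2) return; // cannot be a two-hit event any more
    double nd[3];
    rotate_about(d, cth, 2.0 * M_PI * unif_rand(), nd);
    d[0] = nd[0]; d[1] = nd[1]; d[2] = nd[2];
    E = Ep;
    if (E < 1.0) return; // negligible residual photon
  }
}

struct EventBuf {
  std::vector<double> v; // 14 columns per event
  void push(double x1, double y1, double z1, double E1, int layer,
            double x2, double y2, double z2, double E2, double w,
            double tE0, double tns, double tfa, double tsf) {
    double row[14] = { x1, y1, z1, E1, (double)layer, x2, y2, z2, E2, w,
                       tE0, tns, tfa, tsf };
    v.insert(v.end(), row, row + 14);
  }
};

struct SimCtx {
  std::vector<Layer> L;
  const AttTable *water, *si, *cdte;
  double cube_lo[3], cube_hi[3];
  bool attenuate, blur;
  double si_sig_ref, si_eref, cdte_sig_ref, cdte_eref, blur_scale, trigger;
  double res_exponent;
  int max_scatters;
  bool force;
  double fluor_prob;
  long n_twohit, n_recorded, n_daughters, n_daughter_events;
};

static inline double det_sigma(const SimCtx& c, int mat, double E) {
  if (mat == 0)
    return c.blur_scale * c.si_sig_ref * std::pow(E / c.si_eref, c.res_exponent);
  return c.blur_scale * c.cdte_sig_ref * std::pow(E / c.cdte_eref, c.res_exponent);
}

// finish a photon that reached the camera region: transport, blur, trigger, record
static void finish_at_camera(SimCtx& c, EventBuf& buf,
                             const double* p, const double* d, double E,
                             double w, double E0, int nscat, bool daughter) {
  CamResult res;
  camera_transport(p[0], p[1], p[2], d[0], d[1], d[2], E,
                   c.L, *c.si, *c.cdte, c.fluor_prob, res);
  if (res.n_inter != 2 || res.count[0] != 1) return;
  int abl = 0;
  for (int i = 1; i < 4; ++i) if (res.count[i] == 1) { abl = i; break; }
  if (abl == 0) return;
  c.n_twohit++;
  double E1 = res.edep[0], E2 = res.edep[abl];
  double x1 = res.cx[0], y1 = res.cy[0], z1 = res.cz[0];
  double x2 = res.cx[abl], y2 = res.cy[abl], z2 = res.cz[abl];
  double full = (nscat == 0 && std::fabs(E1 + E2 - E0) < 1e-9) ? 1.0 : 0.0;
  if (c.blur) {
    E1 += norm_rand() * det_sigma(c, 0, E1);
    E2 += norm_rand() * det_sigma(c, 1, E2);
  }
  if (E1 < c.trigger || E2 < c.trigger) return;
  buf.push(x1, y1, z1, E1, abl, x2, y2, z2, E2, w, E0, nscat, full,
           res.first_layer == 0 ? 1.0 : 0.0);
  c.n_recorded++;
  if (daughter) c.n_daughter_events++;
}

// [[Rcpp::export]]
List cpp_simulate(double n_photons, double E0, NumericVector src,
                  int emission_mode, NumericVector cone_axis,
                  double cone_half_angle, double cone_fraction,
                  NumericVector cube_center, double cube_half, bool attenuate,
                  NumericMatrix layers, NumericMatrix tab_water,
                  NumericMatrix tab_si, NumericMatrix tab_cdte,
                  double si_fwhm, double si_eref, double cdte_fwhm,
                  double cdte_eref, double blur_scale, double res_exponent,
                  bool blur, double trigger_kev, int max_scatters,
                  bool force_detection, double fluor_prob) {
  AttTable tw, tsi, tcd;
  tw.init(tab_water); tsi.init(tab_si); tcd.init(tab_cdte);
  SimCtx c;
  c.water = &tw; c.si = &tsi; c.cdte = &tcd;
  for (int i = 0; i < layers.nrow(); ++i) {
    Layer l = { layers(i, 0), layers(i, 1), layers(i, 2), layers(i, 3),
                (int)layers(i, 4) };
    c.L.push_back(l);
  }
  for (int k = 0; k < 3; ++k) {
    c.cube_lo[k] = cube_center[k] - cube_half;
    c.cube_hi[k] = cube_center[k] + cube_half;
  }
  c.attenuate = attenuate; c.blur = blur;
  const double FW2SIG = 2.0 * std::sqrt(2.0 * std::log(2.0));
  c.si_sig_ref = si_fwhm / FW2SIG; c.si_eref = si_eref;
  c.cdte_sig_ref = cdte_fwhm / FW2SIG; c.cdte_eref = cdte_eref;
  c.blur_scale = blur_scale; c.res_exponent = res_exponent;
  c.trigger = trigger_kev;
  c.max_scatters = max_scatters; c.force = force_detection;
  c.fluor_prob = fluor_prob;
  c.n_twohit = c.n_recorded = c.n_daughters = c.n_daughter_events = 0;

  double ca[3] = { cone_axis[0], cone_axis[1], cone_axis[2] };
  double can = std::sqrt(ca[0] * ca[0] + ca[1] * ca[1] + ca[2] * ca[2]);
  for (int k = 0; k < 3; ++k) ca[k] /= can;
  double cos_psi = std::cos(cone_half_angle);
  double omega_cone = 2.0 * M_PI * (1.0 - cos_psi);
  double g_in = cone_fraction / omega_cone + (1.0 - cone_fraction) / (4.0 * M_PI);
  double g_out = (1.0 - cone_fraction) / (4.0 * M_PI);
  double inv4pi = 1.0 / (4.0 * M_PI);

  // Si top face, target of forced-detection daughters
  double si_zt = c.L[0].zt, si_xh = c.L[0].xh, si_yh = c.L[0].yh;
  double si_area = 4.0 * si_xh * si_yh;

  EventBuf buf;
  long n = (long)n_photons;
  for (long ip = 0; ip < n; ++ip) {
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    // --- emission ---
    double d[3], w = 1.0;
    if (emission_mode == 1) { // cone / isotropic mixture with importance weights
      bool in_cone_comp = unif_rand() < cone_fraction;
      if (in_cone_comp) {
        double cth = cos_psi + unif_rand() * (1.0 - cos_psi);
        rotate_about(ca, cth, 2.0 * M_PI * unif_rand(), d);
      } else {
        double cth = 2.0 * unif_rand() - 1.0;
        double phi = 2.0 * M_PI * unif_rand();
        double sth = std::sqrt(1.0 - cth * cth);
        d[0] = sth * std::cos(phi); d[1] = sth * std::sin(phi); d[2] = cth;
      }
      double cda = d[0] * ca[0] + d[1] * ca[1] + d[2] * ca[2];
      w = inv4pi / ((cda >= cos_psi) ? g_in : g_out);
    } else {
      double cth = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double sth = std::sqrt(1.0 - cth * cth);
      d[0] = sth * std::cos(phi); d[1] = sth * std::sin(phi); d[2] = cth;
    }
    double p[3] = { src[0], src[1], src[2] };
    double E = E0;
    int nscat = 0;
    bool alive = true;

    // --- phantom transport ---
    if (attenuate) {
      for (;;) {
        double t0, t1;
        if (!box_intersect(p, d, c.cube_lo[0], c.cube_hi[0], c.cube_lo[1],
                           c.cube_hi[1], c.cube_lo[2], c.cube_hi[2], t0, t1) ||
            t1 <= 0.0) break; // outside already
        double mpe, mc; tw.mu(E, mpe, mc);
        double mut = mpe + mc;
        double s = -std::log(unif_rand()) / mut;
        if (s >= t1) { // leaves the cube
          for (int k = 0; k < 3; ++k) p[k] += d[k] * (t1 + EPS_T);
          break;
        }
        for (int k = 0; k < 3; ++k) p[k] += d[k] * s;
        if (unif_rand() < mpe / mut) { alive = false; break; } // absorbed
        nscat++;
        if (nscat > c.max_scatters) { alive = false; break; }
        if (c.force) {
          // next-event-estimation daughter aimed at the scatterer face
          double tx = -si_xh + 2.0 * si_xh * unif_rand();
          double ty = -si_yh + 2.0 * si_yh * unif_rand();
          double dd[3] = { tx - p[0], ty - p[1], si_zt - p[2] };
          double r2 = dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2];
          double rn = std::sqrt(r2);
          for (int k = 0; k < 3; ++k) dd[k] /= rn;
          double cthf = d[0] * dd[0] + d[1] * dd[1] + d[2] * dd[2];
          double fdir = kn_pdf_dimless(E, cthf) / kn_total_dimless(E);
          double wd = w * fdir * si_area * std::fabs(dd[2]) / r2;
          double Ed = E * kn_ratio(E, cthf);
          c.n_daughters++;
          // analog attenuation over the remaining water path
          double u0, u1;
          box_intersect(p, dd, c.cube_lo[0], c.cube_hi[0], c.cube_lo[1],
                        c.cube_hi[1], c.cube_lo[2], c.cube_hi[2], u0, u1);
          double mpe2, mc2; tw.mu(Ed, mpe2, mc2);
          if (-std::log(unif_rand()) / (mpe2 + mc2) > u1) {
            double pd[3] = { p[0] + dd[0] * (u1 + EPS_T),
                             p[1] + dd[1] * (u1 + EPS_T),
                             p[2] + dd[2] * (u1 + EPS_T) };
            finish_at_camera(c, buf, pd, dd, Ed, wd, E0, nscat, true);
          }
        }
        // analog continuation
        double cth = sample_costh(E);
        double Ep = E * kn_ratio(E, cth);
        double nd[3];
        rotate_about(d, cth, 2.0 * M_PI * unif_rand(), nd);
        d[0] = nd[0]; d[1] = nd[1]; d[2] = nd[2];
        E = Ep;
        if (E < 10.0) { alive = false; break; } // cannot trigger two detectors
      }
    }
    if (!alive) continue;
    // with forced detection, scattered analog photons are dropped here
    // (their camera contribution is carried by the daughters)
    if (c.force && nscat > 0) continue;
    finish_at_camera(c, buf, p, d, E, w, E0, nscat, false);
  }

  long nev = (long)(buf.v.size() / 14);
  NumericMatrix ev(nev, 14);
  for (long i = 0; i < nev; ++i)
    for (int j = 0; j < 14; ++j) ev(i, j) = buf.v[i * 14 + j];
  return List::create(_["events"] = ev,
                      _["n_generated"] = (double)n,
                      _["n_twohit"] = (double)c.n_twohit,
                      _["n_recorded"] = (double)c.n_recorded,
                      _["n_daughters"] = (double)c.n_daughters,
                      _["n_daughter_events"] = (double)c.n_daughter_events);
}

// ------------------------------------------------------------ reconstruction

static inline double cone_residual(const double* apex, const double* axis,
                                   double theta, double px, double py,
                                   double pz) {
  double v0 = px - apex[0], v1 = py - apex[1], v2 = pz - apex[2];
  double n = std::sqrt(v0 * v0 + v1 * v1 + v2 * v2);
  double cb = (v0 * axis[0] + v1 * axis[1] + v2 * axis[2]) / n;
  if (cb > 1.0) cb = 1.0; else if (cb < -1.0) cb = -1.0;
  return std::acos(cb) - theta;
}

// residuals of many events at one reference point (ARM calibration)
// [[Rcpp::export]]
NumericVector cpp_residuals_point(NumericMatrix apex, NumericMatrix axis,
                                  NumericVector theta, NumericVector point) {
  int n = apex.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double a[3] = { apex(i, 0), apex(i, 1), apex(i, 2) };
    double u[3] = { axis(i, 0), axis(i, 1), axis(i, 2) };
    out[i] = cone_residual(a, u, theta[i], point[0], point[1], point[2]);
  }
  return out;
}

// residuals of one event at many points
// [[Rcpp::export]]
NumericVector cpp_residuals_event(NumericVector apex, NumericVector axis,
                                  double theta, NumericMatrix pts) {
  int m = pts.nrow();
  NumericVector out(m);
  double a[3] = { apex[0], apex[1], apex[2] };
  double u[3] = { axis[0], axis[1], axis[2] };
  for (int j = 0; j < m; ++j)
    out[j] = cone_residual(a, u, theta, pts(j, 0), pts(j, 1), pts(j, 2));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix apex, NumericMatrix axis,
                              NumericVector theta, NumericVector w,
                              NumericVector xs, NumericVector ys, double z,
                              double sigma, double gamma, double cutoff) {
  int nev = apex.nrow(), nx = xs.size(), ny = ys.size();
  NumericMatrix img(nx, ny);
  for (int i = 0; i < nev; ++i) {
    if ((i & 0xFF) == 0) Rcpp::checkUserInterrupt();
    double a[3] = { apex(i, 0), apex(i, 1), apex(i, 2) };
    double u[3] = { axis(i, 0), axis(i, 1), axis(i, 2) };
    double wi = w[i], th = theta[i];
    for (int iy = 0; iy < ny; ++iy) {
      double py = ys[iy];
      for (int ix = 0; ix < nx; ++ix) {
        double r = cone_residual(a, u, th, xs[ix], py, z);
        if (std::fabs(r) <= cutoff)
          img(ix, iy) += wi * voigt_density(r, sigma, gamma);
      }
    }
  }
  return img;
}

// list-mode ML-EM; t_ij = Voigt(residual_ij). The per-event kernel rows are
// cached when they fit in cache_max bytes, else recomputed each pass;
// both paths produce identical images.
// [[Rcpp::export]]
List cpp_mlem(NumericMatrix apex, NumericMatrix axis, NumericVector theta,
              NumericVector w, NumericVector xs, NumericVector ys, double z,
              double sigma, double gamma, NumericVector sens,
              NumericVector init, int iterations, double cutoff,
              double cache_max) {
  int nev = apex.nrow(), nx = xs.size(), ny = ys.size();
  long npix = (long)nx * ny;
  std::vector<double> lambda(init.begin(), init.end());
  std::vector<double> px(npix), py(npix), pz(npix, z);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) { px[iy * nx + ix] = xs[ix]; py[iy * nx + ix] = ys[iy]; }

  bool cache = (double)nev * npix * sizeof(double) <= cache_max && nev > 0;
  std::vector<double> T;
  if (cache) T.resize((size_t)nev * npix);
  std::vector<char> excluded(nev, 0);
  int n_excluded = 0;
  std::vector<double> loglik;
  std::vector<double> back(npix);

  for (int it = 0; it < iterations; ++it) {
    std::fill(back.begin(), back.end(), 0.0);
    double ll = 0.0;
    for (int i = 0; i < nev; ++i) {
      if ((i & 0xFF) == 0) Rcpp::checkUserInterrupt();
      if (excluded[i]) continue;
      double a[3] = { apex(i, 0), apex(i, 1), apex(i, 2) };
      double u[3] = { axis(i, 0), axis(i, 1), axis(i, 2) };
      double th = theta[i];
      double* row = cache ? &T[(size_t)i * npix] : NULL;
      double f = 0.0;
      if (cache && it > 0) {
        for (long j = 0; j < npix; ++j) f += row[j] * lambda[j];
      } else {
        for (long j = 0; j < npix; ++j) {
          double r = cone_residual(a, u, th, px[j], py[j], pz[j]);
          double t = (std::fabs(r) <= cutoff) ? voigt_density(r, sigma, gamma) : 0.0;
          if (cache) row[j] = t;
          f += t * lambda[j];
        }
      }
      if (f <= 0.0) {
        if (it == 0) { excluded[i] = 1; n_excluded++; }
        continue;
      }
      ll += w[i] * std::log(f);
      double c = w[i] / f;
      if (cache) {
        for (long j = 0; j < npix; ++j) back[j] += c * row[j];
      } else {
        for (long j = 0; j < npix; ++j) {
          double r = cone_residual(a, u, th, px[j], py[j], pz[j]);
          double t = (std::fabs(r) <= cutoff) ? voigt_density(r, sigma, gamma) : 0.0;
          back[j] += c * t;
        }
      }
    }
    for (long j = 0; j < npix; ++j) lambda[j] *= back[j] / sens[j];
    if (it > 0) loglik.push_back(ll); // ll was evaluated at the previous image
  }
  // log-likelihood at the final image
  if (iterations > 0) {
    double ll = 0.0;
    for (int i = 0; i < nev; ++i) {
      if (excluded[i]) continue;
      double a[3] = { apex(i, 0), apex(i, 1), apex(i, 2) };
      double u[3] = { axis(i, 0), axis(i, 1), axis(i, 2) };
      double f = 0.0;
      if (cache) {
        const double* row = &T[(size_t)i * npix];
        for (long j = 0; j < npix; ++j) f += row[j] * lambda[j];
      } else {
        for (long j = 0; j < npix; ++j) {
          double r = cone_residual(a, u, theta[i], px[j], py[j], pz[j]);
          double t = (std::fabs(r) <= cutoff) ? voigt_density(r, sigma, gamma) : 0.0;
          f += t * lambda[j];
        }
      }
      if (f > 0.0) ll += w[i] * std::log(f);
    }
    loglik.push_back(ll);
  }
  NumericMatrix img(nx, ny);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) img(ix, iy) = lambda[iy * nx + ix];
  return List::create(_["image"] = img, _["loglik"] = NumericVector(loglik.begin(), loglik.end()),
                      _["n_excluded"] = n_excluded);
}
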