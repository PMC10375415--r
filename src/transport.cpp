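// Condensed-history proton transport over a voxel grid.
//
// Physics inputs (stopping power, multiple-scattering sigma, hard-scatter
// cross-section, inverse-CDF of the scattering angle, water range-energy
// tables) are tabulated in R and passed down, so the R physics layer is
// the single source of truth; this file only steps, interpolates and
// scores.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---- RNG: xoshiro256+ seeded via splitmix64, Ziggurat normals -------------
struct RNG {
  uint64_t s[4];
  double zx[129], zf[129];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    // 128-layer Ziggurat table for the standard normal
    const double r = 3.442619855899, v = 9.91256303526217e-3;
    zx[1] = r;
    zx[0] = v / std::exp(-0.5 * r * r);
    for (int i = 2; i <= 127; ++i)
      zx[i] = std::sqrt(-2.0 * std::log(v / zx[i - 1] +
                                        std::exp(-0.5 * zx[i - 1] *
                                                 zx[i - 1])));
    zx[128] = 0.0;
    for (int i = 0; i <= 128; ++i) zf[i] = std::exp(-0.5 * zx[i] * zx[i]);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    const double r = 3.442619855899;
    while (true) {
      uint64_t b = next();
      int i = (int)(b & 127);
      double u = 2.0 * (((b >> 11) + 0.5) *
                        (1.0 / 9007199254740992.0)) - 1.0;
      double x = u * zx[i];
      if (std::fabs(x) < zx[i + 1]) return x;
      if (i == 0) {  // tail
        double xx, yy;
        do {
          xx = -std::log(unif()) / r;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return u > 0 ? r + xx : -(r + xx);
      }
      if (zf[i + 1] + unif() * (zf[i] - zf[i + 1]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---- table interpolation on a log-energy grid -----------------------------
struct ETab {
  double l0, dl;
  int n;
  const double* base;  // column-major nE x nmat
  // t = scaled log-energy index, shared across tables on the same grid
  inline double t_of(double E) const { return (std::log(E) - l0) / dl; }
  inline double at_t(double t, int m) const {
    if (t <= 0) return base[m * n];
    if (t >= n - 1) return base[m * n + n - 1];
    int i = (int)t;
    double f = t - i;
    const double* c = base + m * n + i;
    return c[0] * (1 - f) + c[1] * f;
  }
  inline double at(double E, int m) const { return at_t(t_of(E), m); }
};

struct Vec3 { double x, y, z; };
static inline Vec3 operator+(Vec3 a, Vec3 b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
static inline Vec3 operator-(Vec3 a, Vec3 b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 operator*(double k, Vec3 a) {
  return {k * a.x, k * a.y, k * a.z};
}
static inline double dot(Vec3 a, Vec3 b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline void normalize(Vec3& a) {
  double n = std::sqrt(dot(a, a));
  a.x /= n; a.y /= n; a.z /= n;
}
// orthonormal frame perpendicular to w
static inline void frame(const Vec3& w, Vec3& u, Vec3& v) {
  Vec3 a = (std::fabs(w.z) < 0.9) ? Vec3{0, 0, 1} : Vec3{1, 0, 0};
  u = cross(a, w); normalize(u);
  v = cross(w, u);
}
// rotate w by polar angle theta about azimuth phi in its own frame
static inline Vec3 rotate_dir(const Vec3& w, double theta, double phi) {
  Vec3 u, v; frame(w, u, v);
  double st = std::sin(theta), ct = std::cos(theta);
  Vec3 r = ct * w + st * std::cos(phi) * u + st * std::sin(phi) * v;
  normalize(r);
  return r;
}

struct Detector {
  Vec3 c, n, t1, t2;  // center (mm) and local axes
};

struct Sim {
  // grid
  int nx, ny, nz;
  double vox, ox, oy, oz;
  const double* dens;
  const int* mat;  // 0-based material index
  // tables
  ETab S, MS, SIG;
  const double* strag;    // MeV^2 per cm, per material
  const double* kinA;     // mass number per material
  const double* relstop;  // stopping relative to water, per material
  ETab SPL;               // plastic scintillator stopping power (1 col)
  ETab RNGE;              // water CSDA range cm vs E
  // inverse range: E on a uniform range grid
  double r_max; int nr; const double* einv;
  // scattering angle inverse CDF (uniform quantiles)
  int nq; const double* thq;
  double th_lo, th_hi, norm_omega;
  int conv;  // 0 = sin^4(theta), 1 = sin^4(theta/2)
  // detectors
  std::vector<Detector> det;
  double det_hn = 1.5, det_ht = 5.0;  // half thickness / half face, mm
  // config
  double step_mm, cutoff;
  bool ms_on = true, straggle_on = true, hs_on = true;
  bool do_nee = true, do_analog = false;
  int nee_stride = 1, nee_step = 4;
  long deflect_every = 2;  // direction/straggling substep, in steps
  // scores
  double* dose;
  std::vector<double> cur_nee, cur_analog;
  double escaped = 0, det_analog_sum = 0, nee_total = 0;
  long n_abs = 0, n_esc = 0, n_hit = 0, n_hard = 0;

  inline int vox_idx(const Vec3& p) const {
    int ix = (int)std::floor((p.x - ox) / vox);
    int iy = (int)std::floor((p.y - oy) / vox);
    int iz = (int)std::floor((p.z - oz) / vox);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      return -1;
    return ix + nx * (iy + ny * iz);
  }

  inline double inv_range(double rcm) const {
    double t = rcm / r_max * (nr - 1);
    if (t <= 0) return 0.0;
    if (t >= nr - 1) return einv[nr - 1];
    int i = (int)t; double f = t - i;
    return einv[i] * (1 - f) + einv[i + 1] * f;
  }

  inline double sample_theta(double u) const {
    double t = u * (nq - 1);
    int i = (int)t; if (i >= nq - 1) i = nq - 2;
    double f = t - i;
    return thq[i] * (1 - f) + thq[i + 1] * f;
  }

  inline double kin_frac(double theta, double A) const {
    const double m = 938.2720882, uamu = 931.4941024;
    double M = A * uamu;
    double s = std::sin(theta / 2);
    double fr = 1 - 4 * m * M / ((m + M) * (m + M)) * s * s;
    return fr > 0 ? fr : 0;
  }

  // chord of a ray through a detector box; returns length (mm) and sets
  // tmin; negative return = miss
  double box_chord(const Detector& d, const Vec3& p0, const Vec3& u,
                   double& tmin_out) const {
    Vec3 q = p0 - d.c;
    double tmin = -1e300, tmax = 1e300;
    const Vec3* ax[3] = {&d.n, &d.t1, &d.t2};
    double hs[3] = {det_hn, det_ht, det_ht};
    for (int a = 0; a < 3; ++a) {
      double du = dot(u, *ax[a]), qd = dot(q, *ax[a]);
      if (std::fabs(du) < 1e-12) {
        if (std::fabs(qd) > hs[a]) return -1;
      } else {
        double t1 = (-hs[a] - qd) / du, t2 = (hs[a] - qd) / du;
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
        if (tmin > tmax) return -1;
      }
    }
    if (tmax <= 0) return -1;
    if (tmin < 0) tmin = 0;
    tmin_out = tmin;
    return tmax - tmin;
  }

  // analog: trace an escaping proton to the nearest detector
  void analog_escape(const Vec3& from, const Vec3& u, double E) {
    int best = -1; double best_t = 1e300, best_chord = 0;
    for (size_t j = 0; j < det.size(); ++j) {
      double tmin, ch = box_chord(det[j], from, u, tmin);
      if (ch > 0 && tmin < best_t) { best_t = tmin; best = (int)j;
        best_chord = ch; }
    }
    if (best >= 0 && E > 0) {
      double dep = SPL.at(E, 0) * best_chord / 10.0;
      if (dep > E) dep = E;
      cur_analog[best] += dep;
      det_analog_sum += dep;
      escaped += E - dep;
      ++n_hit;
    } else {
      escaped += E;
    }
    ++n_esc;
  }

  // expected-value (next-event) current tally from one transport step
  void nee_tally(const Vec3& p, const Vec3& dir, double E, int m,
                 double rho, double weight) {
    double sig = SIG.at(E, m);             // per cm
    double base = sig * (step_mm / 10.0) * weight;
    if (base <= 0) return;
    double A = kinA[m];
    for (size_t j = 0; j < det.size(); ++j) {
      Vec3 u = det[j].c - p;
      double d2 = dot(u, u), dist = std::sqrt(d2);
      Vec3 un = (1.0 / dist) * u;
      double ct = dot(un, dir);
      if (ct > 1) ct = 1; if (ct < -1) ct = -1;
      double theta = std::acos(ct);
      if (theta < th_lo || theta > th_hi) continue;
      double s = (conv == 0) ? std::sin(theta) : std::sin(theta / 2);
      double w_ang = 1.0 / (s * s * s * s) / norm_omega;
      double cosf = std::fabs(dot(un, det[j].n));
      if (cosf < 0.05) continue;
      double dOmega = 100.0 * cosf / d2;   // 10x10 mm face
      double Esc = E * kin_frac(theta, A);
      if (Esc <= cutoff) continue;
      // water-equivalent path from p to the grid edge along un
      double range = RNGE.at(Esc, 0);
      double h = 2.0 * vox, wepl = 0;      // march step, mm
      Vec3 q = p + (0.5 * h) * un;
      bool absorbed = false;
      while (true) {
        int idx = vox_idx(q);
        if (idx < 0) break;
        double r = dens[idx];
        if (r > 0.01) {
          wepl += relstop[mat[idx]] * h / 10.0;
          if (wepl >= range) { absorbed = true; break; }
        }
        q = q + h * un;
      }
      if (absorbed) continue;
      double Eex = inv_range(range - wepl);
      if (Eex <= 0.05) continue;
      double chord = det_hn * 2 / cosf;
      if (chord > 12) chord = 12;
      double dep = SPL.at(Eex, 0) * chord / 10.0;
      if (dep > Eex) dep = Eex;
      double w = base * w_ang * dOmega * dep;
      cur_nee[j] += w;
      nee_total += w;
    }
  }

  // transport a single proton; optionally record per-voxel deposits
  // returns: 0 absorbed, 1 escaped
  int run_one(RNG& rng, Vec3 pos, Vec3 dir, double E, bool nee_active,
              std::vector<int>* rec_idx = nullptr,
              std::vector<double>* rec_de = nullptr,
              Vec3* exit_pos = nullptr, Vec3* exit_dir = nullptr,
              double* exit_E = nullptr) {
    Vec3 last_dense = pos;
    long stepi = 0;
    double dx_cm = step_mm / 10.0;
    while (true) {
      int idx = vox_idx(pos);
      if (idx < 0) {
        if (do_analog) analog_escape(last_dense, dir, E);
        else { escaped += E; ++n_esc; }
        if (exit_pos) { *exit_pos = pos; *exit_dir = dir; *exit_E = E; }
        return 1;
      }
      int m = mat[idx];
      double rho = dens[idx];
      bool dense = rho > 0.01;
      if (dense) last_dense = pos;
      bool fluct = (stepi % deflect_every) == (deflect_every - 1);
      double tE = S.t_of(E);
      double de = S.at_t(tE, m) * dx_cm;
      if (straggle_on && dense && fluct)
        de += std::sqrt(strag[m] * dx_cm * deflect_every) * rng.norm();
      if (de < 0) de = 0;
      if (E - de <= cutoff) {
        dose[idx] += E;
        if (rec_idx) { rec_idx->push_back(idx); rec_de->push_back(E); }
        ++n_abs;
        return 0;
      }
      dose[idx] += de;
      if (rec_idx) { rec_idx->push_back(idx); rec_de->push_back(de); }
      E -= de;
      tE = S.t_of(E);
      if (nee_active && dense && (stepi % nee_step == 0))
        nee_tally(pos, dir, E, m, rho,
                  (double)nee_stride * (double)nee_step);
      if (ms_on && dense && fluct) {
        double sg = MS.at_t(tE, m);
        Vec3 u, v; frame(dir, u, v);
        double a1 = sg * rng.norm(), a2 = sg * rng.norm();
        dir = dir + a1 * u + a2 * v;
        normalize(dir);
      }
      if (hs_on && dense) {
        double P = SIG.at_t(tE, m) * dx_cm;
        if (rng.unif() < P) {
          double theta = sample_theta(rng.unif());
          double phi = 6.283185307179586 * rng.unif();
          dir = rotate_dir(dir, theta, phi);
          E *= kin_frac(theta, kinA[m]);
          ++n_hard;
          if (E <= cutoff) {
            dose[idx] += E;
            if (rec_idx) { rec_idx->push_back(idx); rec_de->push_back(E); }
            ++n_abs;
            return 0;
          }
        }
      }
      pos = pos + step_mm * dir;
      ++stepi;
    }
  }
};

static Sim build_sim(NumericVector dens, IntegerVector matid,
                     IntegerVector dims, double voxel_mm,
                     NumericVector origin, List tables, List detectors,
                     List cfg, NumericVector dose) {
  Sim s;
  s.nx = dims[0]; s.ny = dims[1]; s.nz = dims[2];
  s.vox = voxel_mm;
  s.ox = origin[0]; s.oy = origin[1]; s.oz = origin[2];
  s.dens = REAL(dens);
  s.mat = INTEGER(matid);

  NumericVector eg = tables["egrid"];
  double l0 = std::log(eg[0]);
  double dl = std::log(eg[1]) - std::log(eg[0]);
  int nE = eg.size();
  NumericMatrix St = tables["S"], MSt = tables["sigma_ms"],
    SIGt = tables["sigma_hs"];
  s.S = {l0, dl, nE, REAL(St)};
  s.MS = {l0, dl, nE, REAL(MSt)};
  s.SIG = {l0, dl, nE, REAL(SIGt)};
  NumericVector stragv = tables["straggling"], kinAv = tables["A"],
    relv = tables["relstop"];
  s.strag = REAL(stragv); s.kinA = REAL(kinAv); s.relstop = REAL(relv);
  NumericVector spl = tables["s_plastic"], rng_t = tables["range_water"];
  s.SPL = {l0, dl, nE, REAL(spl)};
  s.RNGE = {l0, dl, nE, REAL(rng_t)};
  NumericVector einv = tables["e_of_range"];
  s.einv = REAL(einv); s.nr = einv.size();
  s.r_max = as<double>(tables["range_max"]);
  NumericVector thq = tables["theta_quantiles"];
  s.thq = REAL(thq); s.nq = thq.size();
  s.th_lo = as<double>(tables["theta_lo"]);
  s.th_hi = as<double>(tables["theta_hi"]);
  s.norm_omega = as<double>(tables["norm_omega"]);
  s.conv = as<int>(tables["convention"]);

  NumericMatrix dc = detectors["centers"], dn = detectors["normals"],
    d1 = detectors["t1"], d2 = detectors["t2"];
  for (int j = 0; j < dc.nrow(); ++j) {
    Detector d;
    d.c = {dc(j, 0), dc(j, 1), dc(j, 2)};
    d.n = {dn(j, 0), dn(j, 1), dn(j, 2)};
    d.t1 = {d1(j, 0), d1(j, 1), d1(j, 2)};
    d.t2 = {d2(j, 0), d2(j, 1), d2(j, 2)};
    s.det.push_back(d);
  }
  s.step_mm = as<double>(cfg["step_mm"]);
  s.cutoff = as<double>(cfg["cutoff_mev"]);
  s.ms_on = as<bool>(cfg["ms_on"]);
  s.straggle_on = as<bool>(cfg["straggle_on"]);
  s.hs_on = as<bool>(cfg["hs_on"]);
  std::string est = as<std::string>(cfg["current_estimator"]);
  s.do_nee = (est == "nee");
  s.do_analog = (est == "analog");
  s.nee_stride = as<int>(cfg["nee_stride"]);
  s.nee_step = as<int>(cfg["nee_step"]);
  s.deflect_every = as<int>(cfg["deflect_every"]);
  s.dose = REAL(dose);
  s.cur_nee.assign(s.det.size(), 0.0);
  s.cur_analog.assign(s.det.size(), 0.0);
  return s;
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector dens, IntegerVector matid,
                  IntegerVector dims, double voxel_mm,
                  NumericVector origin, List tables, List detectors,
                  List beam, List cfg) {
  NumericVector dose(dens.size());
  Sim s = build_sim(dens, matid, dims, voxel_mm, origin, tables,
                    detectors, cfg, dose);
  RNG rng((uint64_t)as<double>(cfg["seed"]));
  int n = as<int>(beam["n_protons"]);
  double E0 = as<double>(beam["energy_mev"]);
  double cy = as<double>(beam["center_y_mm"]);
  double cz = as<double>(beam["center_z_mm"]);
  double rb = as<double>(beam["radius_mm"]);
  double rw = as<double>(beam["wobble_mm"]);
  double x0 = s.ox + 1e-9;
  for (int i = 0; i < n; ++i) {
    double rad = rb * std::sqrt(rng.unif());
    double ang = 6.283185307179586 * rng.unif();
    double y = cy + rad * std::cos(ang), z = cz + rad * std::sin(ang);
    if (rw > 0) {
      double ph = 6.283185307179586 * rng.unif();
      y += rw * std::cos(ph); z += rw * std::sin(ph);
    }
    bool nee_active = s.do_nee && (i % s.nee_stride == 0);
    s.run_one(rng, {x0, y, z}, {1, 0, 0}, E0, nee_active);
  }
  return List::create(
    _["dose"] = dose,
    _["currents_nee"] = NumericVector(s.cur_nee.begin(), s.cur_nee.end()),
    _["currents_analog"] = NumericVector(s.cur_analog.begin(),
                                         s.cur_analog.end()),
    _["escaped_mev"] = s.escaped,
    _["detector_analog_mev"] = s.det_analog_sum,
    _["nee_total_mev"] = s.nee_total,
    _["n_absorbed"] = (double)s.n_abs,
    _["n_escaped"] = (double)s.n_esc,
    _["n_detected"] = (double)s.n_hit,
    _["n_hard_scatters"] = (double)s.n_hard);
}

// [[Rcpp::export]]
List cpp_transport_one(NumericVector dens, IntegerVector matid,
                       IntegerVector dims, double voxel_mm,
                       NumericVector origin, List tables, List detectors,
                       NumericVector pos0, NumericVector dir0, double E0,
                       List cfg) {
  NumericVector dose(dens.size());
  Sim s = build_sim(dens, matid, dims, voxel_mm, origin, tables,
                    detectors, cfg, dose);
  RNG rng((uint64_t)as<double>(cfg["seed"]));
  Vec3 d = {dir0[0], dir0[1], dir0[2]};
  double nn = std::sqrt(dot(d, d));
  if (std::fabs(nn - 1.0) > 1e-6)
    stop("direction must be a unit vector");
  std::vector<int> ridx; std::vector<double> rde;
  Vec3 ep = {NA_REAL, NA_REAL, NA_REAL}, ed = ep;
  double eE = NA_REAL;
  int status = s.run_one(rng, {pos0[0], pos0[1], pos0[2]}, d, E0, false,
                         &ridx, &rde, &ep, &ed, &eE);
  return List::create(
    _["status"] = status == 0 ? "absorbed" : "escaped",
    _["voxel"] = IntegerVector(ridx.begin(), ridx.end()),
    _["deposit_mev"] = NumericVector(rde.begin(), rde.end()),
    _["dose"] = dose,
    _["exit_position"] = NumericVector::create(ep.x, ep.y, ep.z),
    _["exit_direction"] = NumericVector::create(ed.x, ed.y, ed.z),
    _["exit_energy"] = eE);
}
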