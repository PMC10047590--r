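// White (absorption-rescaled) Monte Carlo photon transport for a two-fiber
// contact probe on a semi-infinite homogeneous medium.
//
// The baseline run propagates photons at mua = 0 with Henyey-Greenstein
// scattering and records, per photon exiting the top surface, the total
// pathlength, the radial displacement of the exit point from the launch
// point, the launch radius within the source face, the exit weight and the
// exit direction cosine. Absorption and scattering changes are applied
// afterwards by similarity rescaling (pathlengths and displacements scale by
// mus_ref/mus) plus Beer-Lambert weighting, so one baseline run serves every
// wavelength of a spectral fit.
//
// All lengths are in cm. The RNG is a self-contained xoshiro256+ seeded via
// splitmix64 from the user's integer seed, so runs are reproducible and
// independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
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
  // uniform in (0, 1); never exactly 0 so log() is safe
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Azimuthally averaged probability that a point launched at radius r0 from
// the probe axis, displaced by a radial distance d, lands on the detector
// face (disk of radius r_det centred sep from the axis). Uses the classic
// ring-overlap arc fraction, averaged over the relative azimuth of the
// displacement.
struct CaptureTable {
  std::vector<double> tab;
  int n_r0, n_d;
  double r0_max, d_max;

  CaptureTable(double r_src, double sep, double r_det,
               int nr0 = 33, int nd = 2049, int nq = 32) {
    n_r0 = nr0; n_d = nd;
    r0_max = r_src;
    d_max = sep + r_det + r_src + 1e-9;
    tab.assign((size_t)nr0 * nd, 0.0);
    for (int i = 0; i < nr0; ++i) {
      double r0 = r0_max * i / (nr0 - 1);
      for (int j = 0; j < nd; ++j) {
        double d = d_max * j / (nd - 1);
        double acc = 0.0;
        for (int q = 0; q < nq; ++q) {
          double psi = M_PI * (q + 0.5) / nq;
          double ex = std::sqrt(r0 * r0 + d * d - 2.0 * r0 * d * std::cos(psi));
          acc += arc_fraction(ex, sep, r_det);
        }
        tab[(size_t)i * nd + j] = acc / nq;
      }
    }
  }

  static double arc_fraction(double rho, double sep, double r_det) {
    if (rho <= 1e-12) return (sep < r_det) ? 1.0 : 0.0;
    if (rho + 1e-15 >= sep + r_det || rho <= sep - r_det) return 0.0;
    double c = (rho * rho + sep * sep - r_det * r_det) / (2.0 * rho * sep);
    if (c >= 1.0) return 0.0;
    if (c <= -1.0) return 1.0;
    return std::acos(c) / M_PI;
  }

  inline double operator()(double r0, double d) const {
    if (d >= d_max) return 0.0;
    double fi = r0 / r0_max * (n_r0 - 1);
    double fj = d / d_max * (n_d - 1);
    int i = (int)fi, j = (int)fj;
    if (i >= n_r0 - 1) i = n_r0 - 2;
    if (j >= n_d - 1) j = n_d - 2;
    double wi = fi - i, wj = fj - j;
    const double *t = tab.data();
    size_t a = (size_t)i * n_d + j, b = a + n_d;
    return (1 - wi) * ((1 - wj) * t[a] + wj * t[a + 1]) +
           wi * ((1 - wj) * t[b] + wj * t[b + 1]);
  }
};

inline double fresnel_unpolarized(double cos_i, double n_rel) {
  // internal->external, n_rel = n_in / n_out
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n_rel * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n_rel * cos_i - cos_t) / (n_rel * cos_i + cos_t);
  double rp = (n_rel * cos_t - cos_i) / (n_rel * cos_t + cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export]]
List mc_run(double r_src, double na, double n_rel, double mus, double g,
            int n_photons, double seed, double mua, double r_max,
            double l_max, double w_min, double p_survive) {
  if (mus <= 0) stop("mus must be positive");
  if (g < 0 || g >= 1) stop("anisotropy g must lie in [0, 1)");
  Xoshiro rng((uint64_t)seed);

  double mut = mus + mua;
  double albedo = mus / mut;
  double sin_launch = std::min(na / n_rel, 0.999999);
  double cos_launch = std::sqrt(1.0 - sin_launch * sin_launch);

  std::vector<double> vL, vR, vR0, vW, vUZ;
  size_t reserve = (size_t)n_photons / 2;
  vL.reserve(reserve); vR.reserve(reserve); vR0.reserve(reserve);
  vW.reserve(reserve); vUZ.reserve(reserve);
  long n_truncated = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double r0 = r_src * std::sqrt(rng.unif());
    double x = r0, y = 0.0, z = 0.0;   // z >= 0 inside the medium
    // launch direction within the fiber acceptance cone, into the medium
    double uz = cos_launch + (1.0 - cos_launch) * rng.unif();
    double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    double phi = 2.0 * M_PI * rng.unif();
    double ux = st * std::cos(phi), uy = st * std::sin(phi);
    double w = 1.0, L = 0.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.unif()) / mut;
      while (s > 0.0) {
        double z_new = z + uz * s;
        if (z_new < 0.0) {
          // hits the surface before completing the step
          double sb = z / (-uz);
          x += ux * sb; y += uy * sb; L += sb;
          s -= sb; z = 0.0;
          double cos_i = -uz;
          double rf = (n_rel == 1.0) ? 0.0 : fresnel_unpolarized(cos_i, n_rel);
          if (rf > 0.0 && rng.unif() < rf) {
            uz = -uz;  // reflected back into the medium, finish the step
            continue;
          }
          // transmitted: refract the exit angle if index-mismatched
          double cos_out = cos_i;
          if (n_rel != 1.0) {
            double sin_t = n_rel * std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
            cos_out = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
          }
          double rd = std::sqrt((x - r0) * (x - r0) + y * y);
          if (rd <= r_max) {
            vL.push_back(L); vR.push_back(rd); vR0.push_back(r0);
            vW.push_back(w); vUZ.push_back(cos_out);
          }
          alive = false;
          break;
        }
        x += ux * s; y += uy * s; z = z_new; L += s;
        s = 0.0;
      }
      if (!alive) break;
      if (L > l_max) { ++n_truncated; break; }
      // scattering event
      if (mua > 0.0) {
        w *= albedo;
        if (w < w_min) {
          if (rng.unif() < p_survive) w /= p_survive; else break;
        }
      }
      double ct;
      if (g == 0.0) {
        ct = 2.0 * rng.unif() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      }
      double stt = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double ph = 2.0 * M_PI * rng.unif();
      double cph = std::cos(ph), sph = std::sin(ph);
      if (std::fabs(uz) > 0.99999) {
        ux = stt * cph; uy = stt * sph; uz = (uz >= 0 ? 1.0 : -1.0) * ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nx = stt * (ux * uz * cph - uy * sph) / den + ux * ct;
        double ny = stt * (uy * uz * cph + ux * sph) / den + uy * ct;
        double nz = -stt * cph * den + uz * ct;
        ux = nx; uy = ny; uz = nz;
      }
    }
  }

  size_t n = vL.size();
  NumericMatrix rec(n, 5);
  for (size_t i = 0; i < n; ++i) {
    rec(i, 0) = vL[i]; rec(i, 1) = vR[i]; rec(i, 2) = vR0[i];
    rec(i, 3) = vW[i]; rec(i, 4) = vUZ[i];
  }
  colnames(rec) = CharacterVector::create("L", "r_disp", "r0", "w", "uz");
  return List::create(_["records"] = rec, _["n_launched"] = n_photons,
                      _["n_truncated"] = (double)n_truncated);
}

// Probe reflectance for each (mua, scale) pair; scale = mus_ref / mus(lambda).
// Returns a 3 x n matrix: estimate, Monte Carlo SE, effective capture count.
// [[Rcpp::export]]
NumericMatrix mc_reflectance(NumericMatrix records, double n_launched,
                             NumericVector mua, NumericVector scale,
                             double sep, double r_det, double r_src,
                             double cos_acc) {
  CaptureTable cap(r_src, sep, r_det);
  int nw = mua.size();
  if (scale.size() != nw) stop("mua and scale must have equal length");
  size_t nrec = records.nrow();
  NumericMatrix out(3, nw);
  for (int k = 0; k < nw; ++k) {
    double s = scale[k], a = mua[k];
    double sum = 0.0, sum2 = 0.0, neff = 0.0;
    for (size_t i = 0; i < nrec; ++i) {
      if (records(i, 4) < cos_acc) continue;
      double f = cap(records(i, 2), records(i, 1) * s);
      if (f <= 0.0) continue;
      double c = records(i, 3) * f * std::exp(-a * records(i, 0) * s);
      sum += c; sum2 += c * c; neff += 1.0;
    }
    double mean = sum / n_launched;
    double varc = (sum2 - sum * sum / n_launched) / n_launched;
    out(0, k) = mean;
    out(1, k) = std::sqrt(std::max(0.0, varc)) / std::sqrt(n_launched);
    out(2, k) = neff;
  }
  return out;
}

// Reflectance lookup table over a (mua, scale) grid, for fast inversion.
// Rows index mua_grid, columns scale_grid.
// [[Rcpp::export]]
NumericMatrix mc_lut(NumericMatrix records, double n_launched,
                     NumericVector mua_grid, NumericVector scale_grid,
                     double sep, double r_det, double r_src, double cos_acc) {
  CaptureTable cap(r_src, sep, r_det);
  int na = mua_grid.size(), ns = scale_grid.size();
  size_t nrec = records.nrow();
  NumericMatrix out(na, ns);
  std::vector<double> gw, gl;
  gw.reserve(nrec / 8); gl.reserve(nrec / 8);
  for (int j = 0; j < ns; ++j) {
    double s = scale_grid[j];
    gw.clear(); gl.clear();
    for (size_t i = 0; i < nrec; ++i) {
      if (records(i, 4) < cos_acc) continue;
      double f = cap(records(i, 2), records(i, 1) * s);
      if (f <= 0.0) continue;
      gw.push_back(records(i, 3) * f);
      gl.push_back(records(i, 0) * s);
    }
    for (int k = 0; k < na; ++k) {
      double a = mua_grid[k], sum = 0.0;
      for (size_t i = 0; i < gw.size(); ++i) sum += gw[i] * std::exp(-a * gl[i]);
      out(k, j) = sum / n_launched;
    }
  }
  return out;
}
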