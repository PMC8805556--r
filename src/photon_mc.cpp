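// Photon-packet transport in a homogeneous turbid half-space (z > 0) above a
// silicon probe shank occupying the z = 0 plane, with a rectangular photodiode
// window embedded in that plane. Henyey-Greenstein scattering, implicit
// absorption (weight deposition mu_a/mu_t per interaction), Russian roulette
// with an explicit energy ledger, and counter-based per-packet RNG streams so
// results depend only on (seed, packet index).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline uint64_t sm64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// One independent stream per (seed, stream index): splitmix64 seeded by a
// mix of the two, warmed up so nearby stream ids decorrelate immediately.
struct PRng {
  uint64_t s;
  PRng(uint64_t seed, uint64_t stream) {
    s = (seed * 0x9E3779B97F4A7C15ULL) ^
        (stream * 0xBF58476D1CE4E5B9ULL + 0x94D049BB133111EBULL);
    sm64(s); sm64(s);
  }
  // uniform in [0, 1)
  double u() { return (sm64(s) >> 11) * (1.0 / 9007199254740992.0); }
};

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

struct Scene {
  double mu_a, mu_s, g, mu_t;
  double ox, oy, oz, edge;
  int nx, ny, nz;
  double bx0, bx1, by0, by1, bz1; // grid box; bottom face sits in z = 0
  double wcx, wcy, whx, why;      // window centre and half extents
  double rr_thresh, rr_surv;
  double *flu;                    // fluence accumulator, may be NULL
  double dep, esc, shank, win, rr;
};

static void propagate(Scene &S, PRng &rng,
                      double px, double py, double pz,
                      double ux, double uy, double uz, double w) {
  const double INF = 1e300;
  for (int iter = 0; iter < 1000000; ++iter) {
    double s = (S.mu_t > 0.0) ? -std::log(1.0 - rng.u()) / S.mu_t : INF;
    double tp = (uz < 0.0) ? (-pz / uz) : INF;    // shank/window plane z = 0
    double tb = INF;                               // other box faces
    if (ux > 0.0) tb = std::min(tb, (S.bx1 - px) / ux);
    else if (ux < 0.0) tb = std::min(tb, (S.bx0 - px) / ux);
    if (uy > 0.0) tb = std::min(tb, (S.by1 - py) / uy);
    else if (uy < 0.0) tb = std::min(tb, (S.by0 - py) / uy);
    if (uz > 0.0) tb = std::min(tb, (S.bz1 - pz) / uz);

    if (tp <= s && tp <= tb) {
      // hits the probe plane: detected through the window, else absorbed by
      // the shank (reflections/refractions at interfaces are ignored)
      double hx = px + tp * ux, hy = py + tp * uy;
      if (std::fabs(hx - S.wcx) <= S.whx && std::fabs(hy - S.wcy) <= S.why)
        S.win += w;
      else
        S.shank += w;
      return;
    }
    if (tb < s) { S.esc += w; return; }

    // interaction: deposit mu_a/mu_t of the current weight in place
    px += s * ux; py += s * uy; pz += s * uz;
    if (S.mu_a > 0.0) {
      double d = w * S.mu_a / S.mu_t;
      int ix = (int)std::floor((px - S.ox) / S.edge);
      int iy = (int)std::floor((py - S.oy) / S.edge);
      int iz = (int)std::floor((pz - S.oz) / S.edge);
      if (ix >= 0 && ix < S.nx && iy >= 0 && iy < S.ny && iz >= 0 && iz < S.nz) {
        if (S.flu)
          S.flu[(size_t)ix + (size_t)S.nx * ((size_t)iy + (size_t)S.ny * iz)] += d;
        S.dep += d;
      } else {
        S.esc += d; // numerically on the boundary
      }
      w -= d;
    }

    if (w < S.rr_thresh) {
      if (rng.u() < S.rr_surv) {
        double w2 = w / S.rr_surv;
        S.rr -= (w2 - w); // energy ledger: boost borrowed from the residual
        w = w2;
      } else {
        S.rr += w;        // killed weight parked in the residual
        return;
      }
    }

    // Henyey-Greenstein deflection, uniform azimuth
    double ct = hg_cos(S.g, rng.u());
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double phi = 2.0 * M_PI * rng.u();
    double cp = std::cos(phi), sp = std::sin(phi);
    double nux, nuy, nuz;
    if (std::fabs(uz) > 0.999999) {
      nux = st * cp; nuy = st * sp; nuz = (uz > 0.0 ? ct : -ct);
    } else {
      double den = std::sqrt(1.0 - uz * uz);
      nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
      nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
      nuz = -st * cp * den + uz * ct;
    }
    double nn = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
    ux = nux / nn; uy = nuy / nn; uz = nuz / nn;
  }
  S.esc += w; // step-cap safety; never reached at realistic optical depths
}

static Scene make_scene(double mu_a, double mu_s, double g,
                        NumericVector origin, double edge, IntegerVector dims,
                        NumericVector window, double rr_thresh, double rr_surv,
                        double *flu) {
  Scene S;
  S.mu_a = mu_a; S.mu_s = mu_s; S.g = g; S.mu_t = mu_a + mu_s;
  S.ox = origin[0]; S.oy = origin[1]; S.oz = origin[2];
  S.edge = edge;
  S.nx = dims[0]; S.ny = dims[1]; S.nz = dims[2];
  S.bx0 = S.ox; S.bx1 = S.ox + S.nx * edge;
  S.by0 = S.oy; S.by1 = S.oy + S.ny * edge;
  S.bz1 = S.oz + S.nz * edge;
  S.wcx = window[0]; S.wcy = window[1]; S.whx = window[2]; S.why = window[3];
  S.rr_thresh = rr_thresh; S.rr_surv = rr_surv;
  S.flu = flu;
  S.dep = S.esc = S.shank = S.win = S.rr = 0.0;
  return S;
}

// [[Rcpp::export]]
NumericVector cpp_hg_cosine(double g, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// Source: packets launched uniformly over a disc of radius core_radius at
// fiber_tip, perpendicular to fiber_axis, directions uniform in solid angle
// within a cone of the given half-angle about the axis.
// [[Rcpp::export]]
List cpp_simulate_illumination(int n_packets, double seed,
                               double mu_a, double mu_s, double g,
                               NumericVector origin, double edge,
                               IntegerVector dims, NumericVector window,
                               NumericVector fiber_tip,
                               NumericVector fiber_axis,
                               double core_radius, double half_angle,
                               double power,
                               double rr_thresh, double rr_surv,
                               double stream_offset) {
  size_t nvox = (size_t)dims[0] * dims[1] * dims[2];
  NumericVector flu(nvox);
  Scene S = make_scene(mu_a, mu_s, g, origin, edge, dims, window,
                       rr_thresh, rr_surv, REAL(flu));

  double ax = fiber_axis[0], ay = fiber_axis[1], az = fiber_axis[2];
  double an = std::sqrt(ax * ax + ay * ay + az * az);
  ax /= an; ay /= an; az /= an;
  // orthonormal frame about the axis
  double hx = (std::fabs(az) < 0.9) ? 0.0 : 1.0;
  double hz = (std::fabs(az) < 0.9) ? 1.0 : 0.0;
  double e1x = ay * hz - az * 0.0, e1y = az * hx - ax * hz, e1z = ax * 0.0 - ay * hx;
  double e1n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= e1n; e1y /= e1n; e1z /= e1n;
  double e2x = ay * e1z - az * e1y;
  double e2y = az * e1x - ax * e1z;
  double e2z = ax * e1y - ay * e1x;

  double cmin = std::cos(half_angle);
  for (int i = 0; i < n_packets; ++i) {
    PRng rng((uint64_t)seed, (uint64_t)(stream_offset + i));
    double r = core_radius * std::sqrt(rng.u());
    double ph = 2.0 * M_PI * rng.u();
    double px = fiber_tip[0] + r * (std::cos(ph) * e1x + std::sin(ph) * e2x);
    double py = fiber_tip[1] + r * (std::cos(ph) * e1y + std::sin(ph) * e2y);
    double pz = fiber_tip[2] + r * (std::cos(ph) * e1z + std::sin(ph) * e2z);
    double ct = (half_angle > 0.0) ? 1.0 - rng.u() * (1.0 - cmin) : 1.0;
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double ps = 2.0 * M_PI * rng.u();
    double ux = ct * ax + st * (std::cos(ps) * e1x + std::sin(ps) * e2x);
    double uy = ct * ay + st * (std::cos(ps) * e1y + std::sin(ps) * e2y);
    double uz = ct * az + st * (std::cos(ps) * e1z + std::sin(ps) * e2z);
    propagate(S, rng, px, py, pz, ux, uy, uz, 1.0);
  }

  double sc = power / n_packets;
  for (size_t i = 0; i < nvox; ++i) flu[i] *= sc;
  return List::create(_["values"] = flu,
                      _["deposited"] = S.dep * sc,
                      _["escaped"] = S.esc * sc,
                      _["shank"] = S.shank * sc,
                      _["window"] = S.win * sc,
                      _["roulette_residual"] = S.rr * sc,
                      _["launched"] = power);
}

// Isotropic point source at each voxel centre; detection probability is the
// fraction of launched energy crossing the window rectangle.
// [[Rcpp::export]]
List cpp_simulate_acceptance(int n_per_voxel, double seed,
                             double mu_a, double mu_s, double g,
                             NumericVector origin, double edge,
                             IntegerVector dims, NumericVector window,
                             double rr_thresh, double rr_surv) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector p(nvox);
  double esc_tot = 0.0, dep_tot = 0.0, rr_tot = 0.0, shank_tot = 0.0;

  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        size_t vi = (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
        Scene S = make_scene(mu_a, mu_s, g, origin, edge, dims, window,
                             rr_thresh, rr_surv, (double *)0);
        double cx = origin[0] + (ix + 0.5) * edge;
        double cy = origin[1] + (iy + 0.5) * edge;
        double cz = origin[2] + (iz + 0.5) * edge;
        for (int j = 0; j < n_per_voxel; ++j) {
          // distinct stream per (voxel, packet), offset from illumination ids
          PRng rng((uint64_t)seed,
                   0x4000000000000000ULL + vi * (uint64_t)n_per_voxel + j);
          double ct = 2.0 * rng.u() - 1.0;
          double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
          double ph = 2.0 * M_PI * rng.u();
          propagate(S, rng, cx, cy, cz,
                    st * std::cos(ph), st * std::sin(ph), ct, 1.0);
        }
        double pv = S.win / n_per_voxel;
        if (pv > 1.0) pv = 1.0;
        p[vi] = pv;
        esc_tot += S.esc; dep_tot += S.dep; rr_tot += S.rr; shank_tot += S.shank;
      }
    }
  }
  return List::create(_["values"] = p,
                      _["deposited"] = dep_tot,
                      _["escaped"] = esc_tot,
                      _["shank"] = shank_tot,
                      _["roulette_residual"] = rr_tot,
                      _["launched"] = (double)nvox * n_per_voxel);
}
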