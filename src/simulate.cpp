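#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Piecewise-constant light lookup over segments [start, end); holds the last
// level beyond the protocol.  Queries must be non-decreasing in t, which is
// guaranteed by the fixed-step integrators below.
struct LightLookup {
  std::vector<double> seg_end;
  std::vector<double> seg_level;
  int idx;
  LightLookup(const NumericMatrix& segs) : idx(0) {
    const int n = segs.nrow();
    seg_end.resize(n);
    seg_level.resize(n);
    for (int k = 0; k < n; ++k) {
      seg_end[k] = segs(k, 1);
      seg_level[k] = segs(k, 2);
    }
    if (n == 0) { seg_end.push_back(R_PosInf); seg_level.push_back(0.0); }
  }
  inline double at(double t) {
    const int last = (int)seg_end.size() - 1;
    while (idx < last && t >= seg_end[idx]) ++idx;
    return seg_level[idx];
  }
  inline void reset() { idx = 0; }
};

// Counter-based per-cell RNG: xoshiro256++ seeded by splitmix64 from
// (seed, cell), with polar-method standard normals.  Each cell owns an
// independent stream, so its draws do not depend on how many other cells
// are simulated or recorded.
struct CellRNG {
  uint64_t s[4];
  bool has_spare;
  double spare;
  static inline uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  CellRNG(uint64_t seed, uint64_t cell) : has_spare(false), spare(0.0) {
    uint64_t x = seed ^ (0xD1B54A32D192ED03ULL * (cell + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double m = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * m; has_spare = true;
    return u * m;
  }
};

// Transcription activation: protein sequestration with dissociation constant
// K, or its K -> 0 piecewise limit when K < 0 is passed as a sentinel.
inline double activation(double R, double A, double K) {
  if (K < 0.0) {
    const double r = R / A;
    return (r <= 1.0) ? 1.0 - r : 0.0;
  }
  const double q = A - R - K;
  return (q + std::sqrt(q * q + 4.0 * A * K)) / (2.0 * A);
}

inline void check_finite(double M, double P, double R, int step, double t) {
  if (!(std::isfinite(M) && std::isfinite(P) && std::isfinite(R)))
    stop("non-finite state at integration step %d (t = %.3f h)", step, t);
}

// Euler-Maruyama core for one cell.  Writes luminescence every `thin` steps
// into rec (length n_steps/thin + 1, including t = 0) when rec != NULL and
// the full state into states (same length) when states != NULL.
static void em_run(const double* par, LightLookup& light, double* x,
                   double dt, int n_steps, int thin, double sigma,
                   CellRNG* rng, double* rec, double* recM, double* recP,
                   double* recR, double* rec_t) {
  const double A = par[0], dM = par[1], dP = par[2], dR = par[3],
               ilight = par[4], K = par[5];
  double M = x[0], P = x[1], R = x[2], t = 0.0;
  const double sqdt = std::sqrt(dt);
  light.reset();
  int k = 0;
  if (rec) {
    rec[k] = activation(R, A, K);
    if (recM) { recM[k] = M; recP[k] = P; recR[k] = R; rec_t[k] = 0.0; }
    ++k;
  }
  for (int s = 1; s <= n_steps; ++s) {
    const double I = light.at(t);
    const double f = activation(R, A, K);
    const double dMv = f - dM * M + ilight * I;
    const double dPv = M - dP * P;
    const double dRv = P - dR * R;
    if (sigma > 0.0 && rng) {
      M += dMv * dt + sigma * sqdt * rng->norm();
      P += dPv * dt + sigma * sqdt * rng->norm();
      R += dRv * dt + sigma * sqdt * rng->norm();
    } else {
      M += dMv * dt; P += dPv * dt; R += dRv * dt;
    }
    t = s * dt;
    check_finite(M, P, R, s, t);
    if (rec && (s % thin == 0)) {
      rec[k] = activation(R, A, K);
      if (recM) { recM[k] = M; recP[k] = P; recR[k] = R; rec_t[k] = t; }
      ++k;
    }
  }
  x[0] = M; x[1] = P; x[2] = R;
}

// Single stochastic cell on its own stream (seed, cell).
// par = (A, d_M, d_P, d_R, i, K) with K < 0 meaning the piecewise limit.
// [[Rcpp::export]]
List cpp_simulate_cell(NumericVector par, NumericMatrix segs,
                       NumericVector x0, double dt, int n_steps, int thin,
                       double sigma, double seed, double cell) {
  LightLookup light(segs);
  CellRNG rng((uint64_t)seed, (uint64_t)cell);
  const int n_rec = n_steps / thin + 1;
  NumericMatrix out(n_rec, 5);
  std::vector<double> lum(n_rec), m(n_rec), p(n_rec), r(n_rec), tt(n_rec);
  double x[3] = {x0[0], x0[1], x0[2]};
  em_run(&par[0], light, x, dt, n_steps, thin, sigma, &rng, lum.data(),
         m.data(), p.data(), r.data(), tt.data());
  for (int k = 0; k < n_rec; ++k) {
    out(k, 0) = tt[k]; out(k, 1) = m[k]; out(k, 2) = p[k];
    out(k, 3) = r[k]; out(k, 4) = lum[k];
  }
  return List::create(_["traj"] = out,
                      _["final"] = NumericVector::create(x[0], x[1], x[2]));
}

// Population of n independent cells: pointwise mean luminescence, with the
// first n_record single-cell luminescence traces retained.  preroll_steps
// of constant darkness per cell (discarded) optionally disperse phases
// before t = 0.
// [[Rcpp::export]]
List cpp_simulate_population(NumericVector par, NumericMatrix segs,
                             NumericVector x0, double dt, int n_steps,
                             int thin, double sigma, int n, double seed,
                             int n_record, int preroll_steps) {
  LightLookup light(segs);
  NumericMatrix dark(1, 3);
  dark(0, 0) = 0.0; dark(0, 1) = R_PosInf; dark(0, 2) = 0.0;
  LightLookup darkness(dark);
  const int n_rec = n_steps / thin + 1;
  NumericVector mean_lum(n_rec);
  NumericMatrix cells(n_record > 0 ? n_rec : 0, n_record);
  std::vector<double> lum(n_rec);
  for (int j = 1; j <= n; ++j) {
    CellRNG rng((uint64_t)seed, (uint64_t)j);
    double x[3] = {x0[0], x0[1], x0[2]};
    if (preroll_steps > 0)
      em_run(&par[0], darkness, x, dt, preroll_steps, preroll_steps, sigma,
             &rng, nullptr, nullptr, nullptr, nullptr, nullptr);
    em_run(&par[0], light, x, dt, n_steps, thin, sigma, &rng, lum.data(),
           nullptr, nullptr, nullptr, nullptr);
    for (int k = 0; k < n_rec; ++k) mean_lum[k] += lum[k];
    if (j <= n_record)
      for (int k = 0; k < n_rec; ++k) cells(k, j - 1) = lum[k];
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < n_rec; ++k) mean_lum[k] /= n;
  NumericVector times(n_rec);
  for (int k = 0; k < n_rec; ++k) times[k] = (double)k * thin * dt;
  return List::create(_["time"] = times, _["mean_lum"] = mean_lum,
                      _["cells"] = cells);
}

// Classical RK4 integration of the deterministic (sigma = 0) clock.
// [[Rcpp::export]]
List cpp_simulate_rk4(NumericVector par, NumericMatrix segs, NumericVector x0,
                      double dt, int n_steps, int thin, bool record) {
  const double A = par[0], dM = par[1], dP = par[2], dR = par[3],
               ilight = par[4], K = par[5];
  double M = x0[0], P = x0[1], R = x0[2], t = 0.0;
  LightLookup light(segs);

  const int n_rec = record ? n_steps / thin + 1 : 0;
  NumericMatrix out(n_rec, 5);
  int k = 0;
  if (record) {
    out(k, 0) = 0.0; out(k, 1) = M; out(k, 2) = P; out(k, 3) = R;
    out(k, 4) = activation(R, A, K);
    ++k;
  }

  double kM[4], kP[4], kR[4];
  for (int s = 1; s <= n_steps; ++s) {
    // light levels at the three RK4 abscissae (queries stay non-decreasing)
    const double I0 = light.at(t);
    const double Ih = light.at(t + 0.5 * dt);
    const double I1 = light.at(t + dt);
    const double Isub[4] = {I0, Ih, Ih, I1};
    const double c[4] = {0.0, 0.5, 0.5, 1.0};
    for (int j = 0; j < 4; ++j) {
      const double Mj = M + (j > 0 ? c[j] * dt * kM[j - 1] : 0.0);
      const double Pj = P + (j > 0 ? c[j] * dt * kP[j - 1] : 0.0);
      const double Rj = R + (j > 0 ? c[j] * dt * kR[j - 1] : 0.0);
      kM[j] = activation(Rj, A, K) - dM * Mj + ilight * Isub[j];
      kP[j] = Mj - dP * Pj;
      kR[j] = Pj - dR * Rj;
    }
    M += dt / 6.0 * (kM[0] + 2.0 * kM[1] + 2.0 * kM[2] + kM[3]);
    P += dt / 6.0 * (kP[0] + 2.0 * kP[1] + 2.0 * kP[2] + kP[3]);
    R += dt / 6.0 * (kR[0] + 2.0 * kR[1] + 2.0 * kR[2] + kR[3]);
    t = s * dt;
    check_finite(M, P, R, s, t);
    if (record && (s % thin == 0) && k < n_rec) {
      out(k, 0) = t; out(k, 1) = M; out(k, 2) = P; out(k, 3) = R;
      out(k, 4) = activation(R, A, K);
      ++k;
    }
  }
  return List::create(_["traj"] = out,
                      _["final"] = NumericVector::create(M, P, R));
}
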