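#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// xoshiro256++ (Blackman & Vigna), seeded from R's RNG stream at the start of
// every call: trajectories remain fully reproducible under set.seed() while
// uniform draws stay cheap inside the hot loop.
namespace {

struct Xoshiro256 {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro256(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]: never 0, so -log() is always finite
  double runif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
};

}  // namespace

// Gillespie direct-method SSA with mass-action propensities of order 0-2 and
// an optional time-varying zero-order "drive" reaction (used by the hybrid
// scheme, where the birth propensity of nuclear Fus3-PP is the clamped
// derivative of the deterministic trajectory). The drive is supplied as a
// piecewise-linear function of time; time inhomogeneity is handled exactly by
// thinning against the drive's global maximum.
//
// x0            initial molecule counts
// nu            stoichiometry matrix (species x reactions)
// rate          per-reaction propensity constants
// r1, r2        0-based reactant indices (-1: absent); propensity =
//               rate * x[r1] * x[r2] over the present indices
// report_times  strictly increasing times (>= t0) at which counts are taken
// t0            simulation start time (counts before t0 equal x0)
// drive_t/v     breakpoints of the piecewise-linear drive (empty: no drive)
// drive_species species incremented by a drive event
//
// The local PRNG is seeded from R's RNG stream, so runs are reproducible
// under set.seed(). Returns a matrix of counts, rows = report times. When the
// total propensity reaches zero the state is frozen to the end of the run.
// [[Rcpp::export]]
NumericMatrix ssa_direct_cpp(NumericVector x0, IntegerMatrix nu,
                             NumericVector rate, IntegerVector r1,
                             IntegerVector r2, NumericVector report_times,
                             double t0, NumericVector drive_t,
                             NumericVector drive_v, int drive_species) {
  const int ns = x0.size();
  const int nr = rate.size();
  const int nt = report_times.size();
  if (nu.nrow() != ns || nu.ncol() != nr)
    stop("stoichiometry matrix does not match species/reactions");

  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix out(nt, ns);

  uint64_t seed64 = (uint64_t)(unif_rand() * 4294967296.0) << 32;
  seed64 |= (uint64_t)(unif_rand() * 4294967296.0);
  Xoshiro256 rng(seed64);

  const bool has_drive = drive_species >= 0 && drive_t.size() >= 2;
  double drive_max = 0.0;
  for (int i = 0; i < drive_v.size(); ++i)
    if (drive_v[i] > drive_max) drive_max = drive_v[i];

  // per-reaction sparse stoichiometry for cheap state updates
  std::vector<std::vector<std::pair<int, int> > > delta(nr);
  for (int j = 0; j < nr; ++j)
    for (int s = 0; s < ns; ++s)
      if (nu(s, j) != 0) delta[j].push_back(std::make_pair(s, nu(s, j)));

  // reactions whose propensity depends on each species (for incremental
  // propensity updates after an event)
  std::vector<std::vector<int> > dep(ns);
  for (int j = 0; j < nr; ++j) {
    if (r1[j] >= 0) dep[r1[j]].push_back(j);
    if (r2[j] >= 0 && r2[j] != r1[j]) dep[r2[j]].push_back(j);
  }

  int di = 0;  // running drive segment (t is non-decreasing)
  const int nd = drive_t.size();
  double t = t0;
  int ti = 0;
  std::vector<double> a(nr);
  unsigned long long iter = 0;

  double a0 = 0.0;
  for (int j = 0; j < nr; ++j) {
    double aj = rate[j];
    if (r1[j] >= 0) aj *= x[r1[j]];
    if (r2[j] >= 0) aj *= x[r2[j]];
    a[j] = aj;
    a0 += aj;
  }

  while (ti < nt) {
    // guard against floating-point drift of the incrementally updated total
    if ((iter & 0xFFFFF) == 0xFFFFF) {
      a0 = 0.0;
      for (int j = 0; j < nr; ++j) a0 += a[j];
    }
    const double bound = a0 + (has_drive ? drive_max : 0.0);
    if (bound <= 0.0) break;  // nothing can fire: freeze state

    const double tau = -std::log(rng.runif()) / bound;
    const double tnew = t + tau;
    while (ti < nt && report_times[ti] < tnew) {
      for (int s = 0; s < ns; ++s) out(ti, s) = x[s];
      ++ti;
    }
    if (ti >= nt) break;
    t = tnew;

    double d = 0.0;
    if (has_drive) {
      if (t <= drive_t[0]) {
        d = drive_v[0];
      } else if (t >= drive_t[nd - 1]) {
        d = drive_v[nd - 1];
      } else {
        while (di < nd - 2 && drive_t[di + 1] < t) ++di;
        const double w = (t - drive_t[di]) / (drive_t[di + 1] - drive_t[di]);
        d = drive_v[di] + w * (drive_v[di + 1] - drive_v[di]);
      }
    }

    const double u = rng.runif() * bound;
    if (u >= a0 + d) {
      // thinned (phantom) event: state unchanged
    } else if (u < a0) {
      int j = 0;
      double cum = a[0];
      while (u > cum && j < nr - 1) {
        ++j;
        cum += a[j];
      }
      const std::vector<std::pair<int, int> >& dj = delta[j];
      for (size_t k = 0; k < dj.size(); ++k) {
        const int s = dj[k].first;
        x[s] += dj[k].second;
        const std::vector<int>& ds = dep[s];
        for (size_t q = 0; q < ds.size(); ++q) {
          const int jj = ds[q];
          double aj = rate[jj];
          if (r1[jj] >= 0) aj *= x[r1[jj]];
          if (r2[jj] >= 0) aj *= x[r2[jj]];
          a0 += aj - a[jj];
          a[jj] = aj;
        }
      }
    } else {
      x[drive_species] += 1.0;
      const std::vector<int>& ds = dep[drive_species];
      for (size_t q = 0; q < ds.size(); ++q) {
        const int jj = ds[q];
        double aj = rate[jj];
        if (r1[jj] >= 0) aj *= x[r1[jj]];
        if (r2[jj] >= 0) aj *= x[r2[jj]];
        a0 += aj - a[jj];
        a[jj] = aj;
      }
    }
    if ((++iter & 0xFFFFF) == 0) checkUserInterrupt();
  }

  // freeze remaining report rows at the final state
  for (; ti < nt; ++ti)
    for (int s = 0; s < ns; ++s) out(ti, s) = x[s];
  return out;
}
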