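// Approximated simulated annealing over bead-chain configurations.
// The chain is represented compactly: centroids (n x 3) and shared
// endpoints ((n+1) x 3); pivot and crankshaft moves rotate contiguous
// stretches rigidly via quaternion conjugation, so shared-endpoint
// continuity and intra-bead geometry are preserved by construction.
// A private mt19937-based generator keeps runs bit-reproducible per seed.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(unsigned int seed) : gen(seed) {}
  // 53-bit uniform in [0, 1); implementation-independent given mt19937
  double unif() {
    uint64_t hi = gen() >> 5, lo = gen() >> 6;
    return (hi * 67108864.0 + lo) / 9007199254740992.0;
  }
  int unif_int(int k) {  // in [0, k)
    int v = static_cast<int>(unif() * k);
    return v >= k ? k - 1 : v;
  }
};

struct Vec3 { double x, y, z; };

inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 add(const Vec3& a, const Vec3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline double norm(const Vec3& a) { return std::sqrt(a.x * a.x + a.y * a.y + a.z * a.z); }

struct Quat { double w, x, y, z; };

inline Quat quat_axis_angle(const Vec3& u, double angle) {
  double s = std::sin(angle / 2.0);
  return {std::cos(angle / 2.0), s * u.x, s * u.y, s * u.z};
}

// rotate v by unit quaternion q (conjugation q v q*)
inline Vec3 quat_rotate(const Quat& q, const Vec3& v) {
  // t = 2 * (q.xyz x v); v' = v + q.w * t + q.xyz x t
  Vec3 qv = {q.x, q.y, q.z};
  Vec3 t = {2.0 * (qv.y * v.z - qv.z * v.y),
            2.0 * (qv.z * v.x - qv.x * v.z),
            2.0 * (qv.x * v.y - qv.y * v.x)};
  Vec3 c = {qv.y * t.z - qv.z * t.y, qv.z * t.x - qv.x * t.z,
            qv.x * t.y - qv.y * t.x};
  return {v.x + q.w * t.x + c.x, v.y + q.w * t.y + c.y, v.z + q.w * t.z + c.z};
}

struct ChainState {
  std::vector<Vec3> cent;  // n
  std::vector<Vec3> endp;  // n + 1
};

struct Problem {
  std::vector<int> ci, cj;          // restrained pairs (0-based)
  std::vector<double> cn, cdmin;    // counts, touching distances
  std::vector<double> radii;
  bool chip, rna;
  double d_min_target, d_max_target;
  double mu1, mu2, lambda, c;
  int b;
};

inline double odd_pow(double x, int b) {
  double r = 1.0;
  for (int k = 0; k < b; ++k) r *= x;
  return r;
}

double total_cost(const ChainState& s, const Problem& P) {
  double hic = 0.0;
  for (size_t k = 0; k < P.ci.size(); ++k) {
    Vec3 d = sub(s.cent[P.ci[k]], s.cent[P.cj[k]]);
    double dd = norm(d);
    if (dd == 0.0) return R_PosInf;
    double t = P.cdmin[k] / dd - 1.0;
    hic += P.cn[k] * t * t;
  }
  int n = static_cast<int>(s.cent.size());
  double ps = 0.0, dmax = 0.0, dmin_all = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dd = norm(sub(s.cent[i], s.cent[j]));
      if (dd > dmax) dmax = dd;
      if (dd < dmin_all) dmin_all = dd;
      double dt = dd / (P.radii[i] + P.radii[j]);
      if (dt == 0.0) return R_PosInf;
      double u = dt - 1.0 / dt;
      double ub = odd_pow(u, P.b);
      ps += (1.0 / (2.0 * dt)) * (1.0 - P.c * ub / (1.0 + P.c * std::fabs(ub)));
    }
  }
  double chip = 0.0, rna = 0.0;
  if (P.chip && n >= 2) { double e = dmax - P.d_min_target; chip = e * e; }
  if (P.rna && n >= 2) { double e = dmin_all - P.d_max_target; rna = e * e; }
  return hic + P.mu1 * chip + P.mu2 * rna + P.lambda * ps;
}

inline Vec3 random_unit(Rng& rng) {
  double z = 2.0 * rng.unif() - 1.0;
  double phi = 2.0 * M_PI * rng.unif();
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  return {r * std::cos(phi), r * std::sin(phi), z};
}

// rotate centroids [c0, c1] and endpoints [e0, e1] (inclusive) about an axis
void rotate_range(ChainState& s, int c0, int c1, int e0, int e1,
                  const Vec3& origin, const Vec3& axis, double angle) {
  Quat q = quat_axis_angle(axis, angle);
  for (int k = c0; k <= c1; ++k)
    s.cent[k] = add(quat_rotate(q, sub(s.cent[k], origin)), origin);
  for (int k = e0; k <= e1; ++k)
    s.endp[k] = add(quat_rotate(q, sub(s.endp[k], origin)), origin);
}

// one random pivot or crankshaft move, applied in place
void propose(ChainState& s, Rng& rng, double theta_max) {
  int n = static_cast<int>(s.cent.size());
  if (n < 2) return;
  bool pivot = (n < 3) || (rng.unif() < 0.5);
  double angle = (2.0 * rng.unif() - 1.0) * theta_max;
  if (pivot) {
    int k = 1 + rng.unif_int(n - 1);          // bead k rotates onward
    Vec3 origin = s.endp[k];
    Vec3 axis = random_unit(rng);
    rotate_range(s, k, n - 1, k + 1, n, origin, axis, angle);
  } else {
    int p = rng.unif_int(n - 2);              // beads p+1 .. q-1 rotate
    int q = p + 2 + rng.unif_int(n - 1 - (p + 2) + 1);
    Vec3 origin = s.endp[p + 1];
    Vec3 ax = sub(s.endp[q], s.endp[p + 1]);
    double L = norm(ax);
    if (L < 1e-9) return;                     // degenerate hinge: identity
    Vec3 axis = {ax.x / L, ax.y / L, ax.z / L};
    rotate_range(s, p + 1, q - 1, p + 2, q - 1, origin, axis, angle);
  }
}

ChainState state_from_r(const NumericMatrix& cent, const NumericMatrix& endp) {
  ChainState s;
  int n = cent.nrow();
  s.cent.resize(n);
  s.endp.resize(endp.nrow());
  for (int k = 0; k < n; ++k) s.cent[k] = {cent(k, 0), cent(k, 1), cent(k, 2)};
  for (int k = 0; k < endp.nrow(); ++k) s.endp[k] = {endp(k, 0), endp(k, 1), endp(k, 2)};
  return s;
}

NumericMatrix mat_from_state(const std::vector<Vec3>& v) {
  NumericMatrix m(static_cast<int>(v.size()), 3);
  for (size_t k = 0; k < v.size(); ++k) {
    m(k, 0) = v[k].x; m(k, 1) = v[k].y; m(k, 2) = v[k].z;
  }
  return m;
}

}  // namespace

// [[Rcpp::export]]
List anneal_cpp(NumericMatrix centroids, NumericMatrix endpoints,
                NumericVector radii,
                IntegerVector pair_i, IntegerVector pair_j,
                NumericVector pair_n, NumericVector pair_dmin,
                bool chip_flag, double d_min_target,
                bool rna_flag, double d_max_target,
                double mu1, double mu2, double lambda, int b, double c,
                double t0, double cooling, int stages, int moves_per_stage,
                double theta_max, int seed) {
  Problem P;
  P.ci.assign(pair_i.begin(), pair_i.end());
  P.cj.assign(pair_j.begin(), pair_j.end());
  P.cn.assign(pair_n.begin(), pair_n.end());
  P.cdmin.assign(pair_dmin.begin(), pair_dmin.end());
  P.radii.assign(radii.begin(), radii.end());
  P.chip = chip_flag; P.rna = rna_flag;
  P.d_min_target = d_min_target; P.d_max_target = d_max_target;
  P.mu1 = mu1; P.mu2 = mu2; P.lambda = lambda; P.b = b; P.c = c;

  Rng rng(static_cast<unsigned int>(seed));
  ChainState cur = state_from_r(centroids, endpoints);
  double cur_cost = total_cost(cur, P);

  // T0 calibration: median |delta| of 100 probe moves accepted with p ~ 0.8
  if (!(t0 > 0.0)) {
    std::vector<double> deltas;
    for (int k = 0; k < 100; ++k) {
      ChainState probe = cur;
      propose(probe, rng, theta_max);
      double d = std::fabs(total_cost(probe, P) - cur_cost);
      if (std::isfinite(d) && d > 0.0) deltas.push_back(d);
    }
    if (deltas.empty()) {
      t0 = 1.0;
    } else {
      std::sort(deltas.begin(), deltas.end());
      double med = deltas[deltas.size() / 2];
      t0 = med / (-std::log(0.8));
      if (!(t0 > 0.0)) t0 = 1.0;
    }
  }

  ChainState best = cur;
  double best_cost = cur_cost;
  NumericVector trace(stages);
  double T = t0;
  long accepted = 0, proposed = 0;
  for (int stage = 0; stage < stages; ++stage) {
    for (int mv = 0; mv < moves_per_stage; ++mv) {
      ChainState cand = cur;
      propose(cand, rng, theta_max);
      double cand_cost = total_cost(cand, P);
      ++proposed;
      bool accept;
      if (cand_cost <= cur_cost) {
        accept = true;
      } else if (std::isfinite(cand_cost) && std::isfinite(cur_cost)) {
        accept = rng.unif() < std::exp(-(cand_cost - cur_cost) / T);
      } else {
        accept = false;
      }
      if (accept) {
        cur = std::move(cand);
        cur_cost = cand_cost;
        ++accepted;
        if (cur_cost < best_cost) { best = cur; best_cost = cur_cost; }
      }
    }
    trace[stage] = best_cost;
    T *= cooling;
  }
  return List::create(
      _["centroids"] = mat_from_state(best.cent),
      _["endpoints"] = mat_from_state(best.endp),
      _["best_cost"] = best_cost,
      _["initial_cost"] = total_cost(state_from_r(centroids, endpoints), P),
      _["trace"] = trace,
      _["acceptance_rate"] = proposed > 0 ? double(accepted) / double(proposed) : NA_REAL,
      _["t0"] = t0);
}

// Acceptance probe at fixed temperature: fraction of 'n_probes' single moves
// from the given state that Metropolis would accept at temperature t.
// [[Rcpp::export]]
double acceptance_probe_cpp(NumericMatrix centroids, NumericMatrix endpoints,
                            NumericVector radii,
                            IntegerVector pair_i, IntegerVector pair_j,
                            NumericVector pair_n, NumericVector pair_dmin,
                            bool chip_flag, double d_min_target,
                            bool rna_flag, double d_max_target,
                            double mu1, double mu2, double lambda, int b, double c,
                            double t, double theta_max, int n_probes, int seed) {
  Problem P;
  P.ci.assign(pair_i.begin(), pair_i.end());
  P.cj.assign(pair_j.begin(), pair_j.end());
  P.cn.assign(pair_n.begin(), pair_n.end());
  P.cdmin.assign(pair_dmin.begin(), pair_dmin.end());
  P.radii.assign(radii.begin(), radii.end());
  P.chip = chip_flag; P.rna = rna_flag;
  P.d_min_target = d_min_target; P.d_max_target = d_max_target;
  P.mu1 = mu1; P.mu2 = mu2; P.lambda = lambda; P.b = b; P.c = c;
  Rng rng(static_cast<unsigned int>(seed));
  ChainState cur = state_from_r(centroids, endpoints);
  double cur_cost = total_cost(cur, P);
  int acc = 0;
  for (int k = 0; k < n_probes; ++k) {
    ChainState cand = cur;
    propose(cand, rng, theta_max);
    double cc = total_cost(cand, P);
    if (cc <= cur_cost || (std::isfinite(cc) &&
        rng.unif() < std::exp(-(cc - cur_cost) / t)))
      ++acc;
  }
  return double(acc) / double(n_probes);
}
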