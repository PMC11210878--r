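#include "models.h"
#include <random>
using namespace Rcpp;

// Portable normal draws: explicit Box-Muller on top of mt19937_64 so that
// ensembles replay identically across platforms and compilers.
struct NormalGen {
  std::mt19937_64 gen;
  bool have_spare = false;
  double spare = 0.0;
  explicit NormalGen(uint32_t master, uint32_t idx) {
    std::seed_seq ss{master, idx, 0x9E3779B9u};
    gen.seed(ss);
  }
  double unif() {
    // in (0, 1]
    return ((gen() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 6.283185307179586 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

struct PolicySpec {
  int type; // 0 constant, 1 field (q,p), 2 cube (q,p,s)
  double const_dose;
  const int* field; // nq x np
  const Rbyte* cube; // nq x np x ns
  int nq, np, ns;
  double hq, hp, gr, ds_slice; // uniform s-slice spacing (slices 0..ns-1 at k*ds_slice)
  double s0; // s of first slice (0)
};

static inline double lookup_dose(const PolicySpec& ps, const Model& m,
                                 double q, double p, double s) {
  if (ps.type == 0) return ps.const_dose;
  int i = (int)std::lround(q / ps.hq);
  int j = (int)std::lround((p - ps.gr) / ps.hp);
  if (i < 0) i = 0; if (i > ps.nq - 1) i = ps.nq - 1;
  if (j < 0) j = 0; if (j > ps.np - 1) j = ps.np - 1;
  if (ps.type == 1) return ps.field[i + ps.nq * j] ? m.dmax : 0.0;
  int k = (int)std::lround(s / ps.ds_slice);
  if (k < 0) k = 0; if (k > ps.ns - 1) k = ps.ns - 1;
  return ps.cube[i + ps.nq * ((size_t)j + (size_t)ps.np * k)] ? m.dmax : 0.0;
}

// Euler-Maruyama simulation of N therapy courses under a primary feedback
// policy with budget tracking (ds/dt = -K) and fallback dosing once the budget
// is depleted. Barrier crossings are refined by linear interpolation within
// the step. Counter-based per-path seeding gives deterministic replay.
// outcome codes: 1 success, 2 failure (death), 0 censored at tmax.
// [[Rcpp::export]]
List simulate_ensemble_cpp(int tag, NumericVector par,
                           List primary, List fallback,
                           double q0, double p0, double sbar,
                           double dt, int N, int seed, double tmax,
                           bool record_path, int store_every,
                           int counter0) {
  Model m(tag, par);

  auto make_spec = [&](List pl, IntegerVector& keepf, RawVector& keepc,
                       NumericVector& keeps) {
    PolicySpec ps{};
    ps.type = as<int>(pl["type"]);
    ps.gr = m.gr;
    if (ps.type == 0) {
      ps.const_dose = as<double>(pl["dose"]);
    } else if (ps.type == 1) {
      keepf = as<IntegerVector>(pl["field"]);
      IntegerVector dim = keepf.attr("dim");
      ps.nq = dim[0]; ps.np = dim[1];
      ps.field = INTEGER(keepf);
    } else {
      keepc = as<RawVector>(pl["cube"]);
      IntegerVector dim = keepc.attr("dim");
      ps.nq = dim[0]; ps.np = dim[1]; ps.ns = dim[2];
      ps.cube = RAW(keepc);
      keeps = as<NumericVector>(pl["s_levels"]);
      ps.ds_slice = (keeps[ps.ns - 1] - keeps[0]) / (ps.ns - 1);
    }
    if (ps.type > 0) {
      ps.hq = 1.0 / (ps.nq - 1);
      ps.hp = (m.gf - m.gr) / (ps.np - 1);
    }
    return ps;
  };

  IntegerVector pf, ff; RawVector pc, fc; NumericVector psl, fsl;
  PolicySpec prim = make_spec(primary, pf, pc, psl);
  PolicySpec fb = make_spec(fallback, ff, fc, fsl);

  IntegerVector outcome(N);
  NumericVector J(N), Tv(N), tsharp(N), nclamp(N);
  std::vector<double> pt, pq, pp_, pd;

  const long max_steps = (long)std::ceil(tmax / dt) + 1;

  for (int path = 0; path < N; ++path) {
    NormalGen rng((uint32_t)seed, (uint32_t)(counter0 + path));
    double q = q0, p = p0, s = sbar, Jp = 0.0, t = 0.0;
    double tsh = NA_REAL; int clamps = 0;
    int out = 0;
    const bool rec = record_path && path == 0;
    if (p < m.gr) out = 1;
    else if (p > m.gf) out = 2;
    double z[3];
    long step = 0;
    while (out == 0 && step < max_steps) {
      const bool depleted = R_finite(sbar) && s <= 0.0;
      const PolicySpec& use = depleted ? fb : prim;
      const double d = lookup_dose(use, m, q, p, s);
      if (rec && step % store_every == 0) {
        pt.push_back(t); pq.push_back(q); pp_.push_back(p); pd.push_back(d);
      }
      double aq, ap, rowq[3], rowp[3];
      m.drift(q, p, d, aq, ap);
      m.sigma(q, p, d, rowq, rowp);
      const double sq = std::sqrt(dt);
      double dq = aq * dt, dp = ap * dt;
      for (int k = 0; k < m.nW; ++k) {
        z[k] = rng.norm();
        dq += rowq[k] * z[k] * sq;
        dp += rowp[k] * z[k] * sq;
      }
      double qn = q + dq, pn = p + dp;
      if (qn < 0) { qn = 0; ++clamps; } else if (qn > 1) { qn = 1; ++clamps; }
      if (pn < 0) { pn = 0; ++clamps; } else if (pn > 1) { pn = 1; ++clamps; }
      const double Kd = m.K(d);
      if (pn < m.gr || pn > m.gf) {
        const double frac = (pn < m.gr) ? (p - m.gr) / (p - pn)
                                        : (m.gf - p) / (pn - p);
        const double s_pre = s;
        t += frac * dt; Jp += frac * dt * Kd; s -= frac * dt * Kd;
        if (R_finite(sbar) && s <= 0.0 && s_pre > 0.0 && ISNA(tsh))
          tsh = t - frac * dt + s_pre / Kd;
        out = (pn < m.gr) ? 1 : 2; q = qn; p = pn; break;
      }
      const double s_before = s;
      t += dt; Jp += dt * Kd; s -= dt * Kd;
      if (R_finite(sbar) && s <= 0.0 && s_before > 0.0)
        tsh = t - dt + s_before / Kd; // budget depletion time
      q = qn; p = pn; ++step;
    }
    outcome[path] = out;
    J[path] = Jp; Tv[path] = t; tsharp[path] = tsh; nclamp[path] = clamps;
    if (rec) { pt.push_back(t); pq.push_back(q); pp_.push_back(p); pd.push_back(0); }
  }

  List res = List::create(_["outcome"] = outcome, _["J"] = J, _["T"] = Tv,
                          _["t_sharp"] = tsharp, _["n_clamp"] = nclamp);
  if (record_path) {
    res["path"] = List::create(_["time"] = NumericVector(pt.begin(), pt.end()),
                               _["q"] = NumericVector(pq.begin(), pq.end()),
                               _["p"] = NumericVector(pp_.begin(), pp_.end()),
                               _["dose"] = NumericVector(pd.begin(), pd.end()));
  }
  return res;
}
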