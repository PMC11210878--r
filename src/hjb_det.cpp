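#include "models.h"
using namespace Rcpp;

// Bilinear interpolation of a node-centred field on the (q, p) grid.
// q axis: nq nodes uniform on [0,1]; p axis: np nodes uniform on [gr, gf].
static inline double bilinear(const std::vector<double>& u, int nq, int np,
                              double hq, double hp, double gr,
                              double q, double p) {
  double x = q / hq, y = (p - gr) / hp;
  int i = (int)std::floor(x), j = (int)std::floor(y);
  if (i < 0) i = 0; if (i > nq - 2) i = nq - 2;
  if (j < 0) j = 0; if (j > np - 2) j = np - 2;
  double tx = x - i, ty = y - j;
  if (tx < 0) tx = 0; if (tx > 1) tx = 1;
  if (ty < 0) ty = 0; if (ty > 1) ty = 1;
  const double u00 = u[i + nq * j],       u10 = u[i + 1 + nq * j];
  const double u01 = u[i + nq * (j + 1)], u11 = u[i + 1 + nq * (j + 1)];
  return (1 - tx) * (1 - ty) * u00 + tx * (1 - ty) * u10
       + (1 - tx) * ty * u01 + tx * ty * u11;
}

// One-dose semi-Lagrangian candidate value at node (q, p):
//   tau * K(d) + u(x + tau f(x, d)),  tau = h / |f|,
// with the step shortened when the foot crosses a barrier row.
static inline double sl_candidate(const Model& m, const std::vector<double>& u,
                                  int nq, int np, double hq, double hp,
                                  double q, double p, double d, double Umax) {
  double fq, fp;
  m.rate(q, p, d, fq, fp);
  const double nf = std::sqrt(fq * fq + fp * fp);
  if (nf < 1e-12) return Umax; // equilibrium under this dose: success unreachable
  const double h = std::min(hq, hp);
  const double tau = h / nf;
  double qe = q + tau * fq, pe = p + tau * fp;
  const double Kd = m.K(d);
  if (pe < m.gr) {
    const double frac = (p - m.gr) / (p - pe);
    return tau * frac * Kd; // lands on the success barrier, terminal value 0
  }
  if (pe > m.gf) {
    return Umax; // step ends beyond the failure barrier
  }
  if (qe < 0) qe = 0; if (qe > 1) qe = 1;
  double v = tau * Kd + bilinear(u, nq, np, hq, hp, m.gr, qe, pe);
  return v > Umax ? Umax : v;
}

// Stationary first-order HJB, min_d { K + grad(u) . f } = 0, solved by
// semi-Lagrangian Gauss-Seidel value iteration with alternating sweep
// orderings. u = 0 on the stabilization row, u = Umax on the failure row.
// [[Rcpp::export]]
List solve_det_hjb_cpp(int tag, NumericVector par, int nq, int np,
                       double Umax, double tol, int max_sweeps) {
  Model m(tag, par);
  const double hq = 1.0 / (nq - 1), hp = (m.gf - m.gr) / (np - 1);
  std::vector<double> u((size_t)nq * np, Umax);
  for (int i = 0; i < nq; ++i) u[i] = 0.0; // j = 0 row is p = gamma_r

  std::vector<double> resid_hist;
  double resid = R_PosInf;
  int sweep_sets = 0;
  const double doses[2] = {0.0, m.dmax};

  while (sweep_sets < max_sweeps && resid > tol) {
    resid = 0.0;
    for (int ord = 0; ord < 4; ++ord) {
      const bool irev = ord & 1, jrev = ord & 2;
      for (int jj = 1; jj <= np - 2; ++jj) {
        const int j = jrev ? (np - 1 - jj) : jj;
        const double p = m.gr + j * hp;
        for (int ii = 0; ii < nq; ++ii) {
          const int i = irev ? (nq - 1 - ii) : ii;
          const double q = i * hq;
          double best = sl_candidate(m, u, nq, np, hq, hp, q, p, doses[0], Umax);
          const double c1 = sl_candidate(m, u, nq, np, hq, hp, q, p, doses[1], Umax);
          if (c1 < best - 1e-12) best = c1;
          const size_t idx = i + (size_t)nq * j;
          const double diff = std::fabs(best - u[idx]);
          if (diff > resid) resid = diff;
          u[idx] = best;
        }
      }
    }
    resid_hist.push_back(resid);
    ++sweep_sets;
  }

  // extract the bang-bang policy (ties broken toward no drugs)
  IntegerMatrix pol(nq, np);
  for (int j = 1; j <= np - 2; ++j) {
    const double p = m.gr + j * hp;
    for (int i = 0; i < nq; ++i) {
      const double q = i * hq;
      const double c0 = sl_candidate(m, u, nq, np, hq, hp, q, p, doses[0], Umax);
      const double c1 = sl_candidate(m, u, nq, np, hq, hp, q, p, doses[1], Umax);
      pol(i, j) = (c1 < c0 - 1e-12) ? 1 : 0;
    }
  }
  // stabilization row: keep the argmin policy (a nearest-node lookup from a
  // state just above the barrier must not switch the drug off and stall);
  // failure row is never consulted meaningfully
  {
    const double p0 = m.gr;
    for (int i = 0; i < nq; ++i) {
      const double q = i * hq;
      const double c0 = sl_candidate(m, u, nq, np, hq, hp, q, p0, doses[0], Umax);
      const double c1 = sl_candidate(m, u, nq, np, hq, hp, q, p0, doses[1], Umax);
      pol(i, 0) = (c1 < c0 - 1e-12) ? 1 : 0;
      pol(i, np - 1) = pol(i, np - 2);
    }
  }

  NumericMatrix um(nq, np);
  std::copy(u.begin(), u.end(), um.begin());
  return List::create(_["u"] = um, _["policy"] = pol,
                      _["sweeps"] = sweep_sets, _["residual"] = resid,
                      _["residual_history"] = NumericVector(resid_hist.begin(), resid_hist.end()),
                      _["converged"] = resid <= tol);
}

// Closed-loop ODE integration under a feedback policy (constant dose, or a
// nearest-node lookup in a binary policy field). Explicit Euler stepping with
// sub-step linear interpolation of the barrier crossing.
// [[Rcpp::export]]
List integrate_trajectory_cpp(int tag, NumericVector par, double q0, double p0,
                              int policy_type, double const_dose,
                              IntegerMatrix polfield, double dt, double tmax,
                              int store_every) {
  Model m(tag, par);
  const int nq = polfield.nrow(), np = polfield.ncol();
  const double hq = (nq > 1) ? 1.0 / (nq - 1) : 1.0;
  const double hp = (np > 1) ? (m.gf - m.gr) / (np - 1) : 1.0;

  std::vector<double> ts, qs, ps, dsv;
  double q = q0, p = p0, t = 0.0, J = 0.0;
  int outcome = 0; // 0 max-time, 1 success, 2 failure
  if (p0 < m.gr) outcome = 1;
  if (p0 > m.gf) outcome = 2;

  long step = 0;
  while (outcome == 0 && t < tmax) {
    double d;
    if (policy_type == 0) d = const_dose;
    else {
      int i = (int)std::lround(q / hq);
      int j = (int)std::lround((p - m.gr) / hp);
      if (i < 0) i = 0; if (i > nq - 1) i = nq - 1;
      if (j < 0) j = 0; if (j > np - 1) j = np - 1;
      d = polfield(i, j) ? m.dmax : 0.0;
    }
    if (step % store_every == 0) {
      ts.push_back(t); qs.push_back(q); ps.push_back(p); dsv.push_back(d);
    }
    double fq, fp;
    m.rate(q, p, d, fq, fp);
    double qn = q + dt * fq, pn = p + dt * fp;
    if (qn < 0) qn = 0; if (qn > 1) qn = 1;
    const double Kd = m.K(d);
    if (pn < m.gr) {
      const double frac = (p - m.gr) / (p - pn);
      t += frac * dt; J += frac * dt * Kd;
      q = qn; p = m.gr; outcome = 1; break;
    }
    if (pn > m.gf) {
      const double frac = (m.gf - p) / (pn - p);
      t += frac * dt; J += frac * dt * Kd;
      q = qn; p = m.gf; outcome = 2; break;
    }
    t += dt; J += dt * Kd; q = qn; p = pn; ++step;
  }
  ts.push_back(t); qs.push_back(q); ps.push_back(p);
  dsv.push_back(dsv.empty() ? 0.0 : dsv.back());

  return List::create(_["time"] = NumericVector(ts.begin(), ts.end()),
                      _["q"] = NumericVector(qs.begin(), qs.end()),
                      _["p"] = NumericVector(ps.begin(), ps.end()),
                      _["dose"] = NumericVector(dsv.begin(), dsv.end()),
                      _["cost"] = J, _["T"] = t, _["outcome"] = outcome);
}
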