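#include "models.h"
using namespace Rcpp;

// Threshold-aware parabolic HJB, marched explicitly in the remaining budget s:
//   v_s = max_{d in {0, dmax}} [ a(x,d).grad(v) + 1/2 tr(B(x,d) D2 v) ] / K(x,d),
// from v(.,0) = indicator of the success region, with v = 1 / v = 0 pinned on
// the stabilization / failure rows at every level. First-order upwind
// differences for the drift, central differences for the diffusion, and the
// 7-point monotone-leaning stencil for the mixed derivative. Since K > 0 is
// s-independent, all stencil weights are precomputed per node and dose; each
// budget level is then a sparse matvec.
//
// Returns v and the bang-bang policy on a subsampled set of s-slices
// (spacing ~ ds_store), the first slice being s = 0.
// [[Rcpp::export]]
List solve_threshold_cpp(int tag, NumericVector par, int nq, int np,
                         double Sbar, double ds_store, double cfl,
                         bool store_policy, double ds_request) {
  Model m(tag, par);
  const double hq = 1.0 / (nq - 1), hp = (m.gf - m.gr) / (np - 1);
  const size_t nn = (size_t)nq * np;
  const double doses[2] = {0.0, m.dmax};

  // 9 stencil weights per node per dose: E, W, N, S, PP(+q+p), MM, PM(+q-p), MP, C
  std::vector<double> wE(2 * nn, 0), wW(2 * nn, 0), wN(2 * nn, 0), wS(2 * nn, 0),
      wPP(2 * nn, 0), wMM(2 * nn, 0), wPM(2 * nn, 0), wMP(2 * nn, 0), wC(2 * nn, 0);
  double max_abs_wc = 0.0;

  for (int dd = 0; dd < 2; ++dd) {
    const double d = doses[dd], Kd = m.K(d);
    for (int j = 1; j <= np - 2; ++j) {
      const double p = m.gr + j * hp;
      for (int i = 0; i < nq; ++i) {
        const double q = i * hq;
        double aq, ap, Bqq, Bpp, Bqp;
        m.drift(q, p, d, aq, ap);
        m.Bmat(q, p, d, Bqq, Bpp, Bqp);
        double e = 0.5 * Bqq / (hq * hq), w = e;
        double nb = 0.5 * Bpp / (hp * hp), s = nb;
        double pp = 0, mm = 0, pm = 0, mp = 0;
        if (Bqp > 0) {
          const double m2 = Bqp / (2 * hq * hp);
          pp = m2; mm = m2; e -= m2; w -= m2; nb -= m2; s -= m2;
        } else if (Bqp < 0) {
          const double m2 = -Bqp / (2 * hq * hp);
          pm = m2; mp = m2; e -= m2; w -= m2; nb -= m2; s -= m2;
        }
        if (aq > 0) e += aq / hq; else w += -aq / hq;
        if (ap > 0) nb += ap / hp; else s += -ap / hp;
        const double c = -(e + w + nb + s + pp + mm + pm + mp);
        const size_t k = i + nq * (size_t)j + dd * nn;
        wE[k] = e / Kd; wW[k] = w / Kd; wN[k] = nb / Kd; wS[k] = s / Kd;
        wPP[k] = pp / Kd; wMM[k] = mm / Kd; wPM[k] = pm / Kd; wMP[k] = mp / Kd;
        wC[k] = c / Kd;
        if (std::fabs(wC[k]) > max_abs_wc) max_abs_wc = std::fabs(wC[k]);
      }
    }
  }

  double ds_cfl = cfl / max_abs_wc;
  if (ds_request > 0) {
    if (ds_request > ds_cfl)
      stop("requested budget step %g violates the stability bound; need ds <= %g",
           ds_request, ds_cfl);
    ds_cfl = ds_request;
  }
  // uniform stored slices: round the level count up to a multiple of the
  // storage stride so the slice spacing is exact
  const long nlev0 = std::max(1L, (long)std::ceil(Sbar / ds_cfl));
  long kstore = std::max(1L, (long)std::lround(ds_store / (Sbar / nlev0)));
  const long nlev = kstore * (long)std::ceil((double)nlev0 / kstore);
  const double ds = Sbar / nlev;
  std::vector<long> store_levels;
  for (long l = 0; l <= nlev; l += kstore) store_levels.push_back(l);
  const int nstore = store_levels.size();

  NumericVector vout((R_xlen_t)nn * nstore);
  vout.attr("dim") = IntegerVector::create(nq, np, nstore);
  RawVector polout(store_policy ? (R_xlen_t)nn * nstore : 1);
  if (store_policy) polout.attr("dim") = IntegerVector::create(nq, np, nstore);

  std::vector<double> v(nn, 0.0), vn(nn, 0.0);
  for (int i = 0; i < nq; ++i) v[i] = 1.0; // success row (j = 0)
  // failure row j = np-1 stays 0

  auto store_slice = [&](int slot, const std::vector<double>& vv) {
    std::copy(vv.begin(), vv.end(), vout.begin() + (R_xlen_t)nn * slot);
  };
  store_slice(0, v);
  if (store_policy) std::fill(polout.begin(), polout.begin() + nn, (Rbyte)0);

  double max_clip = 0.0;
  int next_store = 1;
  std::vector<Rbyte> polbuf(store_policy ? nn : 0);

  for (long l = 1; l <= nlev; ++l) {
    const bool record = store_policy && next_store < nstore && store_levels[next_store] == l;
    for (int j = 1; j <= np - 2; ++j) {
      const size_t base = nq * (size_t)j;
      for (int i = 0; i < nq; ++i) {
        const size_t k = base + i;
        const double vc = v[k];
        const double vN = v[k + nq], vS = v[k - nq];
        double rhs0, rhs1;
        if (i == 0 || i == nq - 1) {
          // q-faces: all q-direction weights vanish identically
          rhs0 = wN[k] * vN + wS[k] * vS + wC[k] * vc;
          const size_t k1 = k + nn;
          rhs1 = wN[k1] * vN + wS[k1] * vS + wC[k1] * vc;
        } else {
          const double vEv = v[k + 1], vWv = v[k - 1];
          const double vPPv = v[k + 1 + nq], vMMv = v[k - 1 - nq];
          const double vPMv = v[k + 1 - nq], vMPv = v[k - 1 + nq];
          rhs0 = wE[k] * vEv + wW[k] * vWv + wN[k] * vN + wS[k] * vS
               + wPP[k] * vPPv + wMM[k] * vMMv + wPM[k] * vPMv + wMP[k] * vMPv
               + wC[k] * vc;
          const size_t k1 = k + nn;
          rhs1 = wE[k1] * vEv + wW[k1] * vWv + wN[k1] * vN + wS[k1] * vS
               + wPP[k1] * vPPv + wMM[k1] * vMMv + wPM[k1] * vPMv + wMP[k1] * vMPv
               + wC[k1] * vc;
        }
        const bool use_max = rhs1 > rhs0 + 1e-14; // ties -> no drugs
        double nv = vc + ds * (use_max ? rhs1 : rhs0);
        if (nv < 0) { if (-nv > max_clip) max_clip = -nv; nv = 0; }
        else if (nv > 1) { if (nv - 1 > max_clip) max_clip = nv - 1; nv = 1; }
        vn[k] = nv;
        if (record) polbuf[k] = use_max ? 1 : 0;
      }
    }
    // barrier rows are Dirichlet data at every level
    for (int i = 0; i < nq; ++i) { vn[i] = 1.0; vn[i + nn - nq] = 0.0; }
    v.swap(vn);
    if (next_store < nstore && store_levels[next_store] == l) {
      if (ISNAN(v[nn / 2]))
        stop("NaN detected in the budget marching at level %ld (s = %g)", l, l * ds);
      store_slice(next_store, v);
      if (record) {
        // barrier rows inherit the neighbouring interior policy: a nearest-node
        // lookup from a state marginally inside the domain must not stall
        for (int i = 0; i < nq; ++i) {
          polbuf[i] = polbuf[i + nq];
          polbuf[nn - nq + i] = polbuf[nn - 2 * (size_t)nq + i];
        }
        std::copy(polbuf.begin(), polbuf.end(),
                  polout.begin() + (R_xlen_t)nn * next_store);
      }
      ++next_store;
    }
  }

  NumericVector s_levels(nstore);
  for (int k = 0; k < nstore; ++k) s_levels[k] = store_levels[k] * ds;

  return List::create(_["v"] = vout, _["policy"] = polout,
                      _["s_levels"] = s_levels, _["ds"] = ds,
                      _["n_levels"] = (double)nlev,
                      _["cfl_bound"] = max_abs_wc, _["max_clip"] = max_clip);
}
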