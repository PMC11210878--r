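#ifndef THRESHOLDTX_MODELS_H
#define THRESHOLDTX_MODELS_H

#include <Rcpp.h>
#include <cmath>

// Controlled drift-diffusion models on the unit square (q, p).
// tag 0: EGT replicator competition (GLY / DEF / VOP), 3 Brownian channels.
//   par = [b_a, b_v, c, n, d_max, delta, sig_G, sig_D, sig_V, gamma_r, gamma_f]
// tag 1: sensitive-resistant logistic competition, 1 Brownian channel.
//   par = [g_S, g_R, m, betaC, alpha, d_max, delta, sig_S, sig_R, gamma_r, gamma_f]
// tag 2: 1-D test model (q frozen, dp/dt = -d), 1 channel with volatility sig.
//   par = [d_max, delta, gamma_r, gamma_f, sig]
// All diffusion entries carry a q(1-q) or p(1-p) factor, so the state cannot
// diffuse out of [0,1]^2.
struct Model {
  int tag;
  std::vector<double> par;
  double dmax, delta, gr, gf;
  int nW; // number of Brownian channels

  Model(int tag_, const Rcpp::NumericVector& p_) : tag(tag_), par(p_.begin(), p_.end()) {
    if (tag == 0) {
      dmax = par[4]; delta = par[5]; gr = par[9]; gf = par[10]; nW = 3;
    } else if (tag == 1) {
      dmax = par[5]; delta = par[6]; gr = par[9]; gf = par[10]; nW = 1;
    } else {
      dmax = par[0]; delta = par[1]; gr = par[2]; gf = par[3]; nW = 1;
    }
  }

  double K(double d) const { return d + delta; }

  // deterministic vector field f(x, d)
  void rate(double q, double p, double d, double& fq, double& fp) const {
    if (tag == 0) {
      const double ba = par[0], bv = par[1], c = par[2];
      const int n = (int)par[3];
      double S = 1.0, pk = 1.0;
      for (int k = 1; k <= n; ++k) { pk *= p; S += pk; }
      fq = q * (1.0 - q) * (bv / (n + 1.0) * S - c);
      fp = p * (1.0 - p) * (ba / (n + 1.0) - (bv - c) * q - d);
    } else if (tag == 1) {
      const double gS = par[0], gR = par[1], betaC = par[3], alpha = par[4];
      fq = (1.0 - p) * q * (1.0 - q) * (gS - gR) + betaC * p * q * q * (1.0 - q)
           - alpha * q * (1.0 - q) * d;
      fp = p * (1.0 - p) * (gS * q + gR * (1.0 - q)) - betaC * p * p * q * (1.0 - q)
           - alpha * q * p * d;
    } else {
      fq = 0.0;
      fp = -d;
    }
  }

  // SDE drift a(x, d): deterministic rate plus Ito corrections for the
  // reduced (q, p) coordinates.
  void drift(double q, double p, double d, double& aq, double& ap) const {
    if (tag == 0) {
      const double ba = par[0], bv = par[1], c = par[2];
      const int n = (int)par[3];
      const double sG2 = par[6] * par[6], sD2 = par[7] * par[7], sV2 = par[8] * par[8];
      double S = 1.0, pk = 1.0;
      for (int k = 1; k <= n; ++k) { pk *= p; S += pk; }
      aq = q * (1.0 - q) * ((bv / (n + 1.0) * S - c) + ((1.0 - q) * sD2 - q * sV2));
      ap = p * (1.0 - p) * ((ba / (n + 1.0) - (bv - c) * q - d)
           - (sG2 * p - sD2 * (1.0 - p) * (1.0 - q) * (1.0 - q)
                       - sV2 * (1.0 - p) * q * q));
    } else if (tag == 1) {
      const double gS = par[0], gR = par[1], betaC = par[3], alpha = par[4];
      const double sS = par[7], sR = par[8];
      const double omp = 1.0 - p;
      aq = q * (1.0 - q) * (omp * (gS - gR) - alpha * d + betaC * q * p
           + omp * omp * (sR * sR * (1.0 - q) - sS * sS * q + sS * sR * (2.0 * q - 1.0)));
      double fq_unused;
      rate(q, p, d, fq_unused, ap); // p-equation carries no correction
    } else {
      rate(q, p, d, aq, ap);
    }
  }

  // diffusion rows (length nW each)
  void sigma(double q, double p, double /*d*/, double* rowq, double* rowp) const {
    if (tag == 0) {
      const double sG = par[6], sD = par[7], sV = par[8];
      const double qq = q * (1.0 - q), pp = p * (1.0 - p);
      rowq[0] = 0.0;           rowq[1] = -sD * qq;            rowq[2] = sV * qq;
      rowp[0] = sG * pp;       rowp[1] = sD * pp * (1.0 - q); rowp[2] = sV * pp * q;
    } else if (tag == 1) {
      const double sS = par[7], sR = par[8];
      rowq[0] = (1.0 - p) * q * (1.0 - q) * (sS - sR);
      rowp[0] = p * (1.0 - p) * (sS * q + sR * (1.0 - q));
    } else {
      rowq[0] = 0.0;
      rowp[0] = par[4] * p * (1.0 - p);
    }
  }

  // B = Sigma Sigma^T entries
  void Bmat(double q, double p, double d, double& Bqq, double& Bpp, double& Bqp) const {
    double rowq[3] = {0, 0, 0}, rowp[3] = {0, 0, 0};
    sigma(q, p, d, rowq, rowp);
    Bqq = 0.0; Bpp = 0.0; Bqp = 0.0;
    for (int k = 0; k < nW; ++k) {
      Bqq += rowq[k] * rowq[k];
      Bpp += rowp[k] * rowp[k];
      Bqp += rowq[k] * rowp[k];
    }
  }
};

#endif
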