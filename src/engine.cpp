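#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo cell counts for the Gaussian-family observer variants.
//
// nv/na: true counts per condition (0 = absent); tv/ta: true onsets (ms);
// Z: (n_cond * m) x 4 standard-normal deviates, block i holding condition
// i's draws; mode: 0 = 2D causal inference, 1 = 1D causal inference,
// 2 = forced fusion, 3 = flat-prior fusion.
//
// Returned counts: n_cond x 9; bimodal cell = 3 * resp_v + resp_a,
// unisensory cell = resp (columns 3..8 zero).

static inline double log_norm(double x, double mu, double s2) {
  const double d = x - mu;
  return -0.918938533204672742 - 0.5 * std::log(s2) - d * d / (2.0 * s2);
}

static inline int readout(double s) {
  double r = std::floor(s + 0.5);
  if (r < 0.0) r = 0.0;
  if (r > 2.0) r = 2.0;
  return static_cast<int>(r);
}

// [[Rcpp::export]]
IntegerMatrix cell_counts_cpp(IntegerVector nv, IntegerVector na,
                              NumericVector tv, NumericVector ta,
                              int m, NumericMatrix Z,
                              double sv, double sa, double pc,
                              double sp, double mup,
                              double svt, double sat,
                              double mutp, double stp,
                              int mode) {
  const int n_cond = nv.size();
  IntegerMatrix counts(n_cond, 9);

  const double sv2 = sv * sv, sa2 = sa * sa, sp2 = sp * sp;
  const double pv = 1.0 / sv2, pa = 1.0 / sa2, pp = 1.0 / sp2;
  // numerosity common-cause pieces
  const double vw = 1.0 / (pv + pa);
  const double s2_diff = sv2 + sa2;
  const double s2_w = vw + sp2;
  const double s2_v2 = sv2 + sp2, s2_a2 = sa2 + sp2;
  // temporal pieces
  const double svt2 = svt * svt, sat2 = sat * sat, stp2 = stp * stp;
  const double pvt = 1.0 / svt2, pat = 1.0 / sat2;
  const double vwt = 1.0 / (pvt + pat);
  const double t2_diff = svt2 + sat2;
  const double t2_w = vwt + stp2;
  const double t2_v2 = svt2 + stp2, t2_a2 = sat2 + stp2;
  // estimate weights
  const double prec_fused = pv + pa + (mode == 3 ? 0.0 : pp);
  const double prec_segv = pv + pp, prec_sega = pa + pp;
  const double log_pc = (pc > 0.0) ? std::log(pc) : R_NegInf;
  const double log_qc = (pc < 1.0) ? std::log1p(-pc) : R_NegInf;

  for (int c = 0; c < n_cond; ++c) {
    const int base = c * m;
    const bool has_v = nv[c] >= 1, has_a = na[c] >= 1;
    if (has_v && has_a) {
      const double mv = nv[c], ma_ = na[c];
      for (int i = 0; i < m; ++i) {
        const int r = base + i;
        const double xv = mv + sv * Z(r, 0);
        const double xa = ma_ + sa * Z(r, 1);
        int resp_v, resp_a;
        if (mode >= 2) {
          const double fused =
            (xv * pv + xa * pa + (mode == 3 ? 0.0 : mup * pp)) / prec_fused;
          resp_v = resp_a = readout(fused);
        } else {
          double p1;
          if (pc >= 1.0) {
            p1 = 1.0;
          } else if (pc <= 0.0) {
            p1 = 0.0;
          } else {
            const double w = (xv * pv + xa * pa) * vw;
            double l1 = log_pc + log_norm(xv - xa, 0.0, s2_diff) +
              log_norm(w, mup, s2_w);
            double l2 = log_qc + log_norm(xv, mup, s2_v2) +
              log_norm(xa, mup, s2_a2);
            if (mode == 0) {
              const double tvv = tv[c] + svt * Z(r, 2);
              const double taa = ta[c] + sat * Z(r, 3);
              const double wt = (tvv * pvt + taa * pat) * vwt;
              l1 += log_norm(tvv - taa, 0.0, t2_diff) + log_norm(wt, mutp, t2_w);
              l2 += log_norm(tvv, mutp, t2_v2) + log_norm(taa, mutp, t2_a2);
            }
            p1 = 1.0 / (1.0 + std::exp(l2 - l1));
          }
          const double fused = (xv * pv + xa * pa + mup * pp) / prec_fused;
          const double segv = (xv * pv + mup * pp) / prec_segv;
          const double sega = (xa * pa + mup * pp) / prec_sega;
          resp_v = readout(p1 * fused + (1.0 - p1) * segv);
          resp_a = readout(p1 * fused + (1.0 - p1) * sega);
        }
        counts(c, 3 * resp_v + resp_a) += 1;
      }
    } else if (has_v) {
      const double mv = nv[c];
      for (int i = 0; i < m; ++i) {
        const double xv = mv + sv * Z(base + i, 0);
        const double est = (mode == 3) ? xv : (xv * pv + mup * pp) / prec_segv;
        counts(c, readout(est)) += 1;
      }
    } else {
      const double ma_ = na[c];
      for (int i = 0; i < m; ++i) {
        const double xa = ma_ + sa * Z(base + i, 1);
        const double est = (mode == 3) ? xa : (xa * pa + mup * pp) / prec_sega;
        counts(c, readout(est)) += 1;
      }
    }
  }
  return counts;
}
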