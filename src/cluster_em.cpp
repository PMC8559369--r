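// Haplotype-cluster EM for within-cohort genotype imputation.
//
// Diploid hidden Markov model: each sample's two haplotypes follow
// latent clusters k = 1..K; cluster k carries an allele probability
// theta[site, k]; each haplotype switches cluster between consecutive
// sites with probability `jump` (landing uniformly). Transitions
// factorise per haplotype, so the K^2-state forward/backward update
// costs O(K^2) per site via row/column sums.

#include <Rcpp.h>
using namespace Rcpp;

// emission table e[k1,k2] for one site given dosage g (-1 = missing)
static inline void emission(const double* th, int K, int g, double* e) {
  if (g < 0) {
    for (int i = 0; i < K * K; ++i) e[i] = 1.0;
    return;
  }
  for (int k2 = 0; k2 < K; ++k2) {
    double p2 = th[k2];
    for (int k1 = 0; k1 < K; ++k1) {
      double p1 = th[k1];
      double v;
      if (g == 0) v = (1 - p1) * (1 - p2);
      else if (g == 1) v = p1 * (1 - p2) + (1 - p1) * p2;
      else v = p1 * p2;
      e[k1 + K * k2] = v;
    }
  }
}

// A <- c^2 A + c s (rowsum_k1 + colsum_k2) + s^2 S   (in place)
static void transit(double* A, int K, double c, double s,
                    double* r1, double* c1) {
  double S = 0.0;
  for (int k = 0; k < K; ++k) { r1[k] = 0.0; c1[k] = 0.0; }
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1) {
      double v = A[k1 + K * k2];
      r1[k1] += v; c1[k2] += v; S += v;
    }
  double c2 = c * c, cs = c * s, s2 = s * s * S;
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1)
      A[k1 + K * k2] = c2 * A[k1 + K * k2] + cs * (r1[k1] + c1[k2]) + s2;
}

static inline void normalise(double* A, int n) {
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += A[i];
  if (S <= 0) S = 1e-300;
  for (int i = 0; i < n; ++i) A[i] /= S;
}

// [[Rcpp::export]]
IntegerMatrix cluster_impute_em(IntegerMatrix g, NumericMatrix theta0,
                                NumericVector af, int K, int n_iter,
                                double jump) {
  int ns = g.nrow(), nsam = g.ncol();
  int KK = K * K;
  NumericMatrix theta(clone(theta0));
  IntegerMatrix dose(ns, nsam);
  std::vector<double> fwd((size_t)ns * KK), bwd(KK), post(KK), e(KK);
  std::vector<double> r1(K), c1(K);
  std::vector<double> num((size_t)ns * K), den((size_t)ns * K);
  std::vector<double> th(ns * (size_t)K);
  double c = 1.0 - jump, s = jump / K;

  for (int iter = 0; iter <= n_iter; ++iter) {
    bool final_pass = (iter == n_iter);
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    for (int i = 0; i < ns; ++i)
      for (int k = 0; k < K; ++k)
        th[(size_t)i * K + k] = theta(i, k);

    for (int sidx = 0; sidx < nsam; ++sidx) {
      // forward
      for (int i = 0; i < ns; ++i) {
        double* A = &fwd[(size_t)i * KK];
        emission(&th[(size_t)i * K], K, g(i, sidx), e.data());
        if (i == 0) {
          for (int z = 0; z < KK; ++z) A[z] = e[z] / KK;
        } else {
          std::copy(&fwd[(size_t)(i - 1) * KK],
                    &fwd[(size_t)(i - 1) * KK] + KK, A);
          transit(A, K, c, s, r1.data(), c1.data());
          for (int z = 0; z < KK; ++z) A[z] *= e[z];
        }
        normalise(A, KK);
      }
      // backward + accumulate
      for (int z = 0; z < KK; ++z) bwd[z] = 1.0;
      for (int i = ns - 1; i >= 0; --i) {
        const double* A = &fwd[(size_t)i * KK];
        for (int z = 0; z < KK; ++z) post[z] = A[z] * bwd[z];
        normalise(post.data(), KK);

        const double* thi = &th[(size_t)i * K];
        int gi = g(i, sidx);
        if (gi >= 0 && !final_pass) {
          // expected allele per haplotype for the M-step
          for (int k2 = 0; k2 < K; ++k2) {
            double p2 = thi[k2];
            for (int k1 = 0; k1 < K; ++k1) {
              double p1 = thi[k1];
              double w = post[k1 + K * k2];
              if (w <= 0) continue;
              double a1, a2;
              if (gi == 0) { a1 = 0; a2 = 0; }
              else if (gi == 2) { a1 = 1; a2 = 1; }
              else {
                double h = p1 * (1 - p2) + (1 - p1) * p2;
                a1 = h > 0 ? p1 * (1 - p2) / h : 0.5;
                a2 = 1 - a1;
              }
              num[(size_t)i * K + k1] += w * a1;
              den[(size_t)i * K + k1] += w;
              num[(size_t)i * K + k2] += w * a2;
              den[(size_t)i * K + k2] += w;
            }
          }
        } else if (final_pass && gi < 0) {
          // posterior dosage distribution at a missing call
          double p0 = 0, p1s = 0, p2s = 0;
          for (int k2 = 0; k2 < K; ++k2) {
            double p2 = thi[k2];
            for (int k1 = 0; k1 < K; ++k1) {
              double p1 = thi[k1];
              double w = post[k1 + K * k2];
              p0 += w * (1 - p1) * (1 - p2);
              p1s += w * (p1 * (1 - p2) + (1 - p1) * p2);
              p2s += w * p1 * p2;
            }
          }
          int best = 0;
          double bv = p0;
          if (p1s > bv) { best = 1; bv = p1s; }
          if (p2s > bv) { best = 2; bv = p2s; }
          dose(i, sidx) = best;
        }
        if (final_pass && gi >= 0) dose(i, sidx) = gi;

        // extend backward to site i-1
        if (i > 0) {
          emission(thi, K, gi, e.data());
          for (int z = 0; z < KK; ++z) bwd[z] *= e[z];
          transit(bwd.data(), K, c, s, r1.data(), c1.data());
          normalise(bwd.data(), KK);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    if (!final_pass)
      for (int i = 0; i < ns; ++i)
        for (int k = 0; k < K; ++k)
          // shrink toward the site's observed AF so unanchored sites
          // revert to the allele-frequency prior, not to 0.5
          theta(i, k) = (num[(size_t)i * K + k] + af[i]) /
                        (den[(size_t)i * K + k] + 1.0);
  }
  return dose;
}
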