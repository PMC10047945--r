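#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pairwise match statistics for the multivariate sample / fuzzy entropy
// family.  Input is a p x N (already coarse-grained, globally normalised)
// matrix.  Composite delay vectors of dimension m*p are formed channel-block
// by channel-block (channel k contributes x[k, i], x[k, i+d], ...,
// x[k, i+(m-1)d]).
//
// Dimension m:   phi_m = mean over i of the mean similarity of vector i to
//                the other M-1 vectors (M = N - m*d).
// Dimension m+1: there are p ways to extend a vector, appending
//                x[k, i + m*d] for channel k.  Each extension family is a
//                set of M vectors of length m*p+1; the match statistic is
//                computed within each family exactly as at dimension m and
//                the p per-vector probabilities are averaged together,
//                i.e. phi_m1 = mean over the p*M extended vectors of their
//                within-family mean similarity.
//
// hard mode (fuzzy = false): similarity is the indicator dist <= r.
// fuzzy mode: similarity is 1 on [0, lambda*r] and
//             exp(-ln2 * ((dist - lambda*r)/r)^2) beyond; lambda = 1 gives
//             the plain fuzzy membership.
//
// Distances beyond lambda*r + 8r carry similarity < 2^-64 and are skipped;
// the early exit on the running Chebyshev maximum makes the typical pair
// O(1) instead of O(m*p).
//
// Returns c(phi_m, phi_m1).

// [[Rcpp::export]]
NumericVector mv_match_stats(NumericMatrix x, int m, int d, double r,
                             double lambda, bool fuzzy) {
  const int p = x.nrow(), N = x.ncol();
  const int n = m * d;
  const int M = N - n;
  if (M < 2)
    stop("coarse-grained series too short for embedding (need N - m*d >= 2)");
  if (r <= 0) stop("tolerance r must be positive");
  const int mp = m * p;
  const double thr = fuzzy ? lambda * r : r;
  const double cutoff = fuzzy ? thr + 8.0 * r : r;
  const double inv_r2 = 1.0 / (r * r);
  const double ln2 = 0.6931471805599453;

  // row-major embeddings: base[i*mp + k*m + l] = x(k, i + l*d)
  std::vector<double> base((size_t)M * mp);
  std::vector<double> ext((size_t)M * p); // ext[i*p + k] = x(k, i + n)
  for (int i = 0; i < M; ++i) {
    for (int k = 0; k < p; ++k) {
      for (int l = 0; l < m; ++l)
        base[(size_t)i * mp + k * m + l] = x(k, i + l * d);
      ext[(size_t)i * p + k] = x(k, i + n);
    }
  }

  double sum_m = 0.0, sum_m1 = 0.0;

  for (int i = 0; i < M - 1; ++i) {
    const double *bi = &base[(size_t)i * mp];
    const double *ei = &ext[(size_t)i * p];
    for (int j = i + 1; j < M; ++j) {
      const double *bj = &base[(size_t)j * mp];
      double dm = 0.0;
      bool over = false;
      for (int c = 0; c < mp; ++c) {
        double ad = std::fabs(bi[c] - bj[c]);
        if (ad > dm) {
          dm = ad;
          if (dm > cutoff) { over = true; break; }
        }
      }
      if (over) continue;
      if (dm <= thr) sum_m += 1.0;
      else if (fuzzy) {
        double u = dm - thr;
        sum_m += std::exp(-ln2 * u * u * inv_r2);
      }
      const double *ej = &ext[(size_t)j * p];
      for (int k = 0; k < p; ++k) {
        double ad = std::fabs(ei[k] - ej[k]);
        double dd = ad > dm ? ad : dm;
        if (dd <= thr) sum_m1 += 1.0;
        else if (fuzzy && dd <= cutoff) {
          double u = dd - thr;
          sum_m1 += std::exp(-ln2 * u * u * inv_r2);
        }
      }
    }
  }

  // each unordered pair counts twice in the mean-over-i formulation
  double phim = 2.0 * sum_m / ((double)M * (M - 1));
  double phim1 = 2.0 * sum_m1 / ((double)p * M * (M - 1));
  return NumericVector::create(phim, phim1);
}
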