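#include <Rcpp.h>
using namespace Rcpp;

// Composite-LD r^2 over all locus pairs, with optional delete-one
// individual jackknife. Genotypes are alternate-allele counts 0/1/2 with
// NA for missing; individuals in rows, loci in columns. Per pair, r is
// the Pearson correlation of genotype counts over pairwise-complete
// individuals scaled by n/(n-1) (the Burrows composite estimator with
// the within-locus disequilibrium term in the denominators). Pairs are
// weighted by their individual count; S is the harmonic mean of per-pair
// counts.
// [[Rcpp::export(name = ".ldR2Stats")]]
List ldR2Stats(IntegerMatrix G, bool jackknife = false,
               int min_n = 10) {
  const int n = G.nrow(), L = G.ncol();
  long double wsum = 0.0L, wr2 = 0.0L, inv_n = 0.0L;
  double n_pairs = 0.0;
  std::vector<long double> jk_wr2, jk_w, jk_inv, jk_pairs;
  if (jackknife) {
    jk_wr2.assign(n, 0.0L);
    jk_w.assign(n, 0.0L);
    jk_inv.assign(n, 0.0L);
    jk_pairs.assign(n, 0.0L);
  }
  std::vector<int> idx;
  idx.reserve(n);

  for (int j = 0; j < L; ++j) {
    for (int k = j + 1; k < L; ++k) {
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      idx.clear();
      for (int i = 0; i < n; ++i) {
        int x = G(i, j), y = G(i, k);
        if (x == NA_INTEGER || y == NA_INTEGER) continue;
        sx += x; sy += y; sxx += (double)x * x;
        syy += (double)y * y; sxy += (double)x * y;
        idx.push_back(i);
      }
      int m = (int)idx.size();
      if (m < min_n) continue;
      double vx = m * sxx - sx * sx, vy = m * syy - sy * sy;
      if (vx <= 0 || vy <= 0) continue;
      double r = (m * sxy - sx * sy) / std::sqrt(vx * vy);
      double sc = (double)m / (m - 1);
      double r2 = r * r * sc * sc;
      double w = m;
      wsum += w; wr2 += w * r2; inv_n += 1.0 / m;
      n_pairs += 1.0;
      if (jackknife) {
        // individuals absent from this pair keep the full-pair value
        // (accumulate for all, then correct the complete ones)
        for (int i = 0; i < n; ++i) {
          jk_wr2[i] += w * r2; jk_w[i] += w;
          jk_inv[i] += 1.0 / m; jk_pairs[i] += 1.0;
        }
        for (int t = 0; t < m; ++t) {
          int i = idx[t];
          int x = G(i, j), y = G(i, k);
          int m1 = m - 1;
          // remove the full-pair contribution added above
          jk_wr2[i] -= w * r2; jk_w[i] -= w;
          jk_inv[i] -= 1.0 / m; jk_pairs[i] -= 1.0;
          if (m1 < min_n || m1 < 2) continue;
          double sx1 = sx - x, sy1 = sy - y;
          double sxx1 = sxx - (double)x * x,
                 syy1 = syy - (double)y * y,
                 sxy1 = sxy - (double)x * y;
          double vx1 = m1 * sxx1 - sx1 * sx1,
                 vy1 = m1 * syy1 - sy1 * sy1;
          if (vx1 <= 0 || vy1 <= 0) continue;
          double r1 = (m1 * sxy1 - sx1 * sy1) / std::sqrt(vx1 * vy1);
          double sc1 = (double)m1 / (m1 - 1);
          double r21 = r1 * r1 * sc1 * sc1;
          jk_wr2[i] += m1 * r21; jk_w[i] += m1;
          jk_inv[i] += 1.0 / m1; jk_pairs[i] += 1.0;
        }
      }
    }
  }
  if (n_pairs < 1) stop("no locus pair with enough complete individuals");
  double mean_r2 = (double)(wr2 / wsum);
  double S = (double)(n_pairs / inv_n);
  List out = List::create(_["mean_r2"] = mean_r2, _["S"] = S,
                          _["n_pairs"] = n_pairs);
  if (jackknife) {
    NumericVector jr2(n), jS(n);
    for (int i = 0; i < n; ++i) {
      jr2[i] = jk_w[i] > 0 ? (double)(jk_wr2[i] / jk_w[i]) : NA_REAL;
      jS[i] = jk_inv[i] > 0 ? (double)(jk_pairs[i] / jk_inv[i]) : NA_REAL;
    }
    out["jack_r2"] = jr2;
    out["jack_S"] = jS;
  }
  return out;
}
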