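#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Direction of a single comparison: +1 i higher, -1 j higher, 0 tie.
static inline int dir3(double a, double b) {
  return a > b ? 1 : (a < b ? -1 : 0);
}

// Direction of a pair across the columns of a rank/value matrix.
// fS = f * n_samples; counts are compared against fS with a small
// epsilon so that exact thresholds (f = 1, f = 0.99 on round cohorts)
// behave as integer comparisons. Ties count against stability.
static int pair_direction(const NumericMatrix& R, const int i, const int j,
                          const double fS, const bool strict) {
  const int S = R.ncol();
  int hi = 0, lo = 0;
  for (int s = 0; s < S; ++s) {
    const double a = R(i, s), b = R(j, s);
    if (a > b) ++hi; else if (a < b) ++lo;
  }
  if (strict) {
    if (hi > fS + 1e-9) return 1;
    if (lo > fS + 1e-9) return -1;
  } else {
    if (hi >= fS - 1e-9) return 1;
    if (lo >= fS - 1e-9) return -1;
  }
  return 0;
}

// Materialize all stable pairs (indices are 1-based, i < j in matrix order).
// [[Rcpp::export]]
List cpp_stable_pairs(const NumericMatrix& ranks, const double f,
                      const bool strict) {
  const int G = ranks.nrow();
  const double fS = f * ranks.ncol();
  std::vector<int> vi, vj, vd;
  for (int i = 0; i < G - 1; ++i) {
    for (int j = i + 1; j < G; ++j) {
      const int d = pair_direction(ranks, i, j, fS, strict);
      if (d != 0) {
        vi.push_back(i + 1);
        vj.push_back(j + 1);
        vd.push_back(d);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["direction"] = wrap(vd));
}

// Count stable pairs without materializing them.
// [[Rcpp::export]]
double cpp_count_stable(const NumericMatrix& ranks, const double f,
                        const bool strict) {
  const int G = ranks.nrow();
  const double fS = f * ranks.ncol();
  long long n = 0;
  for (int i = 0; i < G - 1; ++i) {
    for (int j = i + 1; j < G; ++j) {
      if (pair_direction(ranks, i, j, fS, strict) != 0) ++n;
    }
    Rcpp::checkUserInterrupt();
  }
  return (double)n;
}

// Consistency score of a query profile against an implicit stable-pair
// reference, optionally excluding the floor(x * n) stable pairs with the
// smallest mean absolute rank difference over the defining samples.
// Pairs are visited in lexicographic gene-id order (lex_order is the
// 0-based permutation sorting gene ids), so ties at the exclusion cutoff
// are dropped deterministically in canonical pair order. Average-rank
// ties make all ranks multiples of 1/2, hence 2 * sum|diff| is integral
// and an exact integer histogram yields the exclusion cutoff without
// storing per-pair records.
// [[Rcpp::export]]
List cpp_consistency_implicit(const NumericMatrix& ref_ranks,
                              const NumericVector& query,
                              const double f, const bool strict,
                              const double exclude_fraction,
                              const bool drop_ties,
                              const IntegerVector& lex_order) {
  const int G = ref_ranks.nrow();
  const int m = ref_ranks.ncol();
  const double fS = f * m;

  long long cutoff_key = -1, drop_at_cut = 0;
  if (exclude_fraction > 0) {
    const long long maxkey = (long long)(2.0 * m * G) + 2;
    std::vector<long long> hist((size_t)maxkey + 1, 0);
    long long n0 = 0;
    for (int a = 0; a < G - 1; ++a) {
      const int i = lex_order[a];
      for (int b = a + 1; b < G; ++b) {
        const int j = lex_order[b];
        if (pair_direction(ref_ranks, i, j, fS, strict) == 0) continue;
        double s2 = 0;
        for (int s = 0; s < m; ++s)
          s2 += std::fabs(ref_ranks(i, s) - ref_ranks(j, s));
        const long long key = (long long)std::llround(2.0 * s2);
        ++hist[(size_t)key];
        ++n0;
      }
      Rcpp::checkUserInterrupt();
    }
    const long long drop = (long long)std::floor(exclude_fraction * (double)n0);
    long long cum = 0;
    for (long long key = 0; key <= maxkey; ++key) {
      if (cum + hist[(size_t)key] >= drop) {
        cutoff_key = key;
        drop_at_cut = drop - cum;
        break;
      }
      cum += hist[(size_t)key];
    }
  }

  long long n_before = 0, n = 0, k = 0, dropped = 0;
  for (int a = 0; a < G - 1; ++a) {
    const int i = lex_order[a];
    const double qi = query[i];
    for (int b = a + 1; b < G; ++b) {
      const int j = lex_order[b];
      const int d = pair_direction(ref_ranks, i, j, fS, strict);
      if (d == 0) continue;
      ++n_before;
      if (cutoff_key >= 0) {
        double s2 = 0;
        for (int s = 0; s < m; ++s)
          s2 += std::fabs(ref_ranks(i, s) - ref_ranks(j, s));
        const long long key = (long long)std::llround(2.0 * s2);
        if (key < cutoff_key) continue;
        if (key == cutoff_key && dropped < drop_at_cut) {
          ++dropped;
          continue;
        }
      }
      const int qd = dir3(qi, query[j]);
      if (qd == 0) {            // query tie
        if (!drop_ties) ++n;    // counts as discordant
        continue;
      }
      ++n;
      if (qd == d) ++k;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_before"] = (double)n_before, _["n"] = (double)n,
                      _["k"] = (double)k);
}

// Reversal pairs between two classes: stable within each class (per f,
// strict) with opposite directions. Returns per-pair class-wise mean
// absolute rank differences alongside indices (1-based).
// [[Rcpp::export]]
List cpp_reversal_pairs(const NumericMatrix& ranks_a,
                        const NumericMatrix& ranks_b,
                        const double f, const bool strict) {
  const int G = ranks_a.nrow();
  const int Sa = ranks_a.ncol(), Sb = ranks_b.ncol();
  const double fSa = f * Sa, fSb = f * Sb;
  std::vector<int> vi, vj, vda;
  std::vector<double> ma, mb;
  for (int i = 0; i < G - 1; ++i) {
    for (int j = i + 1; j < G; ++j) {
      const int da = pair_direction(ranks_a, i, j, fSa, strict);
      if (da == 0) continue;
      const int db = pair_direction(ranks_b, i, j, fSb, strict);
      if (db != -da) continue;
      double sa = 0, sb = 0;
      for (int s = 0; s < Sa; ++s)
        sa += std::fabs(ranks_a(i, s) - ranks_a(j, s));
      for (int s = 0; s < Sb; ++s)
        sb += std::fabs(ranks_b(i, s) - ranks_b(j, s));
      vi.push_back(i + 1);
      vj.push_back(j + 1);
      vda.push_back(da);
      ma.push_back(sa / Sa);
      mb.push_back(sb / Sb);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["direction_a"] = wrap(vda),
                      _["mean_rank_diff_a"] = wrap(ma),
                      _["mean_rank_diff_b"] = wrap(mb));
}
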