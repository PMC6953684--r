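#include <Rcpp.h>
using namespace Rcpp;

// Sequential-swap Markov chain over binary matrices with both margins fixed.
//
// Each attempt is lazy with probability 1/2 (a self-loop); otherwise it
// draws a random 2x2 submatrix (distinct row pair, distinct column pair)
// and, if it is a checkerboard ([[1,0],[0,1]] or [[0,1],[1,0]]), flips it to
// the other checkerboard; any other submatrix leaves the state unchanged.
// Row and column totals are invariant under every step.  The proposal is
// symmetric and the laziness guarantees aperiodicity (without it, a matrix
// whose every submatrix draw is swappable -- e.g. a 2x2 checkerboard --
// alternates deterministically), so the chain's stationary distribution is
// uniform over the set of matrices sharing the margins.
//
// The pairwise co-occurrence counts S[i][k] are maintained incrementally
// (O(R) per accepted swap) so the C-score of each thinned sample costs only
// O(R^2) instead of a full recount.

static inline double cscore_from_S(const std::vector<long>& r,
                                   const std::vector<std::vector<long> >& S,
                                   int R) {
  double total = 0.0;
  for (int i = 0; i < R; ++i)
    for (int k = i + 1; k < R; ++k)
      total += (double)(r[i] - S[i][k]) * (double)(r[k] - S[i][k]);
  double npairs = (double)R * (R - 1) / 2.0;
  return total / npairs;
}

// [[Rcpp::export]]
List cpp_swap_chain(IntegerMatrix m0, int n_samples, int burn_in, int thin,
                    int keep) {
  // keep: 0 = statistic values only, 1 = also flat 0/1 string keys,
  //       2 = also full sampled matrices
  IntegerMatrix m = clone(m0);
  const int R = m.nrow(), C = m.ncol();
  if (R < 2 || C < 2) stop("matrix must have at least 2 rows and 2 columns");

  std::vector<long> r(R, 0), c(C, 0);
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < C; ++j)
      if (m(i, j)) { ++r[i]; ++c[j]; }

  std::vector<std::vector<long> > S(R, std::vector<long>(R, 0));
  for (int i = 0; i < R; ++i)
    for (int k = i + 1; k < R; ++k) {
      long s = 0;
      for (int j = 0; j < C; ++j)
        if (m(i, j) && m(k, j)) ++s;
      S[i][k] = s;
    }

  NumericVector values(n_samples);
  CharacterVector keys(keep == 1 ? n_samples : 0);
  List mats(keep == 2 ? n_samples : 0);
  long long accepted_burnin = 0, accepted_total = 0;
  int margin_violations = 0;

  RNGScope scope;
  std::string keybuf(R * C, '0');

  long long total_attempts =
      (long long)burn_in + (long long)n_samples * (long long)thin;
  int sample_idx = 0;
  long long next_sample = (long long)burn_in + thin;

  for (long long t = 1; t <= total_attempts; ++t) {
    // lazy with probability 1/2: a self-loop that still counts as an attempt
    if (unif_rand() >= 0.5) {
      int i = (int)(unif_rand() * R); if (i == R) i = R - 1;
      int k = (int)(unif_rand() * (R - 1)); if (k >= R - 1) k = R - 2;
      if (k >= i) ++k;
      int j = (int)(unif_rand() * C); if (j == C) j = C - 1;
      int l = (int)(unif_rand() * (C - 1)); if (l >= C - 1) l = C - 2;
      if (l >= j) ++l;

      int a = m(i, j), b = m(i, l), cc = m(k, j), d = m(k, l);
      bool swapped = false;
      if (a == 1 && d == 1 && b == 0 && cc == 0) {
        m(i, j) = 0; m(k, l) = 0; m(i, l) = 1; m(k, j) = 1;
        swapped = true;
      } else if (a == 0 && d == 0 && b == 1 && cc == 1) {
        m(i, j) = 1; m(k, l) = 1; m(i, l) = 0; m(k, j) = 0;
        swapped = true;
      }
      if (swapped) {
        // Row i moved an occurrence between columns j and l; row k the
        // reverse.  Co-occurrence with any third row t changes by the
        // entries of t at those columns; the (i,k) pair is unchanged (both
        // cells stay discordant).
        int from_i = m(i, j) ? l : j;  // column row i just vacated
        int to_i = m(i, j) ? j : l;    // column row i now occupies
        for (int tt = 0; tt < R; ++tt) {
          if (tt == i || tt == k) continue;
          long d_i = (long)m(tt, to_i) - (long)m(tt, from_i);
          int a1 = std::min(i, tt), b1 = std::max(i, tt);
          S[a1][b1] += d_i;
          int a2 = std::min(k, tt), b2 = std::max(k, tt);
          S[a2][b2] -= d_i;
        }
        ++accepted_total;
        if (t <= burn_in) ++accepted_burnin;
      }
    }

    if (t == next_sample && sample_idx < n_samples) {
      values[sample_idx] = cscore_from_S(r, S, R);
      // margin audit: every sample must reproduce the source totals
      for (int ii = 0; ii < R; ++ii) {
        long rs = 0;
        for (int jj = 0; jj < C; ++jj) rs += m(ii, jj);
        if (rs != r[ii]) ++margin_violations;
      }
      for (int jj = 0; jj < C; ++jj) {
        long cs = 0;
        for (int ii = 0; ii < R; ++ii) cs += m(ii, jj);
        if (cs != c[jj]) ++margin_violations;
      }
      if (keep == 1) {
        for (int ii = 0; ii < R; ++ii)
          for (int jj = 0; jj < C; ++jj)
            keybuf[ii * C + jj] = m(ii, jj) ? '1' : '0';
        keys[sample_idx] = keybuf;
      } else if (keep == 2) {
        mats[sample_idx] = clone(m);
      }
      ++sample_idx;
      next_sample += thin;
    }
  }

  List out = List::create(
      _["values"] = values,
      _["accepted_burnin"] = (double)accepted_burnin,
      _["accepted_total"] = (double)accepted_total,
      _["margin_violations"] = margin_violations,
      _["attempts"] = (double)total_attempts);
  if (keep == 1) out["keys"] = keys;
  if (keep == 2) out["matrices"] = mats;
  return out;
}
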