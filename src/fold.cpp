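#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted Nussinov maximum base-pairing over nested structures.
// Pair weights GC=3, AU=2, GU=1; T treated as U. A pair (i,j) requires
// j - i > min_loop (so at least min_loop unpaired bases between them).

static inline int pair_weight(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop) {
  int n = seq.size();
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w == 0) continue;
        int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
        int rest = (k + 1 <= j) ? M[k + 1][j] : 0;
        int s = w + inner + rest;
        if (s > best) best = s;
      }
      M[i][j] = best;
    }
  }

  // traceback: prefer pairing the smallest i, with the largest partner j
  IntegerVector partner(n, -1);
  std::vector<std::pair<int, int>> stack;
  if (n > 1) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    bool paired = false;
    for (int k = j; k > i + min_loop; --k) {
      int w = pair_weight(seq[i], seq[k]);
      if (w == 0) continue;
      int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
      int rest = (k + 1 <= j) ? M[k + 1][j] : 0;
      if (w + inner + rest == M[i][j]) {
        partner[i] = k;
        partner[k] = i;
        if (k - 1 > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  std::string db(n, '.');
  int npairs = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      db[i] = '(';
      db[partner[i]] = ')';
      ++npairs;
    }
  }

  return List::create(_["score"] = (n > 1 ? M[0][n - 1] : 0),
                      _["partner"] = partner,
                      _["dot_bracket"] = db,
                      _["n_pairs"] = npairs);
}

// miRNA:target duplex penalty minimisation with a bounded number of gaps.
// mirna is 5'->3'; site_rev is the target site read 3'->5' so that position
// k of the miRNA faces position k of site_rev. Penalties per miRNA position:
// complementary 0, G:U wobble 0.5, mismatch 1, gap 2; doubled inside the
// seed (miRNA positions seed_lo..seed_hi, 1-based); positions beyond
// score_len are not scored.

static inline double base_pen(char a, char b, double mismatch_pen, double wobble_pen) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
      (a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 0.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wobble_pen;
  return mismatch_pen;
}

static inline double pos_mult(int pos1, int seed_lo, int seed_hi, int score_len,
                              double seed_mult) {
  if (pos1 > score_len) return 0.0;
  if (pos1 >= seed_lo && pos1 <= seed_hi) return seed_mult;
  return 1.0;
}

// [[Rcpp::export(name = ".duplex_dp_cpp")]]
List duplex_dp_cpp(std::string mirna, std::string site_rev, int max_gaps,
                   double gap_pen, int seed_lo, int seed_hi, int score_len,
                   double seed_mult, double mismatch_pen, double wobble_pen) {
  int m = mirna.size(), n = site_rev.size();
  const double INF = 1e18;
  // dp[g][i][j]: min penalty aligning mirna[0..i) with site_rev[0..j) using g gaps
  std::vector<std::vector<std::vector<double>>> dp(
      max_gaps + 1,
      std::vector<std::vector<double>>(m + 1, std::vector<double>(n + 1, INF)));
  for (int g = 0; g <= max_gaps; ++g) dp[g][0][0] = 0.0;

  for (int g = 0; g <= max_gaps; ++g) {
    for (int i = 0; i <= m; ++i) {
      for (int j = 0; j <= n; ++j) {
        double cur = dp[g][i][j];
        if (cur >= INF) continue;
        if (i < m && j < n) {
          double c = cur + base_pen(mirna[i], site_rev[j], mismatch_pen, wobble_pen) *
                               pos_mult(i + 1, seed_lo, seed_hi, score_len, seed_mult);
          if (c < dp[g][i + 1][j + 1]) dp[g][i + 1][j + 1] = c;
        }
        if (g < max_gaps) {
          if (i < m) {  // miRNA base opposite a gap in the site
            double c = cur + gap_pen * pos_mult(i + 1, seed_lo, seed_hi, score_len, seed_mult);
            if (c < dp[g + 1][i + 1][j]) dp[g + 1][i + 1][j] = c;
          }
          if (j < n) {  // site base opposite a gap in the miRNA
            double c = cur + gap_pen * pos_mult(std::min(i + 1, m), seed_lo, seed_hi, score_len, seed_mult);
            if (c < dp[g + 1][i][j + 1]) dp[g + 1][i][j + 1] = c;
          }
        }
      }
    }
  }

  double best = INF;
  int best_g = -1;
  for (int g = 0; g <= max_gaps; ++g) {
    if (dp[g][m][n] < best - 1e-12) {
      best = dp[g][m][n];
      best_g = g;  // ties resolved toward fewer gaps
    }
  }
  if (best_g < 0) return List::create(_["score"] = NA_REAL);

  // traceback (prefer the aligned move, then site-gap, then miRNA-gap)
  std::string a_mir, a_site, a_mark;
  int i = m, j = n, g = best_g;
  while (i > 0 || j > 0) {
    double cur = dp[g][i][j];
    bool moved = false;
    if (i > 0 && j > 0) {
      double c = base_pen(mirna[i - 1], site_rev[j - 1], mismatch_pen, wobble_pen) *
                 pos_mult(i, seed_lo, seed_hi, score_len, seed_mult);
      if (std::abs(dp[g][i - 1][j - 1] + c - cur) < 1e-9) {
        double p = base_pen(mirna[i - 1], site_rev[j - 1], 1.0, 0.5);
        a_mir += mirna[i - 1];
        a_site += site_rev[j - 1];
        a_mark += (p == 0.0 ? '|' : (p == 0.5 ? 'o' : ' '));
        --i; --j;
        moved = true;
      }
    }
    if (!moved && g > 0 && i > 0) {
      double c = gap_pen * pos_mult(i, seed_lo, seed_hi, score_len, seed_mult);
      if (std::abs(dp[g - 1][i - 1][j] + c - cur) < 1e-9) {
        a_mir += mirna[i - 1];
        a_site += '-';
        a_mark += ' ';
        --i; --g;
        moved = true;
      }
    }
    if (!moved && g > 0 && j > 0) {
      a_mir += '-';
      a_site += site_rev[j - 1];
      a_mark += ' ';
      --j; --g;
      moved = true;
    }
    if (!moved) break;  // defensive; should not happen
  }
  std::reverse(a_mir.begin(), a_mir.end());
  std::reverse(a_site.begin(), a_site.end());
  std::reverse(a_mark.begin(), a_mark.end());

  return List::create(_["score"] = best, _["n_gaps"] = best_g,
                      _["mirna_aln"] = a_mir, _["site_aln"] = a_site,
                      _["pairing"] = a_mark);
}
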