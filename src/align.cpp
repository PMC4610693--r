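#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) with explicit match counting.
// Scores: match > 0, mismatch/gap penalties given as non-negative costs;
// a gap of length L costs gap_open + L * gap_extend (BLAST/Biostrings
// convention). Matches are counted on the traceback path; only identical
// A/C/G/T pairs count (N never matches).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct AlnStats {
  double score;
  int matches;
  int columns;
};

// Global (Needleman-Wunsch) alignment, end gaps penalized.
// Traceback prefers diagonal over gap-in-b over gap-in-a so that the
// reported alignment (and hence match count) is deterministic.
static AlnStats nw_align(const std::string &a, const std::string &b,
                         double match, double mismatch,
                         double gap_open, double gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  const double gi = gap_open + gap_extend;  // cost of first gap position
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // predecessor matrix of the cell we came from: 0=M, 1=X, 2=Y
  std::vector<unsigned char> pM((n + 1) * W), pX((n + 1) * W), pY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + i * gap_extend);
    pX[i * W] = (unsigned char) (i == 1 ? 0 : 1);
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + j * gap_extend);
    pY[j] = (unsigned char) (j == 1 ? 0 : 2);
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int k = i * W + j, kd = (i - 1) * W + (j - 1),
                ku = (i - 1) * W + j, kl = i * W + (j - 1);
      // N (or any non-ACGT) never scores as a match
      const double s = (ai == b[j - 1] && is_acgt(ai)) ? match : -mismatch;
      // diagonal
      double best = M[kd]; unsigned char pb = 0;
      if (X[kd] > best) { best = X[kd]; pb = 1; }
      if (Y[kd] > best) { best = Y[kd]; pb = 2; }
      M[k] = best + s; pM[k] = pb;
      // gap in b (consume a_i)
      best = M[ku] - gi; pb = 0;
      if (X[ku] - gap_extend > best) { best = X[ku] - gap_extend; pb = 1; }
      if (Y[ku] - gi > best) { best = Y[ku] - gi; pb = 2; }
      X[k] = best; pX[k] = pb;
      // gap in a (consume b_j)
      best = M[kl] - gi; pb = 0;
      if (X[kl] - gi > best) { best = X[kl] - gi; pb = 1; }
      if (Y[kl] - gap_extend > best) { best = Y[kl] - gap_extend; pb = 2; }
      Y[k] = best; pY[k] = pb;
    }
  }

  const int kend = n * W + m;
  int state = 0;
  double sc = M[kend];
  if (X[kend] > sc) { sc = X[kend]; state = 1; }
  if (Y[kend] > sc) { sc = Y[kend]; state = 2; }

  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    const int k = i * W + j;
    ++columns;
    if (state == 0) {
      if (a[i - 1] == b[j - 1] && is_acgt(a[i - 1])) ++matches;
      state = pM[k]; --i; --j;
    } else if (state == 1) {
      state = pX[k]; --i;
    } else {
      state = pY[k]; --j;
    }
  }
  AlnStats out; out.score = sc; out.matches = matches; out.columns = columns;
  return out;
}

// Local (Smith-Waterman) alignment with affine gaps.
static AlnStats sw_align(const std::string &a, const std::string &b,
                         double match, double mismatch,
                         double gap_open, double gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  const double gi = gap_open + gap_extend;
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: 0 = stop (score 0), 1 = diag, 2 = from X, 3 = from Y
  std::vector<unsigned char> pH((n + 1) * W, 0), pX((n + 1) * W, 0),
      pY((n + 1) * W, 0);

  double best_sc = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int k = i * W + j, kd = (i - 1) * W + (j - 1),
                ku = (i - 1) * W + j, kl = i * W + (j - 1);
      const double s = (ai == b[j - 1] && is_acgt(ai)) ? match : -mismatch;
      double x = H[ku] - gi; unsigned char px = 1;
      if (X[ku] - gap_extend > x) { x = X[ku] - gap_extend; px = 2; }
      X[k] = x; pX[k] = px;
      double y = H[kl] - gi; unsigned char py = 1;
      if (Y[kl] - gap_extend > y) { y = Y[kl] - gap_extend; py = 3; }
      Y[k] = y; pY[k] = py;
      double h = H[kd] + s; unsigned char ph = 1;
      if (x > h) { h = x; ph = 2; }
      if (y > h) { h = y; ph = 3; }
      if (h <= 0.0) { h = 0.0; ph = 0; }
      H[k] = h; pH[k] = ph;
      if (h > best_sc) { best_sc = h; bi = i; bj = j; }
    }
  }

  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 1;  // in H
  while (i > 0 && j > 0) {
    const int k = i * W + j;
    unsigned char p;
    if (state == 1) {
      p = pH[k];
      if (p == 0) break;
      if (p == 1) {
        ++columns;
        if (a[i - 1] == b[j - 1] && is_acgt(a[i - 1])) ++matches;
        --i; --j;
        continue;
      }
      state = (p == 2) ? 2 : 3;
      continue;
    } else if (state == 2) {
      ++columns;
      p = pX[k];
      --i;
      state = (p == 2) ? 2 : 1;
    } else {
      ++columns;
      p = pY[k];
      --j;
      state = (p == 3) ? 3 : 1;
    }
  }
  AlnStats out; out.score = best_sc; out.matches = matches;
  out.columns = columns;
  return out;
}

// Upper bound on achievable matches from base composition: an alignment
// can never match more copies of a base than both sequences carry.
static int composition_bound(const std::string &a, const std::string &b) {
  int ca[4] = {0, 0, 0, 0}, cb[4] = {0, 0, 0, 0};
  for (char c : a) {
    if (c == 'A') ++ca[0]; else if (c == 'C') ++ca[1];
    else if (c == 'G') ++ca[2]; else if (c == 'T') ++ca[3];
  }
  for (char c : b) {
    if (c == 'A') ++cb[0]; else if (c == 'C') ++cb[1];
    else if (c == 'G') ++cb[2]; else if (c == 'T') ++cb[3];
  }
  int tot = 0;
  for (int k = 0; k < 4; ++k) tot += std::min(ca[k], cb[k]);
  return tot;
}

// Arguments are ordered canonically before aligning so that results are
// exactly symmetric even when distinct optimal alignments tie on score
// but differ in match count.
// [[Rcpp::export(name = ".nw_stats")]]
List nw_stats_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  if (b < a) std::swap(a, b);
  AlnStats st = nw_align(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = st.score, _["matches"] = st.matches,
                      _["columns"] = st.columns);
}

// [[Rcpp::export(name = ".sw_stats")]]
List sw_stats_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  if (b < a) std::swap(a, b);
  AlnStats st = sw_align(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = st.score, _["matches"] = st.matches,
                      _["columns"] = st.columns);
}

// Identity of one query against many subjects. denominator: 0 = shorter
// sequence, 1 = alignment columns.
// [[Rcpp::export(name = ".identity_vec")]]
NumericVector identity_vec_cpp(std::string query, CharacterVector subjects,
                               double match, double mismatch, double gap_open,
                               double gap_extend, int denominator) {
  const int nr = subjects.size();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(subjects[r]);
    if (s == query) { out[r] = 1.0; continue; }
    AlnStats st = s < query
        ? nw_align(s, query, match, mismatch, gap_open, gap_extend)
        : nw_align(query, s, match, mismatch, gap_open, gap_extend);
    const double den = denominator == 0
        ? (double) std::min(query.size(), s.size())
        : (double) st.columns;
    out[r] = st.matches / den;
  }
  return out;
}

// Best reference match per query under a similarity threshold.
// Returns 1-based index of the best reference (0 = none reaches the
// threshold) and the best identity seen. Ties on identity go to the
// lowest reference index. The composition bound is a provable skip:
// it only prunes pairs whose identity cannot reach the threshold.
// [[Rcpp::export(name = ".best_match")]]
List best_match_cpp(CharacterVector queries, CharacterVector refs,
                    double match, double mismatch, double gap_open,
                    double gap_extend, int denominator, double threshold) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::string> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<std::string>(refs[r]);
  IntegerVector best_idx(nq);
  NumericVector best_id(nq);
  const double eps = 1e-9;
  for (int q = 0; q < nq; ++q) {
    std::string Q = as<std::string>(queries[q]);
    int bidx = 0; double bid = -1.0;
    // an exact duplicate is always the best possible hit
    for (int r = 0; r < nr; ++r) {
      if (R[r] == Q) { bidx = r + 1; bid = 1.0; break; }
    }
    for (int r = 0; bid < 1.0 - eps && r < nr; ++r) {
      double id;
      if (R[r] == Q) {
        id = 1.0;
      } else {
        const double den0 = (double) std::min(Q.size(), R[r].size());
        if (denominator == 0 && threshold > 0) {
          // pair provably below threshold: can never be the winning match
          const double ub = composition_bound(Q, R[r]) / den0;
          if (ub + eps < threshold) continue;
        }
        AlnStats st = R[r] < Q
            ? nw_align(R[r], Q, match, mismatch, gap_open, gap_extend)
            : nw_align(Q, R[r], match, mismatch, gap_open, gap_extend);
        const double den = denominator == 0 ? den0 : (double) st.columns;
        id = st.matches / den;
      }
      if (id > bid + eps) { bid = id; bidx = r + 1; }
      if (bid >= 1.0 - eps) break;
    }
    if (bid + eps < threshold) bidx = 0;
    best_idx[q] = bidx;
    best_id[q] = bid;
  }
  return List::create(_["index"] = best_idx, _["identity"] = best_id);
}
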