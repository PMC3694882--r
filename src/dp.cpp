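#include <Rcpp.h>
using namespace Rcpp;

// Shared scoring: match/mismatch on {A,C,G,T}; N (code 4) is neutral (0).
// A gap of length k costs gap_open + k * gap_extend.

static inline double subst_score(int a, int b, double match, double mismatch) {
  if (a == 4 || b == 4) return 0.0;        // N vs anything
  return (a == b) ? match : mismatch;
}

// Global affine-gap alignment (Gotoh), deterministic tie-breaking:
// prefer diagonal, then up (gap in b), then left (gap in a).
// Sequences are integer-coded: A=0, C=1, G=2, T=3, N=4.
// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double go = gap_open + gap_extend;   // cost to open a length-1 gap
  // layered DP: M (diag), X (gap in b, consume a), Y (gap in a, consume b)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Y(0, j) = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subst_score(a[i - 1], b[j - 1], match, mismatch);
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      M(i, j) = s + std::max(dM, std::max(dX, dY));
      X(i, j) = std::max(M(i - 1, j) - go,
                std::max(X(i - 1, j) - gap_extend, Y(i - 1, j) - go));
      Y(i, j) = std::max(M(i, j - 1) - go,
                std::max(X(i, j - 1) - go, Y(i, j - 1) - gap_extend));
    }
  }

  // traceback; state 0 = M, 1 = X(up), 2 = Y(left); ties prefer lower state id
  double best = M(n, m); int state = 0;
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }

  std::vector<int> ops; ops.reserve(n + m);   // 0 diag, 1 up, 2 left
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(1); --i; continue; }
    if (state == 0) {
      double s = subst_score(a[i - 1], b[j - 1], match, mismatch);
      double v = M(i, j) - s;
      ops.push_back(0);
      if (v == M(i - 1, j - 1)) state = 0;
      else if (v == X(i - 1, j - 1)) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      double v = X(i, j);
      ops.push_back(1);
      if (v == M(i - 1, j) - go) state = 0;
      else if (v == X(i - 1, j) - gap_extend) state = 1;
      else state = 2;
      --i;
    } else {
      double v = Y(i, j);
      ops.push_back(2);
      if (v == M(i, j - 1) - go) state = 0;
      else if (v == X(i, j - 1) - go) state = 1;
      else state = 2;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["ops"] = wrap(ops));
}

// Smith-Waterman local alignment score with affine gaps (score only).
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;
  std::vector<double> H(m + 1, 0.0), E(m + 1, -1e30), Hprev(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hprev);
    H[0] = 0.0;
    double F = -1e30;                        // gap in b along this row
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(Hprev[j] - go, E[j] - gap_extend);   // gap in a (vertical)
      F = std::max(H[j - 1] - go, F - gap_extend);
      double diag = Hprev[j - 1] +
        subst_score(a[i - 1], b[j - 1], match, mismatch);
      double h = std::max(0.0, std::max(diag, std::max(E[j], F)));
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Profile-profile global alignment over a precomputed column-score matrix S
// (S[i][j] = sum-of-pairs score of column i of profile A vs column j of B).
// Returns score and the merge path (0 diag, 1 up = column from A only,
// 2 left = column from B only). Same affine convention and tie-breaking.
// [[Rcpp::export]]
List profile_nw_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const double go = gap_open + gap_extend;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Y(0, j) = -(gap_open + j * gap_extend);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(i - 1, j - 1);
      M(i, j) = s + std::max(M(i - 1, j - 1),
                std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      X(i, j) = std::max(M(i - 1, j) - go,
                std::max(X(i - 1, j) - gap_extend, Y(i - 1, j) - go));
      Y(i, j) = std::max(M(i, j - 1) - go,
                std::max(X(i, j - 1) - go, Y(i, j - 1) - gap_extend));
    }
  }
  double best = M(n, m); int state = 0;
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  std::vector<int> ops; ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(1); --i; continue; }
    if (state == 0) {
      double v = M(i, j) - S(i - 1, j - 1);
      ops.push_back(0);
      if (v == M(i - 1, j - 1)) state = 0;
      else if (v == X(i - 1, j - 1)) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      double v = X(i, j);
      ops.push_back(1);
      if (v == M(i - 1, j) - go) state = 0;
      else if (v == X(i - 1, j) - gap_extend) state = 1;
      else state = 2;
      --i;
    } else {
      double v = Y(i, j);
      ops.push_back(2);
      if (v == M(i, j - 1) - go) state = 0;
      else if (v == X(i, j - 1) - go) state = 1;
      else state = 2;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["ops"] = wrap(ops));
}

// Pairwise substitution counts for all sequence pairs of an alignment under
// pairwise deletion. X is n x L, coded A=0, C=1, G=2, T=3, N=4, gap=5.
// Transitions are A<->G and C<->T (same parity of the code); any other
// mismatch among {A,C,G,T} is a transversion.
// [[Rcpp::export]]
List pair_counts_cpp(IntegerMatrix X) {
  const int n = X.nrow(), L = X.ncol();
  IntegerMatrix TS(n, n), TV(n, n), NC(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int ts = 0, tv = 0, l = 0;
      for (int k = 0; k < L; ++k) {
        int a = X(i, k), b = X(j, k);
        if (a > 3 || b > 3) continue;        // gap or N in either row
        ++l;
        if (a == b) continue;
        if ((a & 1) == (b & 1)) ++ts; else ++tv;
      }
      TS(i, j) = TS(j, i) = ts;
      TV(i, j) = TV(j, i) = tv;
      NC(i, j) = NC(j, i) = l;
    }
  }
  return List::create(_["transitions"] = TS, _["transversions"] = TV,
                      _["sites"] = NC);
}
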