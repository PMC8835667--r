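#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Profile-HMM dynamic programming in log2 space.
//
// State plan (Durbin et al. plan without J state): flanking N state before
// entry and C state after exit, both emitting at background (log-odds 0,
// free self-transitions); the model is traversed global-in-model (every
// match column visited as M or D), local-in-sequence.
//
// Transition matrix layout: (n_match + 1) x 7, row j = transitions out of
// M_j / I_j / D_j where M_0 is the begin state B and M_{n+1} the end state E.
// Columns: 0 mm, 1 mi, 2 md, 3 im, 4 ii, 5 dm, 6 dd (log2 probabilities,
// -Inf for structural zeros).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// seq: 0-based residue column indices into the emission matrices; the
// caller appends a zero log-odds column for ambiguous (X-class) residues.
// [[Rcpp::export(name = ".forward_bits_cpp")]]
double forward_bits_cpp(NumericMatrix lmatch, NumericMatrix lins,
                        NumericMatrix ltrans, IntegerVector seq) {
  const int n = lmatch.nrow();       // match states 1..n
  const int L = seq.size();

  NumericMatrix M(L + 1, n + 1), I(L + 1, n + 1), D(L + 1, n + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);

  // column 0 of M doubles as the begin state, reachable after any flank
  // prefix at zero cost
  for (int i = 0; i <= L; ++i) M(i, 0) = 0.0;

  // all-delete entry at i = 0
  D(0, 1) = ltrans(0, 2);
  for (int j = 2; j <= n; ++j) D(0, j) = D(0, j - 1) + ltrans(j - 1, 6);

  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    for (int j = 1; j <= n; ++j) {
      double from_m = M(i - 1, j - 1) + ltrans(j - 1, 0);
      double from_i = I(i - 1, j - 1) + ltrans(j - 1, 3);
      double from_d = (j >= 2) ? D(i - 1, j - 1) + ltrans(j - 1, 5) : NEG_INF;
      M(i, j) = lmatch(j - 1, x) + lse3(from_m, from_i, from_d);
    }
    for (int j = 0; j <= n; ++j) {
      double from_m = M(i - 1, j) + ltrans(j, 1);
      double from_i = I(i - 1, j) + ltrans(j, 4);
      I(i, j) = lins(j, x) + lse2(from_m, from_i);
    }
    D(i, 1) = M(i, 0) + ltrans(0, 2);
    for (int j = 2; j <= n; ++j) {
      D(i, j) = lse2(M(i, j - 1) + ltrans(j - 1, 2),
                     D(i, j - 1) + ltrans(j - 1, 6));
    }
  }

  double total = NEG_INF;
  for (int i = 0; i <= L; ++i) {
    double e = lse3(M(i, n) + ltrans(n, 0),
                    I(i, n) + ltrans(n, 3),
                    D(i, n) + ltrans(n, 5));
    total = lse2(total, e);
  }
  return total;
}

// Viterbi with traceback; returns best log-odds and the model-state path as
// a matrix with rows (type, state_index, seq_pos); type 1 = M, 2 = I, 3 = D.
// [[Rcpp::export(name = ".viterbi_bits_cpp")]]
List viterbi_bits_cpp(NumericMatrix lmatch, NumericMatrix lins,
                      NumericMatrix ltrans, IntegerVector seq) {
  const int n = lmatch.nrow();
  const int L = seq.size();

  NumericMatrix M(L + 1, n + 1), I(L + 1, n + 1), D(L + 1, n + 1);
  // predecessor codes: 0 none/begin, 1 M, 2 I, 3 D
  IntegerMatrix pM(L + 1, n + 1), pI(L + 1, n + 1), pD(L + 1, n + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);

  for (int i = 0; i <= L; ++i) M(i, 0) = 0.0;
  D(0, 1) = ltrans(0, 2); pD(0, 1) = 0;
  for (int j = 2; j <= n; ++j) { D(0, j) = D(0, j - 1) + ltrans(j - 1, 6); pD(0, j) = 3; }

  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    for (int j = 1; j <= n; ++j) {
      double cand[3] = {
        M(i - 1, j - 1) + ltrans(j - 1, 0),
        I(i - 1, j - 1) + ltrans(j - 1, 3),
        (j >= 2) ? D(i - 1, j - 1) + ltrans(j - 1, 5) : NEG_INF };
      int best = 0;
      for (int k = 1; k < 3; ++k) if (cand[k] > cand[best]) best = k;
      M(i, j) = lmatch(j - 1, x) + cand[best];
      pM(i, j) = (j == 1 && best == 0) ? 0 : best + 1;
    }
    for (int j = 0; j <= n; ++j) {
      double fm = M(i - 1, j) + ltrans(j, 1);
      double fi = I(i - 1, j) + ltrans(j, 4);
      if (fm >= fi) { I(i, j) = lins(j, x) + fm; pI(i, j) = (j == 0) ? 0 : 1; }
      else          { I(i, j) = lins(j, x) + fi; pI(i, j) = 2; }
    }
    D(i, 1) = M(i, 0) + ltrans(0, 2); pD(i, 1) = 0;
    for (int j = 2; j <= n; ++j) {
      double fm = M(i, j - 1) + ltrans(j - 1, 2);
      double fd = D(i, j - 1) + ltrans(j - 1, 6);
      if (fm >= fd) { D(i, j) = fm; pD(i, j) = 1; } else { D(i, j) = fd; pD(i, j) = 3; }
    }
  }

  double best_score = NEG_INF;
  int best_i = 0, best_type = 1;
  for (int i = 0; i <= L; ++i) {
    double cand[3] = { M(i, n) + ltrans(n, 0),
                       I(i, n) + ltrans(n, 3),
                       D(i, n) + ltrans(n, 5) };
    for (int k = 0; k < 3; ++k) {
      if (cand[k] > best_score) { best_score = cand[k]; best_i = i; best_type = k + 1; }
    }
  }

  // traceback
  std::vector<int> type, state, pos;
  int i = best_i, j = n, t = best_type;
  while (!(t == 1 && j == 0)) {
    type.push_back(t); state.push_back(j); pos.push_back(t == 3 ? NA_INTEGER : i);
    int prev;
    if (t == 1) { prev = pM(i, j); --i; --j; }
    else if (t == 2) { prev = pI(i, j); --i; }
    else { prev = pD(i, j); --j; }
    if (prev == 0) break;
    t = prev;
  }
  const int m = (int) type.size();
  IntegerMatrix path(m, 3);
  for (int k = 0; k < m; ++k) {
    path(k, 0) = type[m - 1 - k];
    path(k, 1) = state[m - 1 - k];
    path(k, 2) = pos[m - 1 - k];
  }
  colnames(path) = CharacterVector::create("type", "state", "seq_pos");
  return List::create(_["bits"] = best_score, _["path"] = path);
}
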