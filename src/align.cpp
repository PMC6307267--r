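#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Gotoh global alignment with affine gaps.
//
// Scoring: +match for identical bases, +mismatch otherwise; a gap of
// length L costs gapOpen + L * gapExt (the first gapped base pays both
// the opening and the extension charge). End gaps are penalized like any
// other gap. Traceback tie-break is fixed: diagonal beats a gap in the
// query row ("up", consuming a reference base) which beats a gap in the
// reference row ("left", consuming a query base), so identical inputs
// always produce the same alignment.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string query,
                 double match = 5.0, double mismatch = -4.0,
                 double gapOpen = 10.0, double gapExt = 0.5) {
  const int n = ref.size();
  const int m = query.size();
  if (n == 0 || m == 0)
    stop("both sequences must be non-empty");

  const double gapFirst = gapOpen + gapExt;  // cost of the first gapped base

  // M: last column aligned ref[i-1] to query[j-1]
  // X: last column is a gap in the query row (consumes ref base i)
  // Y: last column is a gap in the reference row (consumes query base j)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback state: which of M/X/Y achieved the cell, 0=M,1=X,2=Y
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);

  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = -gapOpen - gapExt * i;
    tbX[IDX(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = -gapOpen - gapExt * j;
    tbY[IDX(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (ref[i - 1] == query[j - 1]) ? match : mismatch;

      // diagonal: best of the three states at (i-1, j-1), tie M > X > Y
      {
        double a = M[IDX(i - 1, j - 1)], b = X[IDX(i - 1, j - 1)],
               c = Y[IDX(i - 1, j - 1)];
        double best = a; unsigned char st = 0;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        M[IDX(i, j)] = best + s;
        tbM[IDX(i, j)] = st;
      }
      // gap in query row: extend from (i-1, j)
      {
        double a = M[IDX(i - 1, j)] - gapFirst;
        double b = X[IDX(i - 1, j)] - gapExt;
        double c = Y[IDX(i - 1, j)] - gapFirst;
        double best = a; unsigned char st = 0;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        X[IDX(i, j)] = best;
        tbX[IDX(i, j)] = st;
      }
      // gap in reference row: extend from (i, j-1)
      {
        double a = M[IDX(i, j - 1)] - gapFirst;
        double b = X[IDX(i, j - 1)] - gapFirst;
        double c = Y[IDX(i, j - 1)] - gapExt;
        double best = a; unsigned char st = 0;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        Y[IDX(i, j)] = best;
        tbY[IDX(i, j)] = st;
      }
    }
  }

  // terminal state, tie M > X > Y (diagonal > up > left)
  double score = M[IDX(n, m)];
  unsigned char state = 0;
  if (X[IDX(n, m)] > score) { score = X[IDX(n, m)]; state = 1; }
  if (Y[IDX(n, m)] > score) { score = Y[IDX(n, m)]; state = 2; }

  std::string refRow, queryRow;
  refRow.reserve(n + m);
  queryRow.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = tbM[IDX(i, j)];
      refRow.push_back(ref[i - 1]);
      queryRow.push_back(query[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      unsigned char prev = tbX[IDX(i, j)];
      refRow.push_back(ref[i - 1]);
      queryRow.push_back('-');
      --i;
      state = prev;
    } else {
      unsigned char prev = tbY[IDX(i, j)];
      refRow.push_back('-');
      queryRow.push_back(query[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(refRow.begin(), refRow.end());
  std::reverse(queryRow.begin(), queryRow.end());
#undef IDX

  return List::create(_["ref_row"] = refRow,
                      _["query_row"] = queryRow,
                      _["score"] = score);
}

// Hamming distance of `pattern` against every length-|pattern| window of
// `subject`; returns integer vector of length |subject| - |pattern| + 1.
// Used by the brute-force off-target oracle and the indicator search.
// [[Rcpp::export(name = ".hamming_scan")]]
IntegerVector hamming_scan(std::string subject, std::string pattern) {
  const int n = subject.size(), k = pattern.size();
  if (k == 0 || k > n) return IntegerVector(0);
  IntegerVector out(n - k + 1);
  for (int i = 0; i + k <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < k; ++j)
      if (subject[i + j] != pattern[j]) ++mm;
    out[i] = mm;
  }
  return out;
}
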