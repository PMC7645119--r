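#include <Rcpp.h>
using namespace Rcpp;

// Gotoh local alignment. Gap of length L costs open + (L-1)*extend:
// the first gapped residue is charged `open`, each further one `extend`.
// Cell maxima are resolved toward the first-encountered cell in row-major
// order so tied optima are deterministic.

static const double NEG = -1e30;

// [[Rcpp::export]]
double sw_score_cpp(IntegerVector q, IntegerVector t, NumericMatrix sub,
                    double open, double ext) {
  int m = q.size(), n = t.size();
  int na = sub.nrow();
  std::vector<double> S(sub.begin(), sub.end());  // column-major flat copy
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG);
  std::vector<int> ti(t.begin(), t.end());
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    const double* srow = &S[q[i - 1]];  // row q[i-1], stride na
    double diag = 0.0;      // H[i-1][j-1]
    double F = NEG;         // gap consuming query, within row i
    H[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double e = H[j] - open, e2 = E[j] - ext;
      if (e2 > e) e = e2;
      E[j] = e;
      double f = H[j - 1] - open, f2 = F - ext;
      F = (f2 > f) ? f2 : f;
      double h = diag + srow[(size_t)ti[j - 1] * na];
      if (e > h) h = e;
      if (F > h) h = F;
      if (h < 0.0) h = 0.0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector sw_score_many_cpp(IntegerVector q, List targets,
                                NumericMatrix sub, double open, double ext) {
  int k = targets.size();
  NumericVector out(k);
  for (int i = 0; i < k; ++i)
    out[i] = sw_score_cpp(q, targets[i], sub, open, ext);
  return out;
}

// Full DP with traceback: returns score, 1-based spans on query and target,
// and the number of alignment columns of the best local alignment.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, NumericMatrix sub,
                  double open, double ext) {
  int m = q.size(), n = t.size();
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(H(i, j - 1) - open, E(i, j - 1) - ext);
      F(i, j) = std::max(H(i - 1, j) - open, F(i - 1, j) - ext);
      double h = H(i - 1, j - 1) + sub(q[i - 1], t[j - 1]);
      if (E(i, j) > h) h = E(i, j);
      if (F(i, j) > h) h = F(i, j);
      if (h < 0.0) h = 0.0;
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["t_start"] = NA_INTEGER,
                        _["t_end"] = NA_INTEGER, _["length"] = 0);
  // traceback from (bi,bj); state 0 = H, 1 = E (gap in query), 2 = F
  int i = bi, j = bj, state = 0, len = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H(i, j) == 0.0) break;
      double diag = H(i - 1, j - 1) + sub(q[i - 1], t[j - 1]);
      if (H(i, j) == diag) { --i; --j; ++len; }
      else if (H(i, j) == E(i, j)) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++len;
      if (E(i, j) == E(i, j - 1) - ext) { --j; }
      else { --j; state = 0; }
    } else {
      ++len;
      if (F(i, j) == F(i - 1, j) - ext) { --i; }
      else { --i; state = 0; }
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["t_start"] = j + 1,
                      _["t_end"] = bj, _["length"] = len);
}
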