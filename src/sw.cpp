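#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh). A gap of length k
// costs open + k * ext (the first gapped residue pays open + ext), matching
// the BLAST convention for e.g. BLOSUM62 11/1. `sub` is a square integer
// substitution matrix; `q` and `s` hold 0-based indices into it.
// Identity is computed on the traceback of one optimal local alignment
// (highest-scoring cell; ties resolved to the first cell in row-major order).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector s, IntegerMatrix sub,
              double open, double ext) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e18;
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  // tbH: 0 stop, 1 diag, 2 from F (gap in subject dim, i.e. up), 3 from E
  // tbE: 1 opened from H, 0 extended from E; tbF likewise.
  IntegerMatrix tbH(m + 1, n + 1), tbE(m + 1, n + 1), tbF(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double eOpen = H(i, j - 1) - open - ext, eExt = E(i, j - 1) - ext;
      if (eOpen >= eExt) { E(i, j) = eOpen; tbE(i, j) = 1; }
      else               { E(i, j) = eExt;  tbE(i, j) = 0; }
      double fOpen = H(i - 1, j) - open - ext, fExt = F(i - 1, j) - ext;
      if (fOpen >= fExt) { F(i, j) = fOpen; tbF(i, j) = 1; }
      else               { F(i, j) = fExt;  tbF(i, j) = 0; }
      double diag = H(i - 1, j - 1) + sub(q[i - 1], s[j - 1]);
      double h = 0.0; int t = 0;
      if (diag > h)    { h = diag;    t = 1; }
      if (F(i, j) > h) { h = F(i, j); t = 2; }
      if (E(i, j) > h) { h = E(i, j); t = 3; }
      H(i, j) = h; tbH(i, j) = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, matches = 0, alen = 0;
  int state = 0;  // 0 in H, 2 in F, 3 in E
  while (i > 0 && j > 0) {
    if (state == 0) {
      int t = tbH(i, j);
      if (t == 0) break;
      if (t == 1) {
        if (q[i - 1] == s[j - 1]) ++matches;
        ++alen; --i; --j;
      } else {
        state = t;
      }
    } else if (state == 2) {
      int o = tbF(i, j);
      ++alen; --i;
      if (o == 1) state = 0;
    } else {
      int o = tbE(i, j);
      ++alen; --j;
      if (o == 1) state = 0;
    }
  }
  double identity = alen > 0 ? (double)matches / (double)alen : 0.0;
  return List::create(_["score"] = best, _["identity"] = identity,
                      _["aln_length"] = alen);
}

// Score-only variant with linear memory, used for all-vs-all screening.
// [[Rcpp::export(name = ".sw_score")]]
double sw_score(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                double open, double ext) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e18;
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG), Fc(n + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    double diagPrev = H[0];
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(E[j - 1] - ext, H[j - 1] - open - ext);
      Fc[j] = std::max(Fc[j] - ext, H[j] - open - ext);
      double diag = diagPrev + sub(q[i - 1], s[j - 1]);
      diagPrev = H[j];
      double h = 0.0;
      if (diag > h) h = diag;
      if (Fc[j] > h) h = Fc[j];
      if (E[j] > h) h = E[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
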