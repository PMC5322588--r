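#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Needleman-Wunsch global alignment, linear gap penalty.
// Tie-breaking during fill and traceback: diagonal beats up (gap in b),
// up beats left (gap in a), so co-optimal alignments resolve deterministically.
static void nw_core(const std::string& a, const std::string& b,
                    double match, double mismatch, double gap,
                    std::string& aa, std::string& bb, double& best) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // dir: 0 = diag, 1 = up (consume a), 2 = left (consume b)
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; dir[j] = 2; }
  dir[0] = 0;
  const char* pa = a.data();
  const char* pb = b.data();
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    unsigned char* drow = &dir[(size_t)i * (m + 1)];
    drow[0] = 1;
    const char ai = pa[i - 1];
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (ai == pb[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double s = d; unsigned char k = 0;
      if (u > s) { s = u; k = 1; }
      if (l > s) { s = l; k = 2; }
      cur[j] = s;
      drow[j] = k;
    }
    std::swap(prev, cur);
  }
  best = prev[m];
  aa.clear(); bb.clear();
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char k = dir[(size_t)i * (m + 1) + j];
    if (k == 0) { aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j; }
    else if (k == 1) { aa.push_back(a[i - 1]); bb.push_back('-'); --i; }
    else { aa.push_back('-'); bb.push_back(b[j - 1]); --j; }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
}

static double pdist_core(const std::string& a, const std::string& b) {
  long comparable = 0, diff = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] == '-' || b[i] == '-') continue;
    ++comparable;
    if (a[i] != b[i]) ++diff;
  }
  if (comparable == 0) return NA_REAL;
  return (double)diff / (double)comparable;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  std::string aa, bb; double score;
  nw_core(a, b, match, mismatch, gap, aa, bb, score);
  return List::create(_["a"] = aa, _["b"] = bb, _["score"] = score);
}

// [[Rcpp::export]]
double p_distance_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("aligned sequences must have equal length");
  return pdist_core(a, b);
}

// Full pairwise p-distance matrix: align each pair, then uncorrected
// p-distance under pairwise deletion of gap columns.
// [[Rcpp::export]]
NumericMatrix nw_pdist_matrix_cpp(std::vector<std::string> seqs,
                                  double match, double mismatch, double gap) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::string aa, bb; double score;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      nw_core(seqs[i], seqs[j], match, mismatch, gap, aa, bb, score);
      double d = pdist_core(aa, bb);
      if (NumericVector::is_na(d))
        stop("no comparable alignment columns between a sequence pair");
      out(i, j) = d;
      out(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Mismatch count of `motif` against every window of `s` (sliding Hamming
// scan); returns integer(0) when s is shorter than motif.
// [[Rcpp::export]]
IntegerVector hamming_scan_cpp(std::string s, std::string motif) {
  const int n = s.size(), m = motif.size();
  if (n < m) return IntegerVector(0);
  IntegerVector out(n - m + 1);
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < m; ++j) if (s[i + j] != motif[j]) ++mm;
    out[i] = mm;
  }
  return out;
}
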