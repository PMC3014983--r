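#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Pairwise alignment kernel with linear gap costs.
//
// mode "overlap": semi-global alignment with free end gaps on both
// sequences (first row/column initialised to 0, best score taken over the
// last row and column, traceback stops at the first row/column).
// mode "local": Smith-Waterman (cells floored at 0, best score anywhere,
// traceback stops at a zero cell).
//
// Traceback tie order is fixed (diagonal > up > left) so results are
// deterministic; start-cell ties resolve to the smallest row then column.

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, std::string mode,
                    double match, double mismatch, double gap) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (n == 0 || m == 0)
    stop("sequences must be non-empty");
  const bool local = (mode == "local");
  if (!local && mode != "overlap")
    stop("mode must be 'overlap' or 'local'");

  // score matrix (n+1) x (m+1), row-major
  std::vector<double> S((size_t)(n + 1) * (m + 1), 0.0);
  // traceback: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<unsigned char> T((size_t)(n + 1) * (m + 1), 0);

  if (!local && gap > 0)
    stop("gap penalty must be <= 0");

  for (int i = 1; i <= n; ++i) {
    const char ai = a[(size_t)i - 1];
    const size_t row = (size_t)i * (m + 1);
    const size_t prow = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      const double sub = (ai == b[(size_t)j - 1]) ? match : mismatch;
      double best = S[prow + (j - 1)] + sub;
      unsigned char tb = 1;
      const double up = S[prow + j] + gap;
      if (up > best) { best = up; tb = 2; }
      const double left = S[row + (j - 1)] + gap;
      if (left > best) { best = left; tb = 3; }
      if (local && best <= 0.0) { best = 0.0; tb = 0; }
      S[row + j] = best;
      T[row + j] = tb;
    }
  }

  // locate alignment end
  int ei = 0, ej = 0;
  double bestScore = R_NegInf;
  if (local) {
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j) {
        const double s = S[(size_t)i * (m + 1) + j];
        if (s > bestScore) { bestScore = s; ei = i; ej = j; }
      }
    if (bestScore <= 0.0) {  // no positive-scoring local alignment
      return List::create(_["score"] = 0.0, _["matches"] = 0,
                          _["columns"] = 0, _["aligned_a"] = "",
                          _["aligned_b"] = "", _["a_start"] = 0,
                          _["a_end"] = 0, _["b_start"] = 0, _["b_end"] = 0);
    }
  } else {
    // best over last row then last column; smallest index wins ties
    for (int j = 1; j <= m; ++j) {
      const double s = S[(size_t)n * (m + 1) + j];
      if (s > bestScore) { bestScore = s; ei = n; ej = j; }
    }
    for (int i = 1; i <= n; ++i) {
      const double s = S[(size_t)i * (m + 1) + m];
      if (s > bestScore) { bestScore = s; ei = i; ej = m; }
    }
  }

  // traceback
  std::string ra, rb;
  ra.reserve((size_t)(n + m));
  rb.reserve((size_t)(n + m));
  int i = ei, j = ej;
  int matches = 0;
  while (i > 0 && j > 0) {
    const unsigned char tb = T[(size_t)i * (m + 1) + j];
    if (tb == 0) break;  // local stop
    if (tb == 1) {
      ra.push_back(a[(size_t)i - 1]);
      rb.push_back(b[(size_t)j - 1]);
      if (a[(size_t)i - 1] == b[(size_t)j - 1]) ++matches;
      --i; --j;
    } else if (tb == 2) {
      ra.push_back(a[(size_t)i - 1]);
      rb.push_back('-');
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[(size_t)j - 1]);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(
      _["score"] = bestScore, _["matches"] = matches,
      _["columns"] = (int)ra.size(), _["aligned_a"] = ra,
      _["aligned_b"] = rb, _["a_start"] = i + 1, _["a_end"] = ei,
      _["b_start"] = j + 1, _["b_end"] = ej);
}
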