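#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap costs.
// Traceback tie-break is fixed: prefer diagonal, then up (gap in b),
// then left (gap in a), evaluated from the terminal cell backwards.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b,
              double match, double mismatch, double gap) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  std::vector<double> F((size_t)(n + 1) * (m + 1));
  const int W = m + 1;
  for (int j = 0; j <= m; ++j) F[j] = gap * j;
  for (int i = 1; i <= n; ++i) {
    F[(size_t)i * W] = gap * i;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double s = (ai == b[j - 1]) ? match : mismatch;
      double best = F[(size_t)(i - 1) * W + (j - 1)] + s;
      const double up = F[(size_t)(i - 1) * W + j] + gap;
      if (up > best) best = up;
      const double left = F[(size_t)i * W + (j - 1)] + gap;
      if (left > best) best = left;
      F[(size_t)i * W + j] = best;
    }
  }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    const double cur = F[(size_t)i * W + j];
    if (i > 0 && j > 0) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (std::abs(cur - (F[(size_t)(i - 1) * W + (j - 1)] + s)) < eps) {
        ra.push_back(a[--i]);
        rb.push_back(b[--j]);
        continue;
      }
    }
    if (i > 0 && std::abs(cur - (F[(size_t)(i - 1) * W + j] + gap)) < eps) {
      ra.push_back(a[--i]);
      rb.push_back('-');
      continue;
    }
    ra.push_back('-');
    rb.push_back(b[--j]);
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int pairs = 0, matches = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] != '-' && rb[k] != '-') {
      ++pairs;
      if (ra[k] == rb[k]) ++matches;
    }
  }
  return List::create(_["score"] = F[(size_t)n * W + m],
                      _["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["pairs"] = pairs, _["matches"] = matches);
}
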