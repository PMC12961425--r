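#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh local alignment with affine gaps and full traceback.
// A gap of length k costs gap_open + k * gap_ext (the first gapped column
// pays both), matching the convention of the common pairwise aligners.
// 'N' never matches, not even another 'N'. Traceback starts at the
// highest-scoring cell (smallest i, then j, on ties) and prefers the
// diagonal over gap states, making the reported alignment deterministic.

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b,
              double match = 1.0, double mismatch = -1.0,
              double gap_open = 2.0, double gap_ext = 1.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double NEG = -1e30;
  const double go = gap_open + gap_ext;  // first gapped column

  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);  // gap in b (up)
  std::vector<double> F((n + 1) * (m + 1), NEG);  // gap in a (left)
  // traceback: tb_h: 0 stop, 1 diag, 2 from E, 3 from F
  std::vector<unsigned char> tb_h((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tb_e((n + 1) * (m + 1), 0);  // 1: opened from H
  std::vector<unsigned char> tb_f((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = i * (m + 1) + j;
      const int ku = (i - 1) * (m + 1) + j;   // up
      const int kl = k - 1;                   // left
      const int kd = ku - 1;                  // diag

      double e_open = H[ku] - go, e_ext = E[ku] - gap_ext;
      if (e_open >= e_ext) { E[k] = e_open; tb_e[k] = 1; }
      else { E[k] = e_ext; tb_e[k] = 0; }

      double f_open = H[kl] - go, f_ext = F[kl] - gap_ext;
      if (f_open >= f_ext) { F[k] = f_open; tb_f[k] = 1; }
      else { F[k] = f_ext; tb_f[k] = 0; }

      char ca = a[i - 1], cb = b[j - 1];
      bool is_match = (ca == cb) && ca != 'N' && ca != 'n';
      double diag = H[kd] + (is_match ? match : mismatch);

      double h = 0.0; unsigned char t = 0;
      if (diag >= h) { h = diag; t = 1; }
      if (E[k] > h) { h = E[k]; t = 2; }
      if (F[k] > h) { h = F[k]; t = 3; }
      H[k] = h; tb_h[k] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int matches = 0, columns = 0;
  int i = bi, j = bj;
  int a_end = bi, b_end = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const int k = i * (m + 1) + j;
    if (state == 0) {
      if (H[k] <= 0.0) break;
      unsigned char t = tb_h[k];
      if (t == 0) break;
      if (t == 1) {
        ++columns;
        bool is_match = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N' &&
          a[i - 1] != 'n';
        if (is_match) ++matches;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++columns;
      if (tb_e[k]) state = 0;
      --i;
    } else {
      ++columns;
      if (tb_f[k]) state = 0;
      --j;
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["matches"] = 0,
                        _["columns"] = 0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER);
  }
  // i, j now index the cell *before* the first aligned column (0-based ends)
  return List::create(
    _["score"] = best, _["matches"] = matches, _["columns"] = columns,
    _["a_start"] = i + 1, _["a_end"] = a_end,    // 1-based inclusive
    _["b_start"] = j + 1, _["b_end"] = b_end);
}
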