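#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Best-lag Pearson correlation between two spectrogram magnitude
// matrices (frequency bins x time frames).  Lag L aligns column t of A
// with column t - L of B; lags are visited 0, +1, -1, +2, -2, ... so the
// incumbent-wins rule breaks ties toward the smallest |lag|.
// Returns (value, best_lag, overlap, flag): flag 0 = ok, 1 = every
// admissible lag had a zero-variance overlap, -1 = no admissible lag.
// [[Rcpp::export]]
NumericVector xcorr_best_lag_cpp(NumericMatrix A, NumericMatrix B,
                                 int max_lag, int min_overlap) {
  const int f = A.nrow();
  const int na = A.ncol(), nb = B.ncol();

  // column sums / sums of squares, with cumulative prefixes
  std::vector<double> csa(na + 1, 0.0), csa2(na + 1, 0.0);
  std::vector<double> csb(nb + 1, 0.0), csb2(nb + 1, 0.0);
  for (int j = 0; j < na; ++j) {
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < f; ++i) { double v = A(i, j); s += v; s2 += v * v; }
    csa[j + 1] = csa[j] + s; csa2[j + 1] = csa2[j] + s2;
  }
  for (int j = 0; j < nb; ++j) {
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < f; ++i) { double v = B(i, j); s += v; s2 += v * v; }
    csb[j + 1] = csb[j] + s; csb2[j + 1] = csb2[j] + s2;
  }

  double best = R_NegInf;
  int best_lag = 0, best_ov = 0;
  bool any_admissible = false;

  for (int k = 0; k <= 2 * max_lag; ++k) {
    int L = (k % 2 == 1) ? (k + 1) / 2 : -(k / 2);  // 0, +1, -1, +2, -2, ...
    int ia0 = std::max(0, L);            // 0-based first overlap column in A
    int ia1 = std::min(na, nb + L) - 1;  // 0-based last
    int ov = ia1 - ia0 + 1;
    if (ov < min_overlap) continue;
    any_admissible = true;

    double n = (double)ov * f;
    double sa = csa[ia1 + 1] - csa[ia0];
    double sa2 = csa2[ia1 + 1] - csa2[ia0];
    int ib0 = ia0 - L;
    double sb = csb[ib0 + ov] - csb[ib0];
    double sb2 = csb2[ib0 + ov] - csb2[ib0];
    double va = sa2 - sa * sa / n;
    double vb = sb2 - sb * sb / n;
    if (va <= 0.0 || vb <= 0.0) continue;

    double sab = 0.0;
    for (int j = 0; j < ov; ++j) {
      const double *pa = &A(0, ia0 + j);
      const double *pb = &B(0, ib0 + j);
      for (int i = 0; i < f; ++i) sab += pa[i] * pb[i];
    }
    double r = (sab - sa * sb / n) / std::sqrt(va * vb);
    if (r > best) { best = r; best_lag = L; best_ov = ov; }
  }

  NumericVector out(4);
  if (!any_admissible) {
    out[0] = NA_REAL; out[1] = NA_REAL; out[2] = NA_REAL; out[3] = -1.0;
  } else if (!R_FINITE(best)) {
    out[0] = NA_REAL; out[1] = NA_REAL; out[2] = NA_REAL; out[3] = 1.0;
  } else {
    out[0] = std::min(1.0, std::max(-1.0, best));
    out[1] = best_lag; out[2] = best_ov; out[3] = 0.0;
  }
  return out;
}
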