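#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batched all-pairs version of the best-lag Pearson search.  Each
// spectrogram's row-wise FFT (time axis, zero-padded to a common power
// of two) and column prefix sums are computed once; each pair then needs
// only one cross-spectrum accumulation and one inverse FFT to obtain the
// correlation numerator at every lag simultaneously:
//   S_AB(L) = sum_f sum_t A[f,t] B[f,t-L] = IFFT( sum_f FA_f * conj(FB_f) ).
// The per-lag mean/variance terms come from prefix sums, so the Pearson
// value at each admissible lag is exact up to FFT rounding (~1e-12).
// Lag order and tie-breaking match xcorr_best_lag_cpp.
// Returns an (nA*nB) x 4 matrix (value, best_lag, overlap, flag) with
// row (i*nB + j) for pair (a_i, b_j); flag as in xcorr_best_lag_cpp.
// [[Rcpp::export]]
NumericMatrix xcorr_table_cpp(List a_list, List b_list, int max_lag,
                              double min_overlap_frac) {
  const int nA = a_list.size(), nB = b_list.size();
  std::vector<arma::mat> amats(nA), bmats(nB);
  int f = -1, max_frames = 0;
  for (int i = 0; i < nA; ++i) {
    amats[i] = as<arma::mat>(a_list[i]);
    if (f < 0) f = amats[i].n_rows;
    if ((int)amats[i].n_rows != f) stop("frequency row mismatch");
    max_frames = std::max(max_frames, (int)amats[i].n_cols);
  }
  for (int j = 0; j < nB; ++j) {
    bmats[j] = as<arma::mat>(b_list[j]);
    if ((int)bmats[j].n_rows != f) stop("frequency row mismatch");
    max_frames = std::max(max_frames, (int)bmats[j].n_cols);
  }
  int N = 4;
  while (N < 2 * max_frames) N <<= 1;

  auto prep = [&](const arma::mat &m, arma::cx_mat &F,
                  std::vector<double> &cs, std::vector<double> &cs2) {
    const int n = m.n_cols;
    arma::mat pad(N, f, arma::fill::zeros);
    pad.rows(0, n - 1) = m.t();          // columns = frequency rows
    F = arma::fft(pad);
    cs.assign(n + 1, 0.0); cs2.assign(n + 1, 0.0);
    for (int j = 0; j < n; ++j) {
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < f; ++i) { double v = m(i, j); s += v; s2 += v * v; }
      cs[j + 1] = cs[j] + s; cs2[j + 1] = cs2[j] + s2;
    }
  };

  std::vector<arma::cx_mat> FA(nA), FB(nB);
  std::vector<std::vector<double> > csa(nA), csa2(nA), csb(nB), csb2(nB);
  for (int i = 0; i < nA; ++i) prep(amats[i], FA[i], csa[i], csa2[i]);
  for (int j = 0; j < nB; ++j) prep(bmats[j], FB[j], csb[j], csb2[j]);

  NumericMatrix out(nA * nB, 4);
  arma::cx_vec cross(N);
  for (int i = 0; i < nA; ++i) {
    const int na = amats[i].n_cols;
    for (int j = 0; j < nB; ++j) {
      const int nb = bmats[j].n_cols;
      cross.zeros();
      for (int c = 0; c < f; ++c) {
        cross += FA[i].col(c) % arma::conj(FB[j].col(c));
      }
      arma::cx_vec cc = arma::ifft(cross);

      const int n_short = std::min(na, nb);
      const int ml = (max_lag < 0) ? n_short : max_lag;
      const int min_overlap =
        std::max(1, (int)std::ceil(min_overlap_frac * n_short));

      double best = R_NegInf;
      int best_lag = 0, best_ov = 0;
      bool any_admissible = false;
      for (int k = 0; k <= 2 * ml; ++k) {
        int L = (k % 2 == 1) ? (k + 1) / 2 : -(k / 2);
        if (L >= na || -L >= nb) continue;
        int ia0 = std::max(0, L);
        int ia1 = std::min(na, nb + L) - 1;
        int ov = ia1 - ia0 + 1;
        if (ov < min_overlap) continue;
        any_admissible = true;
        double n = (double)ov * f;
        double sa = csa[i][ia1 + 1] - csa[i][ia0];
        double sa2 = csa2[i][ia1 + 1] - csa2[i][ia0];
        int ib0 = ia0 - L;
        double sb = csb[j][ib0 + ov] - csb[j][ib0];
        double sb2 = csb2[j][ib0 + ov] - csb2[j][ib0];
        double va = sa2 - sa * sa / n;
        double vb = sb2 - sb * sb / n;
        if (va <= 0.0 || vb <= 0.0) continue;
        int m = (L >= 0) ? L : N + L;
        double sab = cc(m).real();
        double r = (sab - sa * sb / n) / std::sqrt(va * vb);
        if (r > best) { best = r; best_lag = L; best_ov = ov; }
      }
      int row = i * nB + j;
      if (!any_admissible) {
        out(row, 0) = NA_REAL; out(row, 1) = NA_REAL;
        out(row, 2) = NA_REAL; out(row, 3) = -1.0;
      } else if (!R_FINITE(best)) {
        out(row, 0) = NA_REAL; out(row, 1) = NA_REAL;
        out(row, 2) = NA_REAL; out(row, 3) = 1.0;
      } else {
        out(row, 0) = std::min(1.0, std::max(-1.0, best));
        out(row, 1) = best_lag; out(row, 2) = best_ov; out(row, 3) = 0.0;
      }
    }
  }
  return out;
}
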