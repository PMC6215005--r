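// Numerical core: FFT-based Morlet convolution, sliding-window artifact
// scans, and an SMO-trained C-SVC with RBF kernel. Everything here is
// deterministic; all randomness stays on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::uword next_pow2(arma::uword n) {
  arma::uword p = 1;
  while (p < n) p <<= 1;
  return p;
}

//' @noRd
// [[Rcpp::export(name = "cwt_power_core")]]
arma::cube cwt_power_core(const arma::mat& x, const List& kernels,
                          int n_trials, int n_channels, double dt) {
  // x: n_samples x (n_trials * n_channels), trial index varying fastest
  // within each channel. Returns mean-over-trials power,
  // n_samples x n_channels x n_freqs. Kernel tails that can never overlap
  // the signal are clipped, and frequencies sharing an FFT size reuse one
  // forward transform (matrix-batched FFTs).
  const arma::uword n = x.n_rows;
  const arma::uword ncol = x.n_cols;
  const int n_freq = kernels.size();
  const double dt2 = dt * dt;

  std::vector<arma::cx_vec> ker(n_freq);
  std::vector<arma::uword> nfft_of(n_freq);
  for (int f = 0; f < n_freq; ++f) {
    arma::cx_vec k = as<arma::cx_vec>(kernels[f]);
    arma::uword L = (k.n_elem - 1) / 2;
    if (L > n - 1) {                 // clip tails beyond any overlap
      arma::uword Lc = n - 1;
      k = k.subvec(L - Lc, L + Lc);
      L = Lc;
    }
    ker[f] = k;
    nfft_of[f] = next_pow2(n + k.n_elem - 1);
  }

  arma::cube out(n, n_channels, n_freq, arma::fill::zeros);
  arma::cx_mat Xf;
  arma::uword cur_nfft = 0;
  // process in order of FFT size so the forward transform is shared
  std::vector<int> order(n_freq);
  for (int f = 0; f < n_freq; ++f) order[f] = f;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return nfft_of[a] < nfft_of[b];
  });
  for (int oi = 0; oi < n_freq; ++oi) {
    const int f = order[oi];
    const arma::uword nfft = nfft_of[f];
    if (nfft != cur_nfft) {
      arma::cx_mat X(nfft, ncol, arma::fill::zeros);
      X.rows(0, n - 1) = arma::conv_to<arma::cx_mat>::from(x);
      Xf = arma::fft(X);
      cur_nfft = nfft;
    }
    const arma::cx_vec& k = ker[f];
    const arma::uword m = k.n_elem;      // odd, centre at (m-1)/2
    const arma::uword L = (m - 1) / 2;
    // cross-correlation with k == convolution with conj(reverse(k))
    arma::cx_vec g(nfft, arma::fill::zeros);
    for (arma::uword j = 0; j < m; ++j) g(j) = std::conj(k(m - 1 - j));
    arma::cx_vec Gf = arma::fft(g);
    arma::cx_mat conv = arma::ifft(arma::cx_mat(Xf.each_col() % Gf));
    for (arma::uword c = 0; c < ncol; ++c) {
      const arma::uword ch = c / (arma::uword)n_trials;
      const std::complex<double>* col = conv.colptr(c);
      double* o = out.slice_colptr(f, ch);
      for (arma::uword t = 0; t < n; ++t)
        o[t] += std::norm(col[t + L]) * dt2;
    }
  }
  out /= (double)n_trials;
  return out;
}

//' @noRd
// [[Rcpp::export(name = "artifact_scan_core")]]
IntegerMatrix artifact_scan_core(const arma::mat& x, int w_diff, int w_act,
                                 double thr_diff, double thr_act) {
  // x: n_samples x n_signals. Column flagged 1 if any w_diff-sample window
  // has range > thr_diff; flagged (col 2) if any w_act window has
  // range < thr_act. Dense scan, step 1 sample.
  const int n = x.n_rows;
  const int ns = x.n_cols;
  IntegerMatrix flags(ns, 2);
  for (int c = 0; c < ns; ++c) {
    const double* col = x.colptr(c);
    bool hit_diff = false, hit_act = false;
    for (int s = 0; s + w_diff <= n && !hit_diff; ++s) {
      double mn = col[s], mx = col[s];
      for (int j = 1; j < w_diff; ++j) {
        double v = col[s + j];
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > thr_diff) hit_diff = true;
    }
    for (int s = 0; s + w_act <= n && !hit_act; ++s) {
      double mn = col[s], mx = col[s];
      for (int j = 1; j < w_act; ++j) {
        double v = col[s + j];
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn < thr_act) hit_act = true;
    }
    flags(c, 0) = hit_diff ? 1 : 0;
    flags(c, 1) = hit_act ? 1 : 0;
  }
  return flags;
}

// ---- RBF C-SVC via SMO ------------------------------------------------
// Dual: min 1/2 a'Qa - e'a, y'a = 0, 0 <= a <= C, Q_ij = y_i y_j K_ij.
// First-order maximal-violating-pair selection (Keerthi); stop when the
// KKT gap drops below eps.

static arma::mat rbf_kernel(const arma::mat& A, const arma::mat& B,
                            double sigma) {
  arma::vec an = arma::sum(arma::square(A), 1);
  arma::vec bn = arma::sum(arma::square(B), 1);
  arma::mat d2 = arma::repmat(an, 1, B.n_rows) +
                 arma::repmat(bn.t(), A.n_rows, 1) - 2.0 * A * B.t();
  d2.elem(arma::find(d2 < 0)).zeros();
  return arma::exp(-d2 / (2.0 * sigma * sigma));
}

//' @noRd
// [[Rcpp::export(name = "svm_train_core")]]
List svm_train_core(const arma::mat& X, const arma::vec& y, double cost,
                    double sigma, double eps = 1e-3, int max_iter = 200000) {
  const int n = X.n_rows;
  arma::mat K = rbf_kernel(X, X, sigma);
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec F(n, arma::fill::zeros);   // F_i = sum_j alpha_j y_j K_ij
  int iter = 0;
  double b = 0.0;
  while (iter++ < max_iter) {
    // select i in I_up maximizing -(F_i - y_i), j in I_low minimizing it
    int i = -1, j = -1;
    double up = -arma::datum::inf, lo = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      double E = F(t) - y(t);
      bool in_up = (y(t) > 0 && alpha(t) < cost) ||
                   (y(t) < 0 && alpha(t) > 0);
      bool in_lo = (y(t) > 0 && alpha(t) > 0) ||
                   (y(t) < 0 && alpha(t) < cost);
      if (in_up && -E > up) { up = -E; i = t; }
      if (in_lo && -E < lo) { lo = -E; j = t; }
    }
    if (i >= 0 && j >= 0) b = (up + lo) / 2.0;
    if (i < 0 || j < 0 || up - lo < eps) break;
    double Ei = F(i) - y(i), Ej = F(j) - y(j);
    double s = y(i) * y(j);
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha(j) - alpha(i));
      H = std::min(cost, cost + alpha(j) - alpha(i));
    } else {
      L = std::max(0.0, alpha(i) + alpha(j) - cost);
      H = std::min(cost, alpha(i) + alpha(j));
    }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    double aj = alpha(j) + y(j) * (Ei - Ej) / eta;
    if (aj < L) aj = L;
    if (aj > H) aj = H;
    double ai = alpha(i) + s * (alpha(j) - aj);
    double dai = ai - alpha(i), daj = aj - alpha(j);
    if (std::abs(daj) < 1e-14 && std::abs(dai) < 1e-14) {
      b = (up + lo) / 2.0;
      break;
    }
    alpha(i) = ai;
    alpha(j) = aj;
    F += dai * y(i) * K.col(i) + daj * y(j) * K.col(j);
  }
  // decision f(x) = sum alpha_i y_i K(x_i, x) + b
  return List::create(_["alpha"] = alpha, _["b"] = b, _["iter"] = iter);
}

//' @noRd
// [[Rcpp::export(name = "svm_decision_core")]]
arma::vec svm_decision_core(const arma::mat& Xtrain, const arma::vec& y,
                            const arma::vec& alpha, double b,
                            const arma::mat& Xtest, double sigma) {
  arma::uvec sv = arma::find(alpha > 1e-12);
  if (sv.n_elem == 0) return arma::vec(Xtest.n_rows, arma::fill::value(b));
  arma::mat Kt = rbf_kernel(Xtest, Xtrain.rows(sv), sigma);
  return Kt * (alpha(sv) % y(sv)) + b;
}
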