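#include <Rcpp.h>
using namespace Rcpp;

// Whittaker smoother with asymmetric weights (AsLS baseline estimation).
//
// Each iteration solves (W + lambda * D2' D2) z = W y, where D2 is the
// second-difference operator. The system matrix is pentadiagonal and SPD,
// so a banded Cholesky factorisation gives an O(n) solve. Weights are
// updated asymmetrically: points above the current baseline (peaks) get
// weight p, points below get 1 - p.

static void banded_chol_solve(const std::vector<double> &a0,
                              const std::vector<double> &a1,
                              const std::vector<double> &a2,
                              const std::vector<double> &b,
                              std::vector<double> &z) {
  const int n = static_cast<int>(a0.size());
  std::vector<double> l0(n), l1(n > 1 ? n - 1 : 0), l2(n > 2 ? n - 2 : 0);
  for (int i = 0; i < n; ++i) {
    double s = a0[i];
    if (i >= 1) s -= l1[i - 1] * l1[i - 1];
    if (i >= 2) s -= l2[i - 2] * l2[i - 2];
    l0[i] = std::sqrt(s);
    if (i + 1 < n) {
      double s1 = a1[i];
      if (i >= 1) s1 -= l2[i - 1] * l1[i - 1];
      l1[i] = s1 / l0[i];
    }
    if (i + 2 < n) l2[i] = a2[i] / l0[i];
  }
  // forward: L c = b (reuse z as c)
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    if (i >= 1) s -= l1[i - 1] * z[i - 1];
    if (i >= 2) s -= l2[i - 2] * z[i - 2];
    z[i] = s / l0[i];
  }
  // backward: L' z = c
  for (int i = n - 1; i >= 0; --i) {
    double s = z[i];
    if (i + 1 < n) s -= l1[i] * z[i + 1];
    if (i + 2 < n) s -= l2[i] * z[i + 2];
    z[i] = s / l0[i];
  }
}

// [[Rcpp::export]]
NumericMatrix als_baseline_cpp(NumericMatrix Y, double lambda, double p,
                               int maxit) {
  const int nspec = Y.nrow(), n = Y.ncol();
  if (n < 3) stop("spectra must have at least 3 channels");
  NumericMatrix Z(nspec, n);

  // bands of lambda * D2'D2 for an n-point second-difference penalty
  std::vector<double> p0(n, 6.0 * lambda), p1(n - 1, -4.0 * lambda),
      p2(n - 2, lambda);
  p0[0] = p0[n - 1] = 1.0 * lambda;
  if (n > 3) {
    p0[1] = p0[n - 2] = 5.0 * lambda;
  } else {
    p0[1] = 4.0 * lambda;  // n == 3: single interior point
  }
  p1[0] = p1[n - 2] = -2.0 * lambda;

  std::vector<double> a0(n), b(n), z(n), w(n), y(n);
  for (int s = 0; s < nspec; ++s) {
    for (int j = 0; j < n; ++j) {
      y[j] = Y(s, j);
      w[j] = 1.0;
    }
    for (int it = 0; it < maxit; ++it) {
      for (int j = 0; j < n; ++j) {
        a0[j] = p0[j] + w[j];
        b[j] = w[j] * y[j];
      }
      banded_chol_solve(a0, p1, p2, b, z);
      bool changed = false;
      for (int j = 0; j < n; ++j) {
        double wn = (y[j] > z[j]) ? p : 1.0 - p;
        if (wn != w[j]) changed = true;
        w[j] = wn;
      }
      if (!changed) break;
    }
    for (int j = 0; j < n; ++j) Z(s, j) = z[j];
  }
  return Z;
}
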