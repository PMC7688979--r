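#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Soft-margin kernel SVM, dual problem solved by SMO in the LIBSVM
// formulation: minimize 0.5 a'Qa - e'a subject to 0 <= a_i <= C, y'a = 0,
// with Q_ij = y_i y_j K_ij. Working-set selection is second order (the
// maximal-violating i, then the j giving the largest guaranteed decrease),
// and the stopping criterion is the maximal KKT violation
// m(a) - M(a) <= tol.

// [[Rcpp::export]]
List svm_smo_cpp(NumericMatrix K, NumericVector y, double C, double tol,
                 int max_iter) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = Qa - e (alpha = 0)
  const double TAU = 1e-12;
  int iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    // i: maximal violation among I_up
    int i = -1;
    double Gmax = -HUGE_VAL, Gmax2 = -HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      if (up && -y[t] * G[t] >= Gmax) { Gmax = -y[t] * G[t]; i = t; }
    }
    // j: second-order selection among I_low
    int j = -1;
    double obj_min = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!low) continue;
      double yG = y[t] * G[t];
      if (yG > Gmax2) Gmax2 = yG;
      double grad_diff = Gmax + yG;
      if (grad_diff > 0) {
        double quad = K(i, i) + K(t, t) - 2.0 * y[i] * y[t] * K(i, t);
        if (quad <= 0) quad = TAU;
        double obj = -(grad_diff * grad_diff) / quad;
        if (obj <= obj_min) { obj_min = obj; j = t; }
      }
    }
    if (i < 0 || j < 0 || Gmax + Gmax2 < tol) { converged = true; break; }

    // LIBSVM two-variable analytic solve (alpha-space), then clipping
    double Qij = y[i] * y[j] * K(i, j);
    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * Qij; // Q_ij = -K_ij here
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * Qij; // Q_ij = +K_ij here
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    ++iter;
  }

  // offset rho: decision value f(x) = sum_t alpha_t y_t K(x_t, x) - rho
  double sum_free = 0.0, ub = HUGE_VAL, lb = -HUGE_VAL;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] <= 0.0) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] >= C) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nr_free;
      sum_free += yG;
    }
  }
  double rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;

  return List::create(Named("alpha") = NumericVector(alpha.begin(), alpha.end()),
                      Named("rho") = rho,
                      Named("iterations") = iter,
                      Named("converged") = converged);
}
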