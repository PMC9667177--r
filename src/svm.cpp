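// Binary C-SVC dual solver (SMO with maximal-violating-pair working set)
// on a precomputed Gram matrix.  Small-n problems (tens to a few hundred
// trials) fitted tens of thousands of times inside permutation loops, so the
// solver works entirely in the dual: callers hand in K once and reuse it
// across label shuffles and folds.
//
// minimise  1/2 a' Q a - e' a ,  Q_ij = y_i y_j K_ij
// s.t.      0 <= a_i <= C,  y' a = 0
//
// Decision value for a new point x: f(x) = sum_i a_i y_i K(x, x_i) + b.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".svc_fit_cpp")]]
Rcpp::List svc_fit_cpp(const arma::mat &K, const arma::vec &y, double C,
                       double eps = 1e-3, int max_iter = 200000) {
  const unsigned int n = K.n_rows;
  vec alpha(n, fill::zeros);
  vec G(n, fill::value(-1.0));  // gradient of the dual objective
  const double tau = 1e-12;

  int it = 0;
  double b = 0.0;
  for (; it < max_iter; ++it) {
    // maximal violating pair
    int i = -1, j = -1;
    double Fmax = -datum::inf, Fmin = datum::inf;
    for (unsigned int t = 0; t < n; ++t) {
      const double F = -y(t) * G(t);
      const bool in_up = (y(t) > 0 && alpha(t) < C) || (y(t) < 0 && alpha(t) > 0);
      const bool in_low = (y(t) > 0 && alpha(t) > 0) || (y(t) < 0 && alpha(t) < C);
      if (in_up && F > Fmax) { Fmax = F; i = t; }
      if (in_low && F < Fmin) { Fmin = F; j = t; }
    }
    if (i < 0 || j < 0 || Fmax - Fmin < eps) { b = (Fmax + Fmin) / 2.0; break; }

    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = tau;
    double step = (Fmax - Fmin) / eta;

    // box constraints along the feasible direction d_i = y_i, d_j = -y_j
    const double cap_i = (y(i) > 0) ? (C - alpha(i)) : alpha(i);
    const double cap_j = (y(j) > 0) ? alpha(j) : (C - alpha(j));
    step = std::min(step, std::min(cap_i, cap_j));

    alpha(i) += y(i) * step;
    alpha(j) -= y(j) * step;
    for (unsigned int t = 0; t < n; ++t)
      G(t) += step * y(t) * (K(t, i) - K(t, j));
  }

  // bias from free support vectors when available
  uvec free_sv = find(alpha > 1e-8 * C && alpha < C * (1 - 1e-8));
  if (free_sv.n_elem > 0) {
    double s = 0.0;
    for (unsigned int m = 0; m < free_sv.n_elem; ++m) {
      const unsigned int t = free_sv(m);
      s += -y(t) * G(t);
    }
    b = s / free_sv.n_elem;
  }

  return Rcpp::List::create(Rcpp::Named("alpha_y") = alpha % y,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = it < max_iter);
}
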