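#include <Rcpp.h>

// Exponential convolution on a uniform grid: the O(n) recursion
//   y[i] = a * y[i-1] + dt/2 * (x[i] + a * x[i-1]),  a = exp(-k2s * dt)
// equal to the trapezoid discretisation of int_0^t exp(-k2s (t-s)) x(s) ds.
// This sits in the innermost loop of the compartment fit, hence C++.
// [[Rcpp::export]]
Rcpp::NumericVector exp_conv_cpp(Rcpp::NumericVector x, double dt, double k2s) {
  const int n = x.size();
  Rcpp::NumericVector y(n);
  const double a = std::exp(-k2s * dt);
  const double h = dt / 2.0;
  double acc = 0.0;
  y[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    acc = a * acc + h * (x[i] + a * x[i - 1]);
    y[i] = acc;
  }
  return y;
}
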