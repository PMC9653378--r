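#include <Rcpp.h>
using namespace Rcpp;

// Fused Adam step with coupled L2 weight decay: one pass over the
// parameter block instead of a dozen vectorized temporaries in R. Returns
// fresh vectors (no in-place mutation of R objects).
// [[Rcpp::export(rng = false)]]
List adam_update(NumericVector p, NumericVector g, NumericVector m,
                 NumericVector v, double lr, double wd, double b1,
                 double b2, double c1, double c2, double eps) {
  R_xlen_t n = p.size();
  NumericVector m2(n), v2(n), p2(n);
  double ic2 = 1.0 / std::sqrt(c2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i] + wd * p[i];
    double mi = b1 * m[i] + (1.0 - b1) * gi;
    double vi = b2 * v[i] + (1.0 - b2) * gi * gi;
    m2[i] = mi;
    v2[i] = vi;
    p2[i] = p[i] - lr * (mi / c1) / (std::sqrt(vi) * ic2 + eps);
  }
  if (!Rf_isNull(p.attr("dim"))) {
    p2.attr("dim") = p.attr("dim");
    m2.attr("dim") = p.attr("dim");
    v2.attr("dim") = p.attr("dim");
  }
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}

// Column-broadcast helpers replacing sweep() in the network hot path:
// each is a single fused pass in column-major order.

// [[Rcpp::export(rng = false)]]
NumericMatrix col_add(NumericMatrix x, NumericVector v) {
  int m = x.nrow(), k = x.ncol();
  NumericMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    double b = v[j];
    for (int i = 0; i < m; ++i) out(i, j) = x(i, j) + b;
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix col_mul(NumericMatrix x, NumericVector v) {
  int m = x.nrow(), k = x.ncol();
  NumericMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    double b = v[j];
    for (int i = 0; i < m; ++i) out(i, j) = x(i, j) * b;
  }
  return out;
}

// out[i, j] = (x[i, j] - a[j]) * b[j] + c[j]
// [[Rcpp::export(rng = false)]]
NumericMatrix col_affine(NumericMatrix x, NumericVector a, NumericVector b,
                         NumericVector c) {
  int m = x.nrow(), k = x.ncol();
  NumericMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    double aj = a[j], bj = b[j], cj = c[j];
    for (int i = 0; i < m; ++i) out(i, j) = (x(i, j) - aj) * bj + cj;
  }
  return out;
}

// Batch-norm training forward: per-column standardization plus scale/shift,
// returning the normalized activations and the batch statistics.
// [[Rcpp::export(rng = false)]]
List bn_train_forward(NumericMatrix z, NumericVector g, NumericVector h,
                      double eps) {
  int m = z.nrow(), k = z.ncol();
  NumericMatrix xhat(m, k), out(m, k);
  NumericVector mu(k), va(k), ivar(k);
  for (int j = 0; j < k; ++j) {
    double s = 0;
    for (int i = 0; i < m; ++i) s += z(i, j);
    double mj = s / m;
    double q = 0;
    for (int i = 0; i < m; ++i) {
      double d = z(i, j) - mj;
      q += d * d;
    }
    double vj = q / m;
    double iv = 1.0 / std::sqrt(vj + eps);
    double gj = g[j], hj = h[j];
    for (int i = 0; i < m; ++i) {
      double xh = (z(i, j) - mj) * iv;
      xhat(i, j) = xh;
      out(i, j) = gj * xh + hj;
    }
    mu[j] = mj; va[j] = vj; ivar[j] = iv;
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["va"] = va, _["ivar"] = ivar);
}

// Batch-norm input gradient (training statistics):
// dx = ivar/m * (m * dxhat - sum(dxhat) - xhat * sum(dxhat * xhat))
// [[Rcpp::export(rng = false)]]
NumericMatrix bn_backward_dx(NumericMatrix dxhat, NumericMatrix xhat,
                             NumericVector s1, NumericVector s2,
                             NumericVector ivar) {
  int m = dxhat.nrow(), k = dxhat.ncol();
  NumericMatrix out(m, k);
  for (int j = 0; j < k; ++j) {
    double a = ivar[j] / m, b = s1[j], c = s2[j];
    for (int i = 0; i < m; ++i)
      out(i, j) = a * (m * dxhat(i, j) - b - xhat(i, j) * c);
  }
  return out;
}
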