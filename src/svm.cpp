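#include <Rcpp.h>
using namespace Rcpp;

// SMO solver for the C-SVC dual with a precomputed kernel matrix:
//   min 0.5 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij.
// Working-set selection is the maximal violating pair; this is the classic
// libsvm-style first-order scheme, adequate because the kernel is held in
// memory. `idx` (0-based) selects the training rows/columns out of the full
// kernel, so leave-one-subject-out folds can share one kernel matrix without
// copying submatrices.
// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix K, IntegerVector idx, NumericVector y,
                   double cost, double eps, int max_iter) {
  const int n = idx.size();
  if (y.size() != n) stop("y and idx length mismatch");
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int it = 0;
  for (; it < max_iter; ++it) {
    // i: argmax -y_t G_t over I_up; j: argmin -y_t G_t over I_low
    int i = -1, j = -1;
    double gmax = -INFINITY, gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      if ((y[t] > 0 && alpha[t] < cost) || (y[t] < 0 && alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v > gmax) { gmax = v; i = t; }
      }
      if ((y[t] < 0 && alpha[t] < cost) || (y[t] > 0 && alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v < gmin) { gmin = v; j = t; }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    double Kii = K(idx[i], idx[i]), Kjj = K(idx[j], idx[j]),
           Kij = K(idx[i], idx[j]);
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = TAU;
    double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > cost) { alpha[i] = cost; alpha[j] = cost - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > cost) { alpha[j] = cost; alpha[i] = cost + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > cost) {
        if (alpha[i] > cost) { alpha[i] = cost; alpha[j] = sum - cost; }
        if (alpha[j] > cost) { alpha[j] = cost; alpha[i] = sum - cost; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      double Kti = K(idx[t], idx[i]), Ktj = K(idx[t], idx[j]);
      G[t] += y[t] * (y[i] * Kti * dai + y[j] * Ktj * daj);
    }
  }

  // rho from the KKT conditions: y_t G_t = rho on free support vectors.
  double rho;
  int nfree = 0; double sumfree = 0.0;
  double ub = INFINITY, lb = -INFINITY;
  for (int t = 0; t < n; ++t) {
    double yg = y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < cost) { ++nfree; sumfree += yg; }
    if ((y[t] > 0 && alpha[t] < cost) || (y[t] < 0 && alpha[t] > 0))
      lb = std::max(lb, yg);
    if ((y[t] < 0 && alpha[t] < cost) || (y[t] > 0 && alpha[t] > 0))
      ub = std::min(ub, yg);
  }
  rho = nfree > 0 ? sumfree / nfree : (ub + lb) / 2.0;

  NumericVector coefs(n);
  for (int t = 0; t < n; ++t) coefs[t] = alpha[t] * y[t];
  return List::create(_["coef"] = coefs, _["rho"] = rho,
                      _["iterations"] = it,
                      _["converged"] = it < max_iter);
}

// Decision values f(x) = sum_i coef_i K(x_i, x) - rho for test rows taken
// from the same precomputed kernel (columns idx_train, rows idx_test).
// [[Rcpp::export]]
NumericVector svm_decision_precomp_cpp(NumericMatrix K, IntegerVector idx_test,
                                       IntegerVector idx_train,
                                       NumericVector coef, double rho) {
  const int m = idx_test.size(), n = idx_train.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      if (coef[i] != 0.0) s += coef[i] * K(idx_test[t], idx_train[i]);
    out[t] = s - rho;
  }
  return out;
}

// In-place kernel finisher: given the cross-product matrix CP = X Y', turn
// it into exp(-gamma * max(rsx_i + rsy_j - 2 CP_ij, 0)) in a single pass
// (the elementwise ops dominate kernel construction time in R).
// [[Rcpp::export]]
NumericMatrix rbf_finish_cpp(NumericMatrix cp, NumericVector rsx,
                             NumericVector rsy, double gamma) {
  const int n = cp.nrow(), m = cp.ncol();
  for (int j = 0; j < m; ++j) {
    double rj = rsy[j];
    double *col = &cp(0, j);
    for (int i = 0; i < n; ++i) {
      double d2 = rsx[i] + rj - 2.0 * col[i];
      col[i] = std::exp(-gamma * (d2 > 0 ? d2 : 0));
    }
  }
  return cp;
}
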