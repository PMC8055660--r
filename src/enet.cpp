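#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent on precomputed second moments of centered data:
// G = X'X/n, c = X'y/n, minimizing
//   (1/2n)||y - X b||^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2).
// Convergence: max_j (delta beta_j)^2 G_jj < tol (glmnet-style scaled
// criterion, robust to near-degenerate directions when p >= n).
// [[Rcpp::export(name = ".enet_cd")]]
List enet_cd(NumericMatrix G, NumericVector c, double alpha, double lambda,
             NumericVector beta_init, double tol, int max_iter) {
  const int p = c.size();
  NumericVector beta = clone(beta_init);
  std::vector<double> denom(p);
  for (int j = 0; j < p; j++) denom[j] = G(j, j) + lambda * (1.0 - alpha);
  const double thr = lambda * alpha;
  int it = 0;
  bool converged = false;
  while (it < max_iter) {
    it++;
    double dmax = 0.0;
    for (int j = 0; j < p; j++) {
      if (denom[j] <= 0.0) { beta[j] = 0.0; continue; }
      double rho = c[j] + G(j, j) * beta[j];
      for (int k = 0; k < p; k++) rho -= G(j, k) * beta[k];
      double nb = 0.0;
      if (rho > thr) nb = (rho - thr) / denom[j];
      else if (rho < -thr) nb = (rho + thr) / denom[j];
      double d = (nb - beta[j]) * (nb - beta[j]) * G(j, j);
      if (d > dmax) dmax = d;
      beta[j] = nb;
    }
    if (dmax < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["iterations"] = it,
                      _["converged"] = converged);
}
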