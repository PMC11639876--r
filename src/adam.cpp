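#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place adam update over all layer weight matrices and bias
// vectors. The caller guarantees the parameter/moment objects are not
// shared with any other R binding (the training loop deep-copies when it
// snapshots a checkpoint).
static void update_block(SEXP par, SEXP m, SEXP v, SEXP g,
                         double lr, double beta1, double beta2, double eps,
                         double c1, double c2) {
  R_xlen_t n = Rf_xlength(par);
  double *pp = REAL(par), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
}

// [[Rcpp::export(name = ".adam_update_inplace")]]
void adam_update_inplace(List W, List b, List mW, List vW, List mb, List vb,
                         List dW, List db, double lr, double beta1,
                         double beta2, double eps, int t) {
  double c1 = 1.0 - std::pow(beta1, t);
  double c2 = 1.0 - std::pow(beta2, t);
  int L = W.size();
  for (int l = 0; l < L; ++l) {
    update_block(W[l], mW[l], vW[l], dW[l], lr, beta1, beta2, eps, c1, c2);
    update_block(b[l], mb[l], vb[l], db[l], lr, beta1, beta2, eps, c1, c2);
  }
}
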