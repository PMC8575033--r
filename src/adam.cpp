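#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update over a nested parameter list. The parameter, gradient
// and moment containers share one structure whose leaves are numeric vectors
// or matrices; updating in place avoids reallocating ~1e6 doubles per
// minibatch, which dominates the R-level implementation.
static void walk(SEXP p, SEXP g, SEXP m, SEXP v,
                 double lr, double bc1, double bc2,
                 double b1, double b2, double eps) {
  if (TYPEOF(p) == VECSXP) {
    R_xlen_t n = Rf_xlength(p);
    for (R_xlen_t i = 0; i < n; ++i) {
      walk(VECTOR_ELT(p, i), VECTOR_ELT(g, i), VECTOR_ELT(m, i),
           VECTOR_ELT(v, i), lr, bc1, bc2, b1, b2, eps);
    }
  } else if (TYPEOF(p) == REALSXP) {
    double *pp = REAL(p), *pg = REAL(g), *pm = REAL(m), *pv = REAL(v);
    R_xlen_t n = Rf_xlength(p);
    for (R_xlen_t i = 0; i < n; ++i) {
      pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
      pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
      pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
    }
  } else {
    stop("unsupported parameter leaf type");
  }
}

// [[Rcpp::export(rng = false)]]
void adam_update_(List params, List grads, List mstate, List vstate,
                  double lr, double step, double b1, double b2, double eps) {
  walk(params, grads, mstate, vstate, lr,
       1.0 - std::pow(b1, step), 1.0 - std::pow(b2, step), b1, b2, eps);
}
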