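#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of a two-stage session under the hybrid agent.
//
// Parameter order: alpha1, alpha2, beta1, beta2, lambda, pi, omega.
// States coded 0 = B, 1 = C; actions 0/1. `ok[t]` marks completed trials;
// trials with ok[t] == false contribute no likelihood terms and no updates
// (the previous first-stage action is retained across them).
//
// All right-hand values in the update rules are the pre-update (trial-t)
// values: the stage-1 correction uses the stage-2 value before its own
// within-trial update, and the eligibility term carries alpha1 * lambda.

static inline double nll_one(const double* par,
                             const int* a1, const int* s2, const int* a2,
                             const int* r, const int* ok, int n,
                             double high_tran, int dest0, double q_init) {
  const double alpha1 = par[0], alpha2 = par[1];
  const double beta1 = par[2], beta2 = par[3];
  const double lambda = par[4], pi = par[5], omega = par[6];
  const double low_tran = 1.0 - high_tran;
  const int dest1 = 1 - dest0;

  double q1[2] = {q_init, q_init};
  double q2[2][2] = {{q_init, q_init}, {q_init, q_init}};
  int prev = -1;
  double nll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (!ok[t]) continue;

    double maxB = q2[0][0] > q2[0][1] ? q2[0][0] : q2[0][1];
    double maxC = q2[1][0] > q2[1][1] ? q2[1][0] : q2[1][1];
    double maxdest[2] = {maxB, maxC};
    double qmb0 = high_tran * maxdest[dest0] + low_tran * maxdest[1 - dest0];
    double qmb1 = high_tran * maxdest[dest1] + low_tran * maxdest[1 - dest1];

    double x0 = beta1 * (omega * qmb0 + (1.0 - omega) * q1[0] + pi * (prev == 0));
    double x1 = beta1 * (omega * qmb1 + (1.0 - omega) * q1[1] + pi * (prev == 1));
    // -log P(chosen) via the stable two-option logistic form
    double d1 = (a1[t] == 0) ? (x1 - x0) : (x0 - x1);
    nll += (d1 > 0) ? d1 + log1p(exp(-d1)) : log1p(exp(d1));

    int s = s2[t];
    double y0 = beta2 * q2[s][0], y1 = beta2 * q2[s][1];
    double d2 = (a2[t] == 0) ? (y1 - y0) : (y0 - y1);
    nll += (d2 > 0) ? d2 + log1p(exp(-d2)) : log1p(exp(d2));

    double q2_old = q2[s][a2[t]];
    double rpe2 = (double)r[t] - q2_old;
    q2[s][a2[t]] = q2_old + alpha2 * rpe2;
    q1[a1[t]] += alpha1 * (q2_old - q1[a1[t]]) + alpha1 * lambda * rpe2;
    prev = a1[t];
  }
  return nll;
}

// [[Rcpp::export]]
double nll_hybrid_cpp(NumericVector par, IntegerVector a1, IntegerVector s2,
                      IntegerVector a2, IntegerVector r, IntegerVector ok,
                      double high_tran, int dest0, double q_init) {
  if (par.size() != 7) stop("`par` must have length 7");
  return nll_one(REAL(par), INTEGER(a1), INTEGER(s2), INTEGER(a2),
                 INTEGER(r), INTEGER(ok), a1.size(), high_tran, dest0, q_init);
}

// [[Rcpp::export]]
NumericVector nll_hybrid_grid_cpp(NumericMatrix par_mat, IntegerVector a1,
                                  IntegerVector s2, IntegerVector a2,
                                  IntegerVector r, IntegerVector ok,
                                  double high_tran, int dest0, double q_init) {
  if (par_mat.ncol() != 7) stop("`par_mat` must have 7 columns");
  int m = par_mat.nrow();
  NumericVector out(m);
  double par[7];
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < 7; ++j) par[j] = par_mat(i, j);
    out[i] = nll_one(par, INTEGER(a1), INTEGER(s2), INTEGER(a2), INTEGER(r),
                     INTEGER(ok), a1.size(), high_tran, dest0, q_init);
  }
  return out;
}
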