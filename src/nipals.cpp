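#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Univariate-response NIPALS. With a single response the weight/score/loading
// updates need no inner iteration: w = X'y (normalized), t = Xw, p = X't/t't,
// q = y't/t't, then deflation of X and y. Extraction stops early if the
// deflated cross-covariance or score norm collapses (rank exhausted).
// Returns the number of components actually extracted.
static int nipals_path(mat Xc, vec yc, int a_max, mat& W, mat& P, vec& q) {
  const double x0 = accu(square(Xc)) + 1e-300;
  int a = 0;
  for (; a < a_max; ++a) {
    vec w = Xc.t() * yc;
    double wn = norm(w);
    if (!std::isfinite(wn) || wn == 0.0) break;
    w /= wn;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt <= 1e-12 * x0) break;
    vec p = Xc.t() * t / tt;
    double qa = dot(yc, t) / tt;
    W.col(a) = w;
    P.col(a) = p;
    q(a) = qa;
    Xc -= t * p.t();
    yc -= qa * t;
  }
  return a;
}

// Leave-one-out PRESS profile for component counts 1..a_max (capped at
// min(n-2, bands)). Each fold is an honest refit on the n-1 remaining
// samples; the held-out prediction is accumulated component by component via
// the standard NIPALS test-deflation recursion. Responses are centered per
// fold; X is column-centered per fold (no variance scaling).
// [[Rcpp::export]]
arma::vec cpp_press_profile(const arma::mat& X, const arma::vec& y, int a_max) {
  const int n = X.n_rows, b = X.n_cols;
  int A = std::min(a_max, std::min(n - 2, b));
  if (A < 1) Rcpp::stop("press: too few samples or bands");
  vec press(A, fill::zeros);
  mat W(b, A), P(b, A);
  vec q(A);
  mat Xtr(n - 1, b);
  vec ytr(n - 1);
  for (int i = 0; i < n; ++i) {
    int r = 0;
    for (int k = 0; k < n; ++k) {
      if (k == i) continue;
      Xtr.row(r) = X.row(k);
      ytr(r) = y(k);
      ++r;
    }
    rowvec xm = mean(Xtr, 0);
    double ym = mean(ytr);
    W.zeros(); P.zeros(); q.zeros();
    mat Xc = Xtr;
    Xc.each_row() -= xm;
    int got = nipals_path(std::move(Xc), ytr - ym, A, W, P, q);
    rowvec xt = X.row(i) - xm;
    double yhat = ym;
    for (int a = 0; a < A; ++a) {
      if (a < got) {
        double ta = dot(xt, W.col(a));
        xt -= ta * P.col(a).t();
        yhat += q(a) * ta;
      }
      double e = y(i) - yhat;
      press(a) += e * e;
    }
  }
  return press;
}
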