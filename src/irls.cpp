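// Robust line/plane fitting by iteratively reweighted least squares with a
// Tukey bisquare weight function, and the leave-one-out cross-validation
// kernel built on it. Kept in C++ because model selection evaluates the
// LOOCV loop for 18 candidate predictors per grid cell.
#define ARMA_WARN_LEVEL 0   // degenerate designs are handled by the caller
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double med(arma::vec v) {
  return arma::median(v);
}

// IRLS fit of y ~ X b with bisquare weights.
// Scale: s = median(|r|) / 0.6745, recomputed each iteration.
// Returns coefficients, converged flag, iteration count, fallback flag.
// On non-convergence or weight collapse the OLS coefficients are returned
// with fallback = true.
static arma::vec irls_core(const arma::mat& X, const arma::vec& y,
                           double c, double tol, int maxit,
                           bool& converged, int& iters, bool& fallback) {
  arma::vec ols = arma::solve(X, y);
  arma::vec beta = ols;
  converged = false; fallback = false; iters = 0;
  for (int it = 1; it <= maxit; ++it) {
    iters = it;
    arma::vec r = y - X * beta;
    double s = med(arma::abs(r)) / 0.6745;
    if (s < 1e-12 * (1.0 + med(arma::abs(y)))) { converged = true; break; }
    arma::vec u = r / (c * s);
    arma::vec w = arma::zeros(y.n_elem);
    for (arma::uword i = 0; i < y.n_elem; ++i) {
      double a = std::abs(u[i]);
      if (a < 1.0) { double q = 1.0 - u[i] * u[i]; w[i] = q * q; }
    }
    if (arma::accu(w) < 1e-12) { fallback = true; return ols; }
    arma::mat Xw = X.each_col() % arma::sqrt(w);
    arma::vec yw = y % arma::sqrt(w);
    arma::vec bnew;
    bool ok = arma::solve(bnew, Xw, yw);
    if (!ok) { fallback = true; return ols; }
    double delta = arma::norm(bnew - beta, 2);
    beta = bnew;
    if (delta < tol * (1.0 + arma::norm(beta, 2))) { converged = true; break; }
  }
  if (!converged) { fallback = true; return ols; }
  return beta;
}

// [[Rcpp::export(name = ".irls_fit_cpp")]]
List irls_fit_cpp(const arma::mat& X, const arma::vec& y,
                  double c = 4.685, double tol = 1e-8, int maxit = 50) {
  bool conv, fb; int it;
  arma::vec beta = irls_core(X, y, c, tol, maxit, conv, it, fb);
  return List::create(_["coefficients"] = beta, _["converged"] = conv,
                      _["iterations"] = it, _["fallback"] = fb);
}

// Leave-one-out CV for a per-cell burned-area model:
//   for each held-out year, robust-detrend BA and every predictor on the
//   training years, standardize the training residuals, fit a robust
//   regression of standardized BA on the standardized predictors, and
//   predict the held-out standardized BA with the trained trend/mean/sd
//   and coefficients. Nothing from the held-out year enters training.
// ba: n vector; Xp: n x p predictor matrix.
// Returns pred, obs_std (both standardized units) and n x p fold betas.
// [[Rcpp::export(name = ".loocv_cpp")]]
List loocv_cpp(const arma::vec& ba, const arma::mat& Xp,
               double c = 4.685, double tol = 1e-8, int maxit = 50) {
  const arma::uword n = ba.n_elem, p = Xp.n_cols;
  arma::vec pred(n, arma::fill::value(NA_REAL));
  arma::vec obs_std(n, arma::fill::value(NA_REAL));
  arma::mat betas(n, p); betas.fill(NA_REAL);
  arma::vec intercepts(n, arma::fill::value(NA_REAL));

  arma::vec yearidx = arma::linspace(1.0, (double)n, n);
  bool conv, fb; int it;

  for (arma::uword hold = 0; hold < n; ++hold) {
    arma::uvec tr(n - 1);
    arma::uword k = 0;
    for (arma::uword i = 0; i < n; ++i) if (i != hold) tr[k++] = i;

    arma::mat Xt(n - 1, 2, arma::fill::ones);
    Xt.col(1) = yearidx.elem(tr);

    // robust detrend + standardize BA on training years
    arma::vec bay = ba.elem(tr);
    arma::vec cb = irls_core(Xt, bay, c, tol, maxit, conv, it, fb);
    arma::vec rb = bay - Xt * cb;
    double mb = arma::mean(rb);
    double sb = arma::stddev(rb);
    if (!(sb > 1e-12)) continue;
    arma::vec zb = (rb - mb) / sb;

    // same for each predictor column
    arma::mat Zx(n - 1, p);
    arma::rowvec xhold(p);
    bool bad = false;
    for (arma::uword j = 0; j < p; ++j) {
      arma::vec xj = Xp.col(j);
      arma::vec cx = irls_core(Xt, xj.elem(tr), c, tol, maxit, conv, it, fb);
      arma::vec rx = xj.elem(tr) - Xt * cx;
      double mx = arma::mean(rx);
      double sx = arma::stddev(rx);
      if (!(sx > 1e-12)) { bad = true; break; }
      Zx.col(j) = (rx - mx) / sx;
      xhold[j] = (xj[hold] - (cx[0] + cx[1] * yearidx[hold]) - mx) / sx;
    }
    if (bad) continue;

    arma::mat Xr(n - 1, p + 1, arma::fill::ones);
    Xr.cols(1, p) = Zx;
    arma::vec cr = irls_core(Xr, zb, c, tol, maxit, conv, it, fb);

    intercepts[hold] = cr[0];
    for (arma::uword j = 0; j < p; ++j) betas(hold, j) = cr[j + 1];
    double yhat = cr[0];
    for (arma::uword j = 0; j < p; ++j) yhat += cr[j + 1] * xhold[j];
    pred[hold] = yhat;
    obs_std[hold] = (ba[hold] - (cb[0] + cb[1] * yearidx[hold]) - mb) / sb;
  }
  return List::create(_["pred"] = pred, _["obs_std"] = obs_std,
                      _["betas"] = betas, _["intercepts"] = intercepts);
}
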