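// Cox partial-likelihood machinery with Efron handling of tied event times.
// Inputs are expected sorted by increasing follow-up time; ties must be
// adjacent. All quantities are accumulated in a single reverse sweep so the
// per-call cost is O(n p^2).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Log partial likelihood, score vector and observed information at beta.
// time: sorted non-decreasing; event: 0/1; X: n x p design (same order).
// [[Rcpp::export(name = ".cox_efron_stats")]]
List cox_efron_stats(const arma::mat& X,
                     const arma::vec& time,
                     const arma::ivec& event,
                     const arma::vec& beta) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (time.n_elem != n || event.n_elem != n)
    stop("time/event length does not match design rows");

  arma::vec eta = X * beta;
  // guard against overflow: partial likelihood is invariant to a constant
  // shift of the linear predictor
  eta -= eta.max();
  arma::vec w = arma::exp(eta);

  double loglik = 0.0;
  arma::vec U(p, arma::fill::zeros);
  arma::mat I(p, p, arma::fill::zeros);

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);

  // walk tie groups from the largest time down
  arma::sword i = static_cast<arma::sword>(n) - 1;
  while (i >= 0) {
    arma::sword j = i;
    while (j >= 0 && time(j) == time(i)) --j;
    // group indices (j, i]
    double s0d = 0.0;
    arma::vec s1d(p, arma::fill::zeros);
    arma::mat s2d(p, p, arma::fill::zeros);
    double sum_eta = 0.0;
    arma::vec sum_x(p, arma::fill::zeros);
    int d = 0;
    for (arma::sword k = i; k > j; --k) {
      const arma::uword uk = static_cast<arma::uword>(k);
      arma::rowvec xk = X.row(uk);
      double wk = w(uk);
      S0 += wk;
      S1 += wk * xk.t();
      S2 += wk * (xk.t() * xk);
      if (event(uk) == 1) {
        ++d;
        sum_eta += eta(uk);
        sum_x += xk.t();
        s0d += wk;
        s1d += wk * xk.t();
        s2d += wk * (xk.t() * xk);
      }
    }
    if (d > 0) {
      loglik += sum_eta;
      U += sum_x;
      for (int l = 0; l < d; ++l) {
        double f = static_cast<double>(l) / d;
        double denom = S0 - f * s0d;
        arma::vec z = (S1 - f * s1d) / denom;
        loglik -= std::log(denom);
        U -= z;
        I += (S2 - f * s2d) / denom - z * z.t();
      }
    }
    i = j;
  }
  return List::create(_["loglik"] = loglik, _["score"] = U,
                      _["info"] = I);
}

// Efron-averaged Schoenfeld residuals, one row per event (in time order),
// plus the Efron-averaged risk-set variance matrix V(t_k) per event.
// Residual for event k in a tie group of size d is x_k - mean over the d
// Efron-adjusted risk-set averages; V(t_k) is the matching average of the
// Efron-adjusted risk-set covariance matrices.
// [[Rcpp::export(name = ".cox_schoenfeld")]]
List cox_schoenfeld(const arma::mat& X,
                    const arma::vec& time,
                    const arma::ivec& event,
                    const arma::vec& beta) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  eta -= eta.max();
  arma::vec w = arma::exp(eta);

  int nev = 0;
  for (arma::uword k = 0; k < n; ++k) if (event(k) == 1) ++nev;
  arma::mat res(nev, p, arma::fill::zeros);
  arma::vec etimes(nev, arma::fill::zeros);
  arma::cube vmat(p, p, nev, arma::fill::zeros);

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);

  int r = nev;  // fill from the back so rows end up in increasing time order
  arma::sword i = static_cast<arma::sword>(n) - 1;
  while (i >= 0) {
    arma::sword j = i;
    while (j >= 0 && time(j) == time(i)) --j;
    double s0d = 0.0;
    arma::vec s1d(p, arma::fill::zeros);
    arma::mat s2d(p, p, arma::fill::zeros);
    int d = 0;
    for (arma::sword k = i; k > j; --k) {
      const arma::uword uk = static_cast<arma::uword>(k);
      double wk = w(uk);
      arma::rowvec xk = X.row(uk);
      S0 += wk;
      S1 += wk * xk.t();
      S2 += wk * (xk.t() * xk);
      if (event(uk) == 1) {
        ++d;
        s0d += wk;
        s1d += wk * xk.t();
        s2d += wk * (xk.t() * xk);
      }
    }
    if (d > 0) {
      arma::vec xbar(p, arma::fill::zeros);
      arma::mat vbar(p, p, arma::fill::zeros);
      for (int l = 0; l < d; ++l) {
        double f = static_cast<double>(l) / d;
        double denom = S0 - f * s0d;
        arma::vec z = (S1 - f * s1d) / denom;
        xbar += z;
        vbar += (S2 - f * s2d) / denom - z * z.t();
      }
      xbar /= d;
      vbar /= d;
      for (arma::sword k = i; k > j; --k) {
        const arma::uword uk = static_cast<arma::uword>(k);
        if (event(uk) == 1) {
          --r;
          res.row(r) = X.row(uk) - xbar.t();
          etimes(r) = time(uk);
          vmat.slice(r) = vbar;
        }
      }
    }
    i = j;
  }
  return List::create(_["residuals"] = res, _["time"] = etimes,
                      _["vmat"] = vmat);
}
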