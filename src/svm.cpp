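// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// L1-loss linear SVM fit by dual coordinate descent (the liblinear
// algorithm), with the bias absorbed as an extra always-one feature.
// Solves min_w 0.5||w||^2 + C * sum_i max(0, 1 - y_i w.x_i).
static arma::vec svm_fit(const arma::mat& X, const arma::vec& y,
                         double cost, int max_iter, double tol) {
  arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat Xa(n, p + 1);
  Xa.cols(0, p - 1) = X;
  Xa.col(p).ones();
  arma::vec qii(n), alpha(n, arma::fill::zeros), w(p + 1, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) qii[i] = arma::dot(Xa.row(i), Xa.row(i));
  for (int it = 0; it < max_iter; ++it) {
    double maxdiff = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      if (qii[i] <= 0) continue;
      double G = y[i] * arma::dot(w, Xa.row(i).t()) - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= cost) PG = std::max(G, 0.0);
      if (std::abs(PG) > 1e-12) {
        double old = alpha[i];
        alpha[i] = std::min(std::max(old - G / qii[i], 0.0), cost);
        w += (alpha[i] - old) * y[i] * Xa.row(i).t();
        maxdiff = std::max(maxdiff, std::abs(alpha[i] - old));
      }
    }
    if (maxdiff < tol) break;
  }
  return w;
}

// Fit on (X, y in {-1,+1}); returns weights c(w, bias). Exported so tests can
// compare decision values against an independent SVM implementation.
// [[Rcpp::export]]
arma::vec cpp_svm_weights(const arma::mat& X, const arma::vec& y,
                          double cost = 1.0, int max_iter = 1000,
                          double tol = 1e-8) {
  return svm_fit(X, y, cost, max_iter, tol);
}

// Per-time-bin split-half decoding for one condition pair.
// trA/trB/teA/teB: arrays [pseudotrial, channel, time] (train/test halves for
// conditions A and B). Fits a linear SVM per bin on the training pseudotrials
// and returns the fraction of test pseudotrials classified correctly, per bin.
// A decision value of exactly zero scores half a trial correct.
// [[Rcpp::export]]
arma::vec cpp_decode_timecourse(const arma::cube& trA, const arma::cube& trB,
                                const arma::cube& teA, const arma::cube& teB,
                                double cost = 1.0, int max_iter = 1000,
                                double tol = 1e-8) {
  arma::uword nt = trA.n_slices;
  if (trB.n_slices != nt || teA.n_slices != nt || teB.n_slices != nt)
    stop("time dimensions differ");
  arma::uword na = trA.n_rows, nb = trB.n_rows;
  arma::uword ma = teA.n_rows, mb = teB.n_rows;
  arma::vec y(na + nb);
  y.head(na).fill(1.0);
  y.tail(nb).fill(-1.0);
  arma::vec acc(nt);
  for (arma::uword t = 0; t < nt; ++t) {
    arma::mat Xtr = arma::join_cols(trA.slice(t), trB.slice(t));
    arma::vec w = svm_fit(Xtr, y, cost, max_iter, tol);
    arma::vec wf = w.head(w.n_elem - 1);
    double b = w[w.n_elem - 1];
    double correct = 0.0;
    for (arma::uword i = 0; i < ma; ++i) {
      double s = arma::dot(teA.slice(t).row(i), wf) + b;
      correct += (s > 0) ? 1.0 : (s == 0 ? 0.5 : 0.0);
    }
    for (arma::uword i = 0; i < mb; ++i) {
      double s = arma::dot(teB.slice(t).row(i), wf) + b;
      correct += (s < 0) ? 1.0 : (s == 0 ? 0.5 : 0.0);
    }
    acc[t] = correct / (double)(ma + mb);
  }
  return acc;
}
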