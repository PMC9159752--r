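// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 0-based condensed index of local pair (i < j) among m items.
static inline int cidx(int i, int j, int m) {
  if (i > j) std::swap(i, j);
  return i * m - (i * (i + 1)) / 2 + (j - i) - 1;
}

// Classical (Torgerson) 2D MDS of a small dissimilarity matrix, rescaled to
// the unit disk, with optional Gaussian placement jitter (R RNG).
// [[Rcpp::export]]
arma::mat cpp_mds_disk(const arma::mat& D, double sigma) {
  int m = D.n_rows;
  arma::mat D2 = arma::square(D);
  arma::mat J = arma::eye(m, m) - arma::ones(m, m) / (double)m;
  arma::mat B = -0.5 * J * D2 * J;
  B = 0.5 * (B + B.t());
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, B); // ascending
  arma::mat coords(m, 2, arma::fill::zeros);
  for (int d = 0; d < 2 && d < m; ++d) {
    double lam = eval[m - 1 - d];
    if (lam > 0) coords.col(d) = evec.col(m - 1 - d) * std::sqrt(lam);
  }
  double r = 0.0;
  for (int i = 0; i < m; ++i)
    r = std::max(r, std::sqrt(coords(i, 0) * coords(i, 0) +
                              coords(i, 1) * coords(i, 1)));
  if (r > 0) coords /= r;
  if (sigma > 0) {
    for (int i = 0; i < m; ++i) {
      coords(i, 0) += R::rnorm(0.0, sigma);
      coords(i, 1) += R::rnorm(0.0, sigma);
    }
    r = 0.0;
    for (int i = 0; i < m; ++i)
      r = std::max(r, std::sqrt(coords(i, 0) * coords(i, 0) +
                                coords(i, 1) * coords(i, 1)));
    if (r > 1) coords /= r;
  }
  return coords;
}

// Next lift-the-weakest subset (1-based local item indices), or an empty
// vector when every pair has reached the criterion.
// evidence: condensed vector over m local items; appearances: per-item trial
// counts; Dest: m x m estimated dissimilarities guiding the zoom-in growth
// (all-zero matrix disables it). Seed pair = minimal evidence (preferring
// rarely shown items, random tie-break); growth = unseen items first, then
// items closest to the seed pair under Dest (ties: least evidence with the
// seed, then random).
// [[Rcpp::export]]
IntegerVector cpp_next_subset(const arma::vec& evidence,
                              const arma::ivec& appearances,
                              const arma::mat& Dest,
                              int size, double criterion) {
  int m = appearances.n_elem;
  if (evidence.min() >= criterion) return IntegerVector(0);
  // seed pair
  double emin = evidence.min();
  double best_key = R_PosInf;
  int bi = 0, bj = 1;
  for (int i = 0; i < m - 1; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double e = evidence[cidx(i, j, m)];
      if (e > emin + 1e-15) continue;
      double load = appearances[i] + appearances[j];
      double key = load + 0.5 * R::unif_rand(); // random tie-break
      if (key < best_key) { best_key = key; bi = i; bj = j; }
    }
  }
  std::vector<int> chosen = {bi, bj};
  std::vector<bool> in(m, false);
  in[bi] = in[bj] = true;
  if (size > m) size = m;
  while ((int)chosen.size() < size) {
    double best = R_PosInf;
    int pick = -1;
    for (int x = 0; x < m; ++x) {
      if (in[x]) continue;
      double key;
      if (appearances[x] == 0) {
        // coverage: unseen items take priority, nearest to the seed first
        key = -1e6 + Dest(x, bi) + Dest(x, bj) + 1e-9 * R::unif_rand();
      } else {
        double ev = evidence[cidx(x, bi, m)] + evidence[cidx(x, bj, m)];
        key = Dest(x, bi) + Dest(x, bj) + 1e-6 * ev + 1e-9 * R::unif_rand();
      }
      if (key < best) { best = key; pick = x; }
    }
    in[pick] = true;
    chosen.push_back(pick);
  }
  std::sort(chosen.begin(), chosen.end());
  IntegerVector out(chosen.size());
  for (size_t q = 0; q < chosen.size(); ++q) out[q] = chosen[q] + 1;
  return out;
}
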