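// Pruning likelihood for codon models on a fixed tree.
//
// The GY94 rate matrix is reversible, so Q is symmetrised with the
// pi^{1/2} similarity transform and exponentiated through a symmetric
// eigendecomposition; transition matrices for all edges reuse the same
// decomposition. Per-pattern partial likelihoods are rescaled at every
// internal node to avoid underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Compute per-pattern log-likelihoods for one rate matrix.
//
// Q:          n x n unscaled rate matrix (rows sum to zero)
// pi:         stationary frequencies (length n)
// edge:       (2 x nedge) ape-style edge matrix in postorder, 1-based
// edge_len:   effective edge lengths (already scaled to expected
//             substitutions per codon for this model)
// n_tip:      number of terminal nodes
// tip_states: ntip x npat integer matrix, 0-based state, -1 = missing
// root_prior: length-n prior at the root
// [[Rcpp::export]]
NumericVector cpp_codon_site_loglik(const arma::mat& Q,
                                    const arma::vec& pi,
                                    const IntegerMatrix& edge,
                                    const NumericVector& edge_len,
                                    int n_tip,
                                    const IntegerMatrix& tip_states,
                                    const arma::vec& root_prior) {
  const int n = Q.n_rows;
  const int nedge = edge.nrow();
  const int npat = tip_states.ncol();
  const int n_all = nedge + 2;  // every non-root node has one edge

  arma::vec sq = arma::sqrt(pi);
  arma::mat B = arma::diagmat(sq) * Q * arma::diagmat(1.0 / sq);
  B = 0.5 * (B + B.t());  // clean numerical asymmetry
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, B);
  arma::mat left = arma::diagmat(1.0 / sq) * evec;   // n x n
  arma::mat right = evec.t() * arma::diagmat(sq);    // n x n

  // partials: one (n x npat) matrix per node, allocated lazily
  std::vector<arma::mat> part(n_all + 1);
  std::vector<arma::rowvec> logscale(n_all + 1);
  std::vector<bool> seen(n_all + 1, false);

  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0) - 1;
    int child = edge(e, 1) - 1;
    arma::mat P = left * arma::diagmat(arma::exp(eval * edge_len[e])) * right;
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });

    arma::mat down(n, npat);
    if (child < n_tip) {
      for (int s = 0; s < npat; ++s) {
        int st = tip_states(child, s);
        if (st < 0) {
          down.col(s) = arma::sum(P, 1);  // missing: sum over all states
        } else {
          down.col(s) = P.col(st);
        }
      }
    } else {
      down = P * part[child];
    }
    if (!seen[parent]) {
      part[parent] = down;
      logscale[parent] = arma::rowvec(npat, arma::fill::zeros);
      if (child >= n_tip) logscale[parent] += logscale[child];
      seen[parent] = true;
    } else {
      part[parent] %= down;
      if (child >= n_tip) logscale[parent] += logscale[child];
      // rescale
      arma::rowvec mx = arma::max(part[parent], 0);
      mx.transform([](double v) { return v <= 0.0 ? 1.0 : v; });
      part[parent].each_row() /= mx;
      logscale[parent] += arma::log(mx);
    }
  }

  int root = edge(nedge - 1, 0) - 1;
  arma::rowvec lik = root_prior.t() * part[root];
  NumericVector out(npat);
  for (int s = 0; s < npat; ++s) {
    out[s] = (lik[s] > 0 ? std::log(lik[s]) : R_NegInf) + logscale[root][s];
  }
  return out;
}
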