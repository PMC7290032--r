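#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Transition probabilities of a finite-state CTMC: P(t) = exp(Q t),
// computed by scaling-and-squaring (arma::expmat).
// [[Rcpp::export]]
arma::mat ctmc_transition_cpp(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// Felsenstein pruning log-likelihood for a fixed root state.
//
// edge         : 2-column matrix of (parent, child) node ids, 1-based,
//                in postorder (every child edge precedes its parent's edge).
// edge_length  : branch lengths aligned with edge rows.
// tip_partials : n_tip x k matrix of tip conditional likelihoods
//                (indicator rows for observed states, all-ones for missing).
// n_node       : number of internal nodes.
// Q            : k x k rate matrix.
// root         : node id of the root (1-based).
// root_state   : index of the fixed root state (1-based).
// [[Rcpp::export]]
double pruning_loglik_cpp(const arma::imat& edge,
                          const arma::vec& edge_length,
                          const arma::mat& tip_partials,
                          int n_node,
                          const arma::mat& Q,
                          int root,
                          int root_state) {
  const int k = Q.n_cols;
  const int n_tip = tip_partials.n_rows;
  arma::mat L(n_tip + n_node, k, arma::fill::ones);
  L.rows(0, n_tip - 1) = tip_partials;
  double logscale = 0.0;
  for (arma::uword i = 0; i < edge.n_rows; ++i) {
    const int p = edge(i, 0) - 1;
    const int c = edge(i, 1) - 1;
    arma::mat P = arma::expmat(Q * edge_length(i));
    // down(a) = sum_b P(a,b) L_c(b)
    arma::rowvec down = L.row(c) * P.t();
    L.row(p) %= down;
    const double m = L.row(p).max();
    if (m > 0.0 && m < 1e-120) {  // rescale to avoid underflow on deep trees
      L.row(p) /= m;
      logscale += std::log(m);
    }
  }
  const double lr = L(root - 1, root_state - 1);
  if (!(lr > 0.0)) return R_NegInf;
  return std::log(lr) + logscale;
}
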