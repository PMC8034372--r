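// Pruning core for DEC-family likelihoods.
//
// The anagenetic process is a CTMC over range states (matrix Q, per-Ma
// rates); cladogenesis is a finite scenario table (parent, left, right,
// probability) applied at every internal node.  Likelihoods are rescaled
// per node to avoid underflow on large trees.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Post-order conditional likelihoods.
//
// node/child1/child2: 0-based node indices; tips are 0..ntip-1 and
// internal nodes follow, `node` listed in post-order (root last).
// tip_clv: ntip x S indicator matrix.  Scenario vectors are 0-based state
// indices with probabilities already normalised per parent state.
// [[Rcpp::export]]
List dec_downpass_cpp(const arma::mat& Q,
                      const IntegerVector& node,
                      const IntegerVector& child1,
                      const IntegerVector& child2,
                      const NumericVector& blen1,
                      const NumericVector& blen2,
                      const arma::mat& tip_clv,
                      const IntegerVector& cl_parent,
                      const IntegerVector& cl_left,
                      const IntegerVector& cl_right,
                      const NumericVector& cl_prob,
                      const arma::vec& root_prior,
                      const bool return_arrays) {
  const int S = Q.n_rows;
  const int ntip = tip_clv.n_rows;
  const int nint = node.size();
  const int nnode = ntip + nint;
  const int nsc = cl_parent.size();

  arma::mat clv(nnode, S, arma::fill::zeros);
  clv.rows(0, ntip - 1) = tip_clv;
  arma::vec logscale(nnode, arma::fill::zeros);

  arma::cube P1, P2;
  arma::mat B1m, B2m;
  if (return_arrays) {
    P1.set_size(S, S, nint);
    P2.set_size(S, S, nint);
    B1m.set_size(nint, S);
    B2m.set_size(nint, S);
  }

  for (int k = 0; k < nint; ++k) {
    const int v = node[k];
    const int a = child1[k];
    const int b = child2[k];
    arma::mat Pa = arma::expmat(Q * blen1[k]);
    arma::mat Pb = arma::expmat(Q * blen2[k]);
    arma::vec Ba = Pa * clv.row(a).t();
    arma::vec Bb = Pb * clv.row(b).t();
    arma::vec out(S, arma::fill::zeros);
    for (int s = 0; s < nsc; ++s)
      out[cl_parent[s]] += cl_prob[s] * Ba[cl_left[s]] * Bb[cl_right[s]];
    double m = out.max();
    if (!(m > 0.0) || !std::isfinite(m)) m = 1.0;  // dead subtree: keep zeros
    clv.row(v) = (out / m).t();
    logscale[v] = std::log(m) + logscale[a] + logscale[b];
    if (return_arrays) {
      P1.slice(k) = Pa;
      P2.slice(k) = Pb;
      B1m.row(k) = Ba.t();
      B2m.row(k) = Bb.t();
    }
  }

  const int root = node[nint - 1];
  const double rootlik = arma::dot(root_prior, clv.row(root).t());
  const double lnL = std::log(rootlik) + logscale[root];

  List out = List::create(_["loglik"] = lnL,
                          _["clv"] = clv,
                          _["logscale"] = logscale);
  if (return_arrays) {
    out["P1"] = P1;
    out["P2"] = P2;
    out["B1"] = B1m;
    out["B2"] = B2m;
  }
  return out;
}
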