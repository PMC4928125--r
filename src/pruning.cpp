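// Felsenstein pruning over the 61 sense-codon state space.
// Edges must be supplied in postorder (every child edge before its parent's
// edge); tip states are 1-based codon indices, 0 meaning missing (gap codon).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Per-pattern log-likelihoods, one column per site class.
//
// eigen_sets: list over site classes; each element is a list over edge
// regimes; each regime is list(A, Ainv, d) with Q = A diag(d) Ainv, so
// P(t) = A diag(exp(d t)) Ainv.
// [[Rcpp::export]]
arma::mat cs_pruning_loglik(const arma::imat& edge,
                            const arma::vec& edge_len,
                            const arma::ivec& edge_regime,
                            const arma::imat& tip_states,
                            int n_tip,
                            int n_node_total,
                            int root,
                            const List& eigen_sets,
                            const arma::vec& pi) {
  const int n_pat = tip_states.n_cols;
  const int n_class = eigen_sets.size();
  const int n_state = pi.n_elem;
  const int n_edge = edge.n_rows;
  arma::mat out(n_pat, n_class);

  for (int k = 0; k < n_class; ++k) {
    List regimes = eigen_sets[k];
    const int n_reg = regimes.size();
    std::vector<arma::mat> A(n_reg), Ainv(n_reg);
    std::vector<arma::vec> d(n_reg);
    for (int r = 0; r < n_reg; ++r) {
      List e = regimes[r];
      A[r] = as<arma::mat>(e["A"]);
      Ainv[r] = as<arma::mat>(e["Ainv"]);
      d[r] = as<arma::vec>(e["d"]);
    }

    std::vector<arma::mat> part(n_node_total + 1);
    std::vector<bool> has_part(n_node_total + 1, false);
    arma::rowvec logscale(n_pat, arma::fill::zeros);

    for (int e = 0; e < n_edge; ++e) {
      const int parent = edge(e, 0);
      const int child = edge(e, 1);
      const int r = edge_regime(e) - 1;
      arma::mat P = A[r] * arma::diagmat(arma::exp(d[r] * edge_len(e))) * Ainv[r];
      P.elem(arma::find(P < 0)).zeros();
      if (!has_part[parent]) {
        part[parent] = arma::mat(n_state, n_pat, arma::fill::ones);
        has_part[parent] = true;
      }
      arma::mat& pp = part[parent];
      if (child <= n_tip) {
        for (int j = 0; j < n_pat; ++j) {
          const int s = tip_states(child - 1, j);
          if (s > 0) pp.col(j) %= P.col(s - 1);
        }
      } else {
        pp %= P * part[child];
        part[child].reset();
      }
      arma::rowvec m = arma::max(pp, 0);
      for (int j = 0; j < n_pat; ++j) {
        if (m(j) > 0.0 && m(j) < 1e-100) {
          pp.col(j) /= m(j);
          logscale(j) += std::log(m(j));
        }
      }
    }

    arma::rowvec root_lik = pi.t() * part[root];
    for (int j = 0; j < n_pat; ++j) {
      out(j, k) = std::log(root_lik(j)) + logscale(j);
    }
  }
  return out;
}
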