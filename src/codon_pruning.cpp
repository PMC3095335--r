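// Felsenstein pruning for GY94-style codon models.
//
// The generator Q is reversible with respect to the codon frequencies pi, so
// P(t) = exp(Qt) is computed from the symmetric eigendecomposition of
// diag(sqrt(pi)) Q diag(1/sqrt(pi)).  The per-pattern partial-likelihood
// recursion runs over a postorder edge list (ape "phylo" convention: tips are
// nodes 1..n_tip, edges as a 2-column matrix of parent/child node ids).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Eigendecomposition of a scaled GY94 generator.
// neighbour table: 0-based codon indices i/j differing at one position,
// ts = 1 for transitions, syn = 1 for synonymous changes.
// Returns lambda, U, Ui with exp(Qt) = U diag(exp(lambda t)) Ui.
// [[Rcpp::export]]
List cpp_gy94_eigen(const arma::vec& pi, double kappa, double omega,
                    const arma::uvec& ii, const arma::uvec& jj,
                    const arma::uvec& ts, const arma::uvec& syn) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword k = 0; k < ii.n_elem; ++k) {
    double r = pi(jj(k));
    if (ts(k)) r *= kappa;
    if (!syn(k)) r *= omega;
    Q(ii(k), jj(k)) = r;
  }
  Q.diag() = -arma::sum(Q, 1);
  double scale = -arma::dot(pi, Q.diag());
  if (scale <= 0) stop("degenerate rate matrix (zero total rate)");
  Q /= scale;

  arma::vec sp = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= sp;       // diag(sp) * Q
  B.each_row() /= sp.t();   // ... * diag(1/sp)
  B = 0.5 * (B + B.t());    // symmetrize against rounding
  arma::vec lambda;
  arma::mat V;
  if (!arma::eig_sym(lambda, V, B)) stop("eigendecomposition failed");
  arma::mat U = V;
  U.each_col() /= sp;
  arma::mat Ui = V.t();
  Ui.each_row() %= sp.t();
  return List::create(_["lambda"] = lambda, _["U"] = U, _["Ui"] = Ui);
}

static arma::mat pmat_from_eigen(const arma::vec& lambda, const arma::mat& U,
                                 const arma::mat& Ui, double t) {
  arma::mat P = U * arma::diagmat(arma::exp(lambda * t)) * Ui;
  P.transform([](double x) { return x < 0 ? 0.0 : x; });
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_pmat(const List& eig, double t) {
  return pmat_from_eigen(as<arma::vec>(eig["lambda"]), as<arma::mat>(eig["U"]),
                         as<arma::mat>(eig["Ui"]), t);
}

// Per-pattern log-likelihood under one substitution process (one P per edge).
static arma::vec prune_one(const arma::imat& edge, const arma::vec& edge_len,
                           int n_node, const arma::imat& tips,
                           const std::vector<const List*>& eigs,
                           const arma::vec& pi) {
  const int n_states = pi.n_elem;
  const int m = tips.n_cols;
  const int n_tip = tips.n_rows;
  const int E = edge.n_rows;

  std::vector<arma::mat> part(n_node + 1);
  std::vector<bool> seen(n_node + 1, false);
  arma::rowvec logscale(m, arma::fill::zeros);

  for (int e = 0; e < E; ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    const List& eg = *eigs[e];
    arma::mat P = pmat_from_eigen(as<arma::vec>(eg["lambda"]),
                                  as<arma::mat>(eg["U"]),
                                  as<arma::mat>(eg["Ui"]), edge_len(e));
    arma::mat down(n_states, m);
    if (child <= n_tip) {
      arma::mat tipL(n_states, m, arma::fill::zeros);
      for (int s = 0; s < m; ++s) {
        int st = tips(child - 1, s);
        if (st == 0) tipL.col(s).ones();   // gap / missing data
        else tipL(st - 1, s) = 1.0;
      }
      down = P * tipL;
    } else {
      down = P * part[child];
      part[child].reset();
    }
    if (!seen[parent]) {
      part[parent] = down;
      seen[parent] = true;
    } else {
      part[parent] %= down;
    }
    // rescale to avoid underflow on deep trees
    arma::rowvec mx = arma::max(part[parent], 0);
    for (int s = 0; s < m; ++s) {
      if (mx(s) > 0 && (mx(s) < 1e-100 || mx(s) > 1e100)) {
        part[parent].col(s) /= mx(s);
        logscale(s) += std::log(mx(s));
      }
    }
  }
  int root = edge(E - 1, 0);
  arma::rowvec lik = pi.t() * part[root];
  arma::vec out(m);
  for (int s = 0; s < m; ++s)
    out(s) = std::log(lik(s)) + logscale(s);
  return out;
}

// Per-pattern log-likelihoods for each omega class (shared eigen per class).
// Returns an m x K matrix.
// [[Rcpp::export]]
arma::mat cpp_class_loglik(const arma::imat& edge, const arma::vec& edge_len,
                           int n_node, const arma::imat& tips,
                           const List& eig_list, const arma::vec& pi) {
  const int K = eig_list.size();
  const int m = tips.n_cols;
  arma::mat out(m, K);
  std::vector<List> keep(K);
  for (int k = 0; k < K; ++k) keep[k] = eig_list[k];
  for (int k = 0; k < K; ++k) {
    std::vector<const List*> eigs(edge.n_rows, &keep[k]);
    out.col(k) = prune_one(edge, edge_len, n_node, tips, eigs, pi);
  }
  return out;
}

// Per-pattern log-likelihood with one process per edge (branch models).
// [[Rcpp::export]]
arma::vec cpp_branch_loglik(const arma::imat& edge, const arma::vec& edge_len,
                            int n_node, const arma::imat& tips,
                            const List& eig_per_edge, const arma::vec& pi) {
  std::vector<List> keep(edge.n_rows);
  std::vector<const List*> eigs(edge.n_rows);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    keep[e] = eig_per_edge[e];
    eigs[e] = &keep[e];
  }
  return prune_one(edge, edge_len, n_node, tips, eigs, pi);
}
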