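// Felsenstein pruning over 61 sense-codon states with per-pattern scaling,
// plus the two-pass (post-order/pre-order) algorithm for analytic
// derivatives of the log-likelihood with respect to arbitrary per-edge
// perturbations dP of the transition matrices (used for branch lengths via
// dP = Q P, and for rate parameters via finite differences on the R side).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NS = 61;

// tips: ntip x npat integer matrix, 0-based codon states, -1 = missing.
// edge: nedge x 2 (parent, child), 1-based node ids, postorder (children
//       before parents); tips are nodes 1..ntip.
// P:    NS x NS x nedge transition matrices, rows = parent state.
// dP:   NS x NS x nslice perturbation matrices; slice k perturbs edge
//       dP_edge[k] and accumulates into gradient entry dP_param[k].
// [[Rcpp::export]]
Rcpp::List pruning_loglik_cpp(const Rcpp::IntegerMatrix& tips,
                              const arma::vec& weights,
                              const Rcpp::IntegerMatrix& edge,
                              const arma::cube& P,
                              const arma::vec& pi,
                              const bool want_grad,
                              const arma::cube& dP,
                              const Rcpp::IntegerVector& dP_edge,
                              const Rcpp::IntegerVector& dP_param,
                              const int npar) {
  const int ntip = tips.nrow();
  const int npat = tips.ncol();
  const int nedge = edge.nrow();

  int nnodes = 0;
  for (int e = 0; e < nedge; ++e) {
    nnodes = std::max(nnodes, std::max(edge(e, 0), edge(e, 1)));
  }

  std::vector<mat> L(nnodes + 1);          // scaled partials per node
  std::vector<rowvec> cs(nnodes + 1);      // cumulative log-scalers
  std::vector<std::vector<int>> child_edges(nnodes + 1);

  for (int t = 1; t <= ntip; ++t) {
    mat Lt(NS, npat, fill::zeros);
    for (int s = 0; s < npat; ++s) {
      int st = tips(t - 1, s);
      if (st < 0) {
        Lt.col(s).ones();
      } else {
        Lt(st, s) = 1.0;
      }
    }
    L[t] = std::move(Lt);
    cs[t] = rowvec(npat, fill::zeros);
  }

  std::vector<mat> X(nedge);               // P_e * L[child], per edge

  // post-order pass
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0);
    const int ch = edge(e, 1);
    child_edges[par].push_back(e);
    mat Xe = P.slice(e) * L[ch];
    if (L[par].n_elem == 0) {
      L[par] = Xe;
      cs[par] = cs[ch];
    } else {
      L[par] %= Xe;
      cs[par] += cs[ch];
    }
    if (want_grad) X[e] = std::move(Xe);
    // rescale parent partials pattern-wise
    rowvec m = max(L[par], 0);
    for (int s = 0; s < npat; ++s) {
      if (m(s) <= 0 || !std::isfinite(m(s))) {
        Rcpp::stop("numerical underflow in pruning at pattern %d", s + 1);
      }
    }
    L[par].each_row() /= m;
    cs[par] += log(m);
  }

  const int root = edge(nedge - 1, 0);
  rowvec rootdot = pi.t() * L[root];
  rowvec site_loglik = log(rootdot) + cs[root];
  double loglik = dot(site_loglik, weights.t());

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = loglik,
      Rcpp::Named("site_loglik") =
          Rcpp::NumericVector(site_loglik.begin(), site_loglik.end()));

  if (!want_grad) return out;

  // pre-order pass: R[v] = scaled partial for everything outside the
  // subtree of v (row-vector semantics, stored as NS x npat), rs[v] its
  // log-scaler. For each edge e = (par, ch): U_e = R[par] .* prod of
  // sibling X's, with log-scaler du_e = rs[par] + sum of sibling subtree
  // scalers; then R[ch] = P_e^T U_e.
  std::vector<mat> R(nnodes + 1);
  std::vector<rowvec> rs(nnodes + 1);
  R[root] = repmat(pi, 1, npat);
  rs[root] = rowvec(npat, fill::zeros);

  std::vector<mat> U(nedge);
  std::vector<rowvec> du(nedge);

  for (int e = nedge - 1; e >= 0; --e) {
    const int par = edge(e, 0);
    const int ch = edge(e, 1);
    mat Ue = R[par];
    rowvec d = rs[par];
    for (int b : child_edges[par]) {
      if (b == e) continue;
      Ue %= X[b];
      d += cs[edge(b, 1)];
    }
    if (ch > ntip) {
      mat Rc = P.slice(e).t() * Ue;
      rowvec m = max(Rc, 0);
      Rc.each_row() /= m;
      R[ch] = std::move(Rc);
      rs[ch] = d + log(m);
    }
    U[e] = std::move(Ue);
    du[e] = d;
  }

  // contraction for each perturbation slice
  vec grad(npar, fill::zeros);
  const int nslice = dP.n_slices;
  for (int k = 0; k < nslice; ++k) {
    const int e = dP_edge[k] - 1;
    const int ch = edge(e, 1);
    mat M = dP.slice(k) * L[ch];
    rowvec num = sum(U[e] % M, 0);
    rowvec deficit = du[e] + cs[ch] - site_loglik;
    double g = 0.0;
    for (int s = 0; s < npat; ++s) {
      g += weights(s) * num(s) * std::exp(deficit(s));
    }
    grad(dP_param[k] - 1) += g;
  }

  out["grad"] = Rcpp::NumericVector(grad.begin(), grad.end());
  return out;
}
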