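// Core numerics for the pruning (Felsenstein) likelihood of a
// continuous-time Markov chain on a rooted tree.  State spaces here are
// small (<= 15 composite states) so dense linear algebra is exact and fast.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// P(t) = expm(Q t) for every branch length.  Q is diagonalised once; each
// branch then costs two small matrix products.  If the eigenvector matrix
// is ill-conditioned (defective or near-defective Q) every branch falls
// back to scaling-and-squaring.
static cube pmats_cube(const mat &Q, const vec &lens) {
  const uword s = Q.n_rows, ne = lens.n_elem;
  cube P(s, s, ne);

  cx_vec ev;
  cx_mat V, Vi;
  bool use_eig = eig_gen(ev, V, Q);
  if (use_eig) {
    double rc = rcond(cx_mat(V));
    use_eig = std::isfinite(rc) && rc > 1e-9 && inv(Vi, V);
  }

  for (uword e = 0; e < ne; ++e) {
    const double t = lens[e];
    if (!(t > 0)) {  // zero-length branch: identity, no expm call
      P.slice(e) = eye(s, s);
      continue;
    }
    mat Pt;
    if (use_eig) {
      Pt = real(V * diagmat(exp(ev * t)) * Vi);
    } else {
      Pt = expmat(Q * t);
    }
    Pt.elem(find(Pt < 0)).zeros();
    vec rs = sum(Pt, 1);
    for (uword i = 0; i < s; ++i)
      if (rs[i] > 0) Pt.row(i) /= rs[i];
    P.slice(e) = Pt;
  }
  return P;
}

// [[Rcpp::export]]
arma::cube cpp_pmats(const arma::mat &Q, const arma::vec &lens) {
  return pmats_cube(Q, lens);
}

// Post-order pruning pass.
//  edge:      (n_edge x 2) 1-based (parent, child) rows in post-order
//  partials0: (n_state x n_node) conditional likelihoods at tips and
//             0/1 constraint masks at internal nodes
// Per-node rescaling keeps partials in range on 10^4-tip trees; the
// accumulated log factor is returned separately.
// [[Rcpp::export]]
Rcpp::List cpp_pruning(const arma::imat &edge, const arma::vec &lens,
                       const arma::mat &partials0, const arma::mat &Q,
                       const bool details) {
  const uword ne = edge.n_rows, s = Q.n_rows;
  cube P = pmats_cube(Q, lens);
  mat part = partials0;
  mat W;
  if (details) W.set_size(s, ne);

  double logscale = 0.0;
  for (uword e = 0; e < ne; ++e) {
    const uword p = (uword)edge(e, 0) - 1, c = (uword)edge(e, 1) - 1;
    vec w = P.slice(e) * part.col(c);
    if (details) W.col(e) = w;
    part.col(p) %= w;
    const double m = part.col(p).max();
    if (m > 0) {
      part.col(p) /= m;
      logscale += std::log(m);
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("partials") = part, Rcpp::Named("logscale") = logscale);
  if (details) {
    out["W"] = W;
    out["P"] = P;
  }
  return out;
}
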