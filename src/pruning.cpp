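// Felsenstein pruning core: transition matrices by eigendecomposition of the
// generator (scaling-and-squaring fallback for near-defective Q), postorder
// accumulation of conditional likelihoods with per-node rescaling.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct GenDecomp {
  bool use_eig;
  cx_vec values;
  cx_mat vectors;
  cx_mat vinv;
  mat Q;
};

GenDecomp decompose(const mat& Q) {
  GenDecomp d;
  d.Q = Q;
  d.use_eig = false;
  cx_vec val;
  cx_mat vec;
  if (eig_gen(val, vec, Q)) {
    cx_mat vinv;
    if (inv(vinv, vec)) {
      double cond = norm(vec, "inf") * norm(vinv, "inf");
      if (std::isfinite(cond) && cond < 1e9) {
        d.use_eig = true;
        d.values = val;
        d.vectors = vec;
        d.vinv = vinv;
      }
    }
  }
  return d;
}

mat pmat(const GenDecomp& d, double t) {
  const uword k = d.Q.n_rows;
  if (t == 0.0) return eye(k, k);
  mat P;
  if (d.use_eig) {
    cx_vec ev = exp(d.values * t);
    P = real(d.vectors * diagmat(ev) * d.vinv);
  } else {
    P = expmat(d.Q * t);
  }
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

}  // namespace

// edge: n_edge x 2 (1-based, postorder); partials: n_tip x k;
// returns root partial, log scaling and optionally the full bookkeeping
// needed for ancestral reconstruction and stochastic mapping.
// [[Rcpp::export(name = ".prune_core")]]
Rcpp::List prune_core(const arma::imat& edge, const arma::vec& lengths,
                      const arma::mat& partials, const arma::mat& Q,
                      int n_tip, int n_node, bool keep) {
  const uword k = Q.n_rows;
  const uword n_edge = edge.n_rows;
  const uword n_tot = n_tip + n_node;
  const uword root = n_tip;  // 0-based index of root (R index n_tip + 1)

  GenDecomp dec = decompose(Q);

  mat lik(n_tot, k, fill::zeros);
  lik.rows(0, n_tip - 1) = partials;
  std::vector<bool> seen(n_tot, false);
  double logscale = 0.0;
  bool zero = false;

  cube pm;
  mat up_msg;
  if (keep) {
    pm.set_size(k, k, n_edge);
    up_msg.set_size(n_edge, k);
  }

  for (uword e = 0; e < n_edge; ++e) {
    const uword p = edge(e, 0) - 1;
    const uword ch = edge(e, 1) - 1;
    mat P = pmat(dec, lengths(e));
    rowvec msg = lik.row(ch) * P.t();
    if (keep) {
      pm.slice(e) = P;
      up_msg.row(e) = msg;
    }
    if (!seen[p]) {
      lik.row(p) = msg;
      seen[p] = true;
    } else {
      lik.row(p) %= msg;
    }
    double s = accu(lik.row(p));
    if (s <= 0.0) {
      zero = true;
      break;
    }
    if (s < 1e-12 || s > 1e12) {
      lik.row(p) /= s;
      logscale += std::log(s);
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("root_partial") = lik.row(root).t(),
      Rcpp::Named("logscale") = logscale,
      Rcpp::Named("zero") = zero);
  if (keep) {
    out["lik"] = lik;
    out["pm"] = pm;
    out["up_msg"] = up_msg;
  }
  return out;
}

// Transition matrix for external use (same engine as the likelihood).
// [[Rcpp::export(name = ".pmat_core")]]
arma::mat pmat_core(const arma::mat& Q, double t) {
  GenDecomp dec = decompose(Q);
  mat P = pmat(dec, t);
  for (uword i = 0; i < P.n_rows; ++i) {
    double s = accu(P.row(i));
    if (s > 0) P.row(i) /= s;
  }
  return P;
}
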