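// Codon-model likelihood engine: Felsenstein pruning over compressed site
// patterns on the 61 sense-codon state space, with site-class mixtures
// (branch-site models) and analytic branch-length gradients via a
// post-order/pre-order two-pass scheme.  Reversible GY-style matrices are
// exponentiated through symmetric eigendecomposition.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const int NSTATE = 61;

struct EigQ {
  mat V;    // diag(1/sqrt(pi)) * U
  mat W;    // U' * diag(sqrt(pi))
  vec lam;  // eigenvalues of the scaled generator
  mat Q;    // scaled generator (for gradients)
};

// unscaled mean substitution rate at stationarity
double mean_rate(const vec& pi, double kappa, double omega, const imat& pairs) {
  double mu = 0.0;
  for (uword k = 0; k < pairs.n_rows; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double r = (pairs(k, 2) ? kappa : 1.0) * (pairs(k, 3) ? 1.0 : omega);
    mu += 2.0 * r * pi(i) * pi(j);
  }
  return mu;
}

EigQ eig_codon(const vec& pi, double kappa, double omega, const imat& pairs,
               double scale) {
  mat Q(NSTATE, NSTATE, fill::zeros);
  for (uword k = 0; k < pairs.n_rows; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double r = (pairs(k, 2) ? kappa : 1.0) * (pairs(k, 3) ? 1.0 : omega);
    Q(i, j) = r * pi(j);
    Q(j, i) = r * pi(i);
  }
  Q.diag() = -sum(Q, 1);
  if (scale > 0) Q /= scale;
  vec d = sqrt(pi);
  mat B = Q;
  B.each_col() %= d;
  B.each_row() /= d.t();
  B = (B + B.t()) / 2.0;
  EigQ e;
  mat U;
  eig_sym(e.lam, U, B);
  e.V = U;
  e.V.each_col() /= d;
  e.W = U.t();
  e.W.each_row() %= d.t();
  e.Q = Q;
  return e;
}

mat pmat(const EigQ& e, double t) {
  mat P = e.V * (e.W.each_col() % exp(e.lam * t));
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List codon_loglik_engine(
    const arma::imat& states,       // ntip x npat, 0-based codon states, -1 missing
    const arma::vec& weights,       // npat
    const arma::imat& edges0,       // nedge x 2 (parent, child), postorder, 0-based
    const arma::vec& edge_len,
    const arma::ivec& edge_fg,      // 0/1 per edge
    const int n_node,
    const int root0,
    const arma::vec& pi,
    const double kappa,
    const arma::mat& class_omega,   // nclass x 2: (background, foreground) omega
    const arma::vec& class_prob,
    const arma::imat& pairs,
    const bool common_scale,
    const bool want_grad,
    const bool want_class_sitelik) {
  const int ntip = states.n_rows;
  const int npat = states.n_cols;
  const int nedge = edges0.n_rows;
  const int nclass = class_omega.n_rows;

  // one scale factor: per-matrix unit mean rate for single-class models,
  // mixture-averaged background mean rate for site-class mixtures
  std::map<double, double> scale_of;  // omega -> divisor
  if (common_scale && nclass > 1) {
    double mu = 0.0;
    for (int c = 0; c < nclass; ++c)
      mu += class_prob(c) * mean_rate(pi, kappa, class_omega(c, 0), pairs);
    for (int c = 0; c < nclass; ++c) {
      scale_of[class_omega(c, 0)] = mu;
      scale_of[class_omega(c, 1)] = mu;
    }
  } else {
    for (int c = 0; c < nclass; ++c)
      for (int s = 0; s < 2; ++s) {
        double om = class_omega(c, s);
        if (!scale_of.count(om)) scale_of[om] = mean_rate(pi, kappa, om, pairs);
      }
  }
  std::map<double, EigQ> eig_of;
  for (auto& kv : scale_of)
    eig_of.emplace(kv.first, eig_codon(pi, kappa, kv.first, pairs, kv.second));

  // tip partials shared by all classes
  std::vector<mat> tipL(ntip);
  for (int v = 0; v < ntip; ++v) {
    tipL[v] = mat(NSTATE, npat, fill::zeros);
    for (int s = 0; s < npat; ++s) {
      int st = states(v, s);
      if (st < 0)
        tipL[v].col(s).ones();
      else
        tipL[v](st, s) = 1.0;
    }
  }

  mat class_logf(nclass, npat, fill::zeros);
  mat grad_edge_acc(nedge, npat, fill::zeros);  // sum_c r_c * dlogf_c/dt_e
  vec grad_t(nedge, fill::zeros);
  vec grad_p(nclass, fill::zeros);
  cube grad_class;  // per-class dlogf/dt, reused buffer
  if (want_grad) grad_class.set_size(nedge, npat, nclass);
  bool degenerate = false;

  for (int c = 0; c < nclass && !degenerate; ++c) {
    // per-edge transition matrices and scaled generators
    std::vector<const EigQ*> eq(nedge);
    std::vector<mat> P(nedge);
    for (int e = 0; e < nedge; ++e) {
      double om = class_omega(c, edge_fg(e) ? 1 : 0);
      eq[e] = &eig_of.at(om);
      P[e] = pmat(*eq[e], edge_len(e));
    }

    // post-order pass; M[e] holds rescaled P_e * down[child]
    std::vector<mat> down(n_node), M(want_grad ? nedge : 0);
    mat logscale(n_node, npat, fill::zeros);
    std::vector<bool> seen(n_node, false);
    for (int v = 0; v < ntip; ++v) {
      down[v] = tipL[v];
      seen[v] = true;
    }
    for (int e = 0; e < nedge && !degenerate; ++e) {
      int u = edges0(e, 0), v = edges0(e, 1);
      mat Me = P[e] * down[v];
      rowvec ls = logscale.row(v);
      rowvec cmax = max(Me, 0);
      for (int s = 0; s < npat; ++s) {
        if (cmax(s) <= 0.0) { degenerate = true; break; }
        Me.col(s) /= cmax(s);
        ls(s) += std::log(cmax(s));
      }
      if (degenerate) break;
      if (!seen[u]) {
        down[u] = Me;
        logscale.row(u) = ls;
        seen[u] = true;
      } else {
        down[u] %= Me;
        logscale.row(u) += ls;
      }
      if (want_grad) M[e] = std::move(Me);
    }
    if (degenerate) break;

    rowvec froot = pi.t() * down[root0];
    for (int s = 0; s < npat; ++s) {
      if (froot(s) <= 0.0) { degenerate = true; break; }
      class_logf(c, s) = std::log(froot(s)) + logscale(root0, s);
    }
    if (degenerate) break;

    if (want_grad) {
      // pre-order pass: up[u] holds the partial from everything outside u's
      // subtree (root prior included); scalers cancel in the per-edge ratio
      std::vector<mat> up(n_node);
      up[root0] = mat(NSTATE, npat);
      up[root0].each_col() = pi;
      // children lists in the postorder edge array
      std::vector<std::vector<int>> child_edges(n_node);
      for (int e = 0; e < nedge; ++e) child_edges[edges0(e, 0)].push_back(e);
      for (int e = nedge - 1; e >= 0; --e) {
        int u = edges0(e, 0), v = edges0(e, 1);
        mat sib(NSTATE, npat, fill::ones);
        for (int e2 : child_edges[u])
          if (e2 != e) sib %= M[e2];
        mat T = up[u] % sib;
        mat dM = eq[e]->Q * M[e];
        rowvec num = sum(T % dM, 0);
        rowvec den = sum(T % M[e], 0);
        for (int s = 0; s < npat; ++s)
          grad_class(e, s, c) = den(s) > 0 ? num(s) / den(s) : 0.0;
        if (v >= ntip) {
          mat upv = P[e].t() * T;
          rowvec cmax = max(upv, 0);
          for (int s = 0; s < npat; ++s)
            if (cmax(s) > 0) upv.col(s) /= cmax(s);
          up[v] = std::move(upv);
        }
      }
    }
  }

  Rcpp::List out;
  if (degenerate) {
    out["loglik"] = R_NegInf;
    out["degenerate"] = true;
    return out;
  }

  // combine classes
  vec logp = log(class_prob);
  vec site_logf(npat);
  for (int s = 0; s < npat; ++s) {
    double m = -datum::inf;
    for (int c = 0; c < nclass; ++c)
      m = std::max(m, logp(c) + class_logf(c, s));
    double acc = 0.0;
    for (int c = 0; c < nclass; ++c)
      acc += std::exp(logp(c) + class_logf(c, s) - m);
    site_logf(s) = m + std::log(acc);
  }
  double loglik = dot(weights, site_logf);

  if (want_grad) {
    for (int s = 0; s < npat; ++s) {
      for (int c = 0; c < nclass; ++c) {
        double r = std::exp(logp(c) + class_logf(c, s) - site_logf(s));
        grad_p(c) += weights(s) * std::exp(class_logf(c, s) - site_logf(s));
        for (int e = 0; e < nedge; ++e)
          grad_edge_acc(e, s) += r * grad_class(e, s, c);
      }
    }
    grad_t = grad_edge_acc * weights;
  }

  out["loglik"] = loglik;
  out["site_loglik"] = site_logf;
  out["degenerate"] = false;
  if (want_class_sitelik) out["class_site_loglik"] = class_logf;
  if (want_grad) {
    out["grad_t"] = grad_t;
    out["grad_p"] = grad_p;
  }
  return out;
}
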