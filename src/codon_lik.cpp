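// Codon substitution model machinery: Goldman-Yang style rate matrix over
// the 61 sense codons (kappa transition/transversion ratio, omega
// nonsynonymous/synonymous ratio, arbitrary codon frequencies), transition
// probabilities via symmetric eigendecomposition, and Felsenstein pruning
// with per-node rescaling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// pairType codes: 0 none/diagonal, 1 syn transversion, 2 syn transition,
// 3 nonsyn transversion, 4 nonsyn transition.
static void build_eigen(const arma::imat& type, const arma::vec& pi,
                        double kappa, double omega,
                        arma::mat& U, arma::vec& d, arma::vec& sqp) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      int t = type(i, j);
      if (t == 0) continue;
      double r = pi(j);
      if (t == 2 || t == 4) r *= kappa;
      if (t >= 3) r *= omega;
      Q(i, j) = r;
    }
  }
  arma::vec rs = arma::sum(Q, 1);
  Q.diag() = -rs;
  double scale = arma::dot(pi, rs);
  if (scale <= 0) scale = 1e-12;
  Q /= scale;
  sqp = arma::sqrt(pi);
  arma::mat A(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A(i, j) = Q(i, j) * sqp(i) / sqp(j);
  A = 0.5 * (A + A.t());
  arma::eig_sym(d, U, A);
}

static arma::mat pmat_from_eigen(const arma::mat& U, const arma::vec& d,
                                 const arma::vec& sqp, double t) {
  arma::vec e = arma::exp(d * t);
  arma::mat M = U * arma::diagmat(e) * U.t();
  const int n = U.n_rows;
  arma::mat P(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      P(i, j) = M(i, j) * sqp(j) / sqp(i);
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

// [[Rcpp::export]]
arma::mat codon_pmat(const arma::imat& type, const arma::vec& pi,
                     double kappa, double omega, double t) {
  arma::mat U; arma::vec d, sqp;
  build_eigen(type, pi, kappa, omega, U, d, sqp);
  return pmat_from_eigen(U, d, sqp, t);
}

// Per-class, per-site conditional log-likelihoods by pruning.
// tips: ntaxa x nsite integer matrix, 1-based codon states, NA = missing.
// edge: nedge x 2 (parent, child), postorder, ape node numbering
// (tips 1..ntaxa, root = ntaxa+1). class_mult rescales branch lengths per
// class (relative substitution rate of the class under a common clock).
// [[Rcpp::export]]
arma::mat codon_class_loglik(const arma::imat& tips, const arma::imat& edge,
                             const arma::vec& elen, const arma::vec& pi,
                             double kappa, const arma::vec& omegas,
                             const arma::vec& class_mult,
                             const arma::imat& type, int nnode) {
  const int ntaxa = tips.n_rows;
  const int nsite = tips.n_cols;
  const int nstate = pi.n_elem;
  const int nedge = edge.n_rows;
  const int nclass = omegas.n_elem;
  const int root = ntaxa + 1;
  arma::mat out(nclass, nsite);

  for (int k = 0; k < nclass; ++k) {
    arma::mat U; arma::vec d, sqp;
    build_eigen(type, pi, kappa, omegas(k), U, d, sqp);

    std::vector<arma::mat> partial(ntaxa + nnode + 1);
    arma::mat logscale(ntaxa + nnode + 1, nsite, arma::fill::zeros);
    std::vector<bool> seen(ntaxa + nnode + 1, false);

    for (int e = 0; e < nedge; ++e) {
      int par = edge(e, 0);
      int chi = edge(e, 1);
      arma::mat P = pmat_from_eigen(U, d, sqp, elen(e) * class_mult(k));
      arma::mat cl;
      if (chi <= ntaxa) {
        cl.zeros(nstate, nsite);
        for (int s = 0; s < nsite; ++s) {
          int st = tips(chi - 1, s);
          if (st == NA_INTEGER || st < 1) cl.col(s).ones();
          else cl(st - 1, s) = 1.0;
        }
      } else {
        cl = partial[chi];
      }
      arma::mat up = P * cl;
      if (!seen[par]) {
        partial[par] = up;
        seen[par] = true;
      } else {
        partial[par] %= up;
      }
      if (chi > ntaxa) logscale.row(par) += logscale.row(chi);
      // rescale parent partials
      arma::rowvec mx = arma::max(partial[par], 0);
      for (int s = 0; s < nsite; ++s) {
        if (mx(s) > 0 && (mx(s) < 1e-100 || mx(s) > 1e100)) {
          partial[par].col(s) /= mx(s);
          logscale(par, s) += std::log(mx(s));
        }
      }
    }
    arma::rowvec lik = pi.t() * partial[root];
    for (int s = 0; s < nsite; ++s) {
      double v = lik(s);
      out(k, s) = (v > 0 ? std::log(v) : -1e300) + logscale(root, s);
    }
  }
  return out;
}
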