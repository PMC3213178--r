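// Mass-action kinetics kernels: reaction rates, dx/dt = S r(x,k), and the
// analytical Jacobian dF/dx and parameter-derivative dF/dk used by the
// stiff integrator and the forward sensitivity equations.
//
// The network is passed in a flat "compiled" form: one row per
// (reaction, reactant) incidence with 0-based species index `ri`, 0-based
// reaction index `rj` and kinetic exponent `re` (the reactant
// stoichiometric coefficient).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec monomials(const arma::vec& x,
                           const arma::ivec& ri,
                           const arma::ivec& rj,
                           const arma::vec& re,
                           int n_rxn) {
  arma::vec mono(n_rxn, arma::fill::ones);
  for (arma::uword e = 0; e < ri.n_elem; ++e) {
    mono(rj(e)) *= std::pow(x(ri(e)), re(e));
  }
  return mono;
}

// [[Rcpp::export(name = ".ma_rates")]]
arma::vec ma_rates(const arma::vec& x, const arma::vec& k,
                   const arma::ivec& ri, const arma::ivec& rj,
                   const arma::vec& re) {
  if (x.min() < 0.0) stop("negative concentration passed to mass-action rate");
  return k % monomials(x, ri, rj, re, k.n_elem);
}

// [[Rcpp::export(name = ".ma_rhs")]]
arma::vec ma_rhs(const arma::vec& x, const arma::vec& k, const arma::mat& S,
                 const arma::ivec& ri, const arma::ivec& rj,
                 const arma::vec& re) {
  return S * (k % monomials(x, ri, rj, re, k.n_elem));
}

// Analytical dF/dx and dF/dk at (x, k).
//
// dr_j/dx_s = k_j * sigma_s * x_s^(sigma_s - 1) * prod_{s' != s} x_{s'}^{sigma_{s'}}
// dr_j/dk_j = prod_s x_s^{sigma_s}   (the reaction monomial)
// J = S * dr/dx,  B = S * diag(mono)
// [[Rcpp::export(name = ".ma_jac_dfdk")]]
List ma_jac_dfdk(const arma::vec& x, const arma::vec& k, const arma::mat& S,
                 const arma::ivec& ri, const arma::ivec& rj,
                 const arma::vec& re,
                 bool want_jac, bool want_dfdk) {
  const int n_sp = S.n_rows, n_rxn = S.n_cols;
  arma::vec mono = monomials(x, ri, rj, re, n_rxn);

  List out;
  if (want_jac) {
    // group incidence entries by reaction (entries are few per reaction,
    // so the inner product over "other reactants" is cheap)
    std::vector< std::vector<arma::uword> > by_rxn(n_rxn);
    for (arma::uword e = 0; e < ri.n_elem; ++e) by_rxn[rj(e)].push_back(e);

    arma::mat dRdx(n_rxn, n_sp, arma::fill::zeros);
    for (int j = 0; j < n_rxn; ++j) {
      const std::vector<arma::uword>& ent = by_rxn[j];
      for (size_t a = 0; a < ent.size(); ++a) {
        const arma::uword ea = ent[a];
        double d = k(j) * re(ea) * std::pow(x(ri(ea)), re(ea) - 1.0);
        for (size_t b = 0; b < ent.size(); ++b) {
          if (b == a) continue;
          const arma::uword eb = ent[b];
          d *= std::pow(x(ri(eb)), re(eb));
        }
        dRdx(j, ri(ea)) += d;
      }
    }
    out["J"] = S * dRdx;
  }
  if (want_dfdk) {
    arma::mat B = S;
    B.each_row() %= mono.t();
    out["B"] = B;
  }
  out["rates"] = k % mono;
  return out;
}
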