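// Backpropagation-through-time core for the leaky recurrent network.
// Mirrors the reference R implementation in R/training.R (bptt_step); the
// two are cross-checked in the test suite. Population index ranges are
// contiguous, so all population access uses submatrix views.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".bptt_core")]]
List bptt_core(const arma::mat& W, const arma::vec& beta,
               const arma::cube& U, const arma::mat& z0,
               const arma::cube& gc, Nullable<NumericVector> smc_,
               const arma::uvec& gc_idx1, const arma::uvec& smc_idx1,
               const arma::uvec& input_idx1,
               double state_noise, bool rate_sup, bool want_grads) {
  const arma::uword d = W.n_rows;
  const arma::uword B = z0.n_cols;
  const arma::uword Tn = U.n_slices + 1;
  const arma::uword g0 = gc_idx1.min() - 1, g1 = gc_idx1.max() - 1;
  const arma::uword i0 = input_idx1.min() - 1, i1 = input_idx1.max() - 1;
  const arma::uword n_gc = g1 - g0 + 1;
  const bool has_smc = smc_idx1.n_elem > 0;
  const arma::uword s0 = has_smc ? smc_idx1.min() - 1 : 0;
  const arma::uword s1 = has_smc ? smc_idx1.max() - 1 : 0;
  const arma::uword n_smc = has_smc ? (s1 - s0 + 1) : 0;

  arma::cube smc;
  if (smc_.isNotNull() && has_smc) {
    NumericVector sv(smc_.get());
    IntegerVector dim = sv.attr("dim");
    smc = arma::cube(sv.begin(), dim[0], dim[1], dim[2]);
  }

  arma::vec a = 1.0 / (1.0 + arma::exp(-beta));
  arma::vec one_a = 1.0 - a;
  arma::mat A = arma::repmat(a, 1, B);
  arma::mat OA = arma::repmat(one_a, 1, B);

  arma::cube S(d, B, Tn), Fc(d, B, Tn - 1);
  arma::mat Z = z0, M(d, B);
  S.slice(0) = Z;
  for (arma::uword t = 0; t + 1 < Tn; ++t) {
    arma::mat& Fz = Fc.slice(t);
    Fz = Z;
    Fz.transform([](double v) { return v > 0 ? v : 0.0; });
    M = W * Fz;
    M.rows(i0, i1) += U.slice(t);
    Z = A % Z + OA % M;
    if (state_noise > 0) {
      NumericVector eps = rnorm(d * B, 0.0, state_noise);
      Z += arma::mat(eps.begin(), d, B);
    }
    S.slice(t + 1) = Z;
  }
  if (!Z.is_finite())
    stop("training diverged: non-finite state");

  const double norm_gc = (double)(Tn - 1) * n_gc * B;
  const double norm_smc = (double)(Tn - 1) * n_smc * B;
  arma::cube err_gc(n_gc, B, Tn - 1);
  arma::cube err_smc(n_smc, B, Tn - 1);
  double loss_gc = 0.0, loss_smc = 0.0;
  for (arma::uword t = 0; t + 1 < Tn; ++t) {
    arma::mat out = S.slice(t + 1).rows(g0, g1);
    if (rate_sup) out.transform([](double v) { return v > 0 ? v : 0.0; });
    err_gc.slice(t) = out - gc.slice(t + 1);
    loss_gc += arma::accu(arma::square(err_gc.slice(t)));
    if (has_smc) {
      arma::mat outs = S.slice(t + 1).rows(s0, s1);
      if (rate_sup) outs.transform([](double v) { return v > 0 ? v : 0.0; });
      err_smc.slice(t) = outs - smc.slice(t + 1);
      loss_smc += arma::accu(arma::square(err_smc.slice(t)));
    }
  }
  loss_gc /= norm_gc;
  if (has_smc) loss_smc /= norm_smc;

  if (!want_grads)
    return List::create(_["loss_gc"] = loss_gc, _["loss_smc"] = loss_smc,
                        _["states"] = S);

  arma::mat DN(d, B * (Tn - 1));
  arma::vec dbeta_acc(d, arma::fill::zeros);
  arma::mat delta(d, B, arma::fill::zeros);
  arma::mat dn(d, B), prop(d, B);
  for (arma::uword tt = Tn - 1; tt >= 1; --tt) {
    const arma::uword t = tt - 1; // err index for state tt
    const arma::mat& St1 = S.slice(tt);
    const arma::mat& St = S.slice(t);
    // supervision gradient (through the rectifier when supervising rates)
    arma::mat gg = err_gc.slice(t) * (2.0 / norm_gc);
    if (rate_sup) gg %= arma::conv_to<arma::mat>::from(St1.rows(g0, g1) > 0);
    delta.rows(g0, g1) += gg;
    if (has_smc) {
      arma::mat gs = err_smc.slice(t) * (2.0 / norm_smc);
      if (rate_sup) gs %= arma::conv_to<arma::mat>::from(St1.rows(s0, s1) > 0);
      delta.rows(s0, s1) += gs;
    }
    dn = OA % delta;
    DN.cols(t * B, t * B + B - 1) = dn;
    // d/d alpha: S_{t+1} = a S_t + (1-a) M_t  =>  dS/da = S_t - M_t
    arma::mat Mt = (St1 - A % St) / OA;
    dbeta_acc += arma::sum(delta % (St - Mt), 1);
    prop = W.t() * dn;
    prop %= arma::conv_to<arma::mat>::from(St > 0);
    delta = A % delta + prop;
  }
  arma::mat FC(Fc.memptr(), d, B * (Tn - 1), false);
  arma::mat dW = DN * FC.t();
  arma::vec dbeta = dbeta_acc % a % one_a;
  return List::create(_["loss_gc"] = loss_gc, _["loss_smc"] = loss_smc,
                      _["dW"] = dW, _["dbeta"] = dbeta);
}

// Forward rollout only (no gradients, no noise): used for evaluation.
// [[Rcpp::export(name = ".rollout_core")]]
arma::cube rollout_core(const arma::mat& W, const arma::vec& beta,
                        const arma::cube& U, const arma::mat& z0,
                        const arma::uvec& input_idx1) {
  const arma::uword d = W.n_rows;
  const arma::uword B = z0.n_cols;
  const arma::uword Tn = U.n_slices + 1;
  const arma::uword i0 = input_idx1.min() - 1, i1 = input_idx1.max() - 1;
  arma::vec a = 1.0 / (1.0 + arma::exp(-beta));
  arma::mat A = arma::repmat(a, 1, B);
  arma::mat OA = arma::repmat(1.0 - a, 1, B);
  arma::cube S(d, B, Tn);
  arma::mat Z = z0;
  S.slice(0) = Z;
  for (arma::uword t = 0; t + 1 < Tn; ++t) {
    arma::mat Fz = Z;
    Fz.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::mat M = W * Fz;
    M.rows(i0, i1) += U.slice(t);
    Z = A % Z + OA % M;
    S.slice(t + 1) = Z;
  }
  return S;
}
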