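// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Shallow spiking classifier with synaptic-conductance LIF output units:
//   Isyn[t] = alpha * Isyn[t-1] + x[t] W
//   U[t]    = beta * U[t-1] + Isyn[t] - S[t-1] * thr      (soft reset)
//   S[t]    = 1  iff  U[t] >= thr
// X: cube with slice t = batch x inputs; W: inputs x outputs;
// thr: per-output threshold (row vector).

static void snn_run(const arma::cube& X, const arma::mat& W,
                    const arma::rowvec& thr, double alpha, double beta,
                    arma::cube& Usav, arma::cube& Ssav) {
  const arma::uword T = X.n_slices, B = X.n_rows, J = W.n_cols;
  arma::mat Isyn(B, J, arma::fill::zeros);
  arma::mat U(B, J, arma::fill::zeros);
  arma::mat S(B, J, arma::fill::zeros);
  Usav.set_size(B, J, T);
  Ssav.set_size(B, J, T);
  for (arma::uword t = 0; t < T; ++t) {
    Isyn = alpha * Isyn + X.slice(t) * W;
    U = beta * U + Isyn - (S.each_row() % thr);  // soft reset of previous step
    arma::mat diff = U;
    diff.each_row() -= thr;
    S = arma::conv_to<arma::mat>::from(diff >= 0);
    Usav.slice(t) = U;
    Ssav.slice(t) = S;
  }
}

// [[Rcpp::export]]
List snn_forward_cpp(arma::cube X, arma::mat W, arma::rowvec thr,
                     double alpha, double beta, bool return_spikes = false) {
  arma::cube Usav, Ssav;
  snn_run(X, W, thr, alpha, beta, Usav, Ssav);
  arma::mat counts = arma::sum(Ssav, 2);
  if (return_spikes)
    return List::create(_["counts"] = counts, _["spikes"] = Ssav,
                        _["membrane"] = Usav);
  return List::create(_["counts"] = counts);
}

// Fused forward + backward-through-time with fast-sigmoid surrogate
// derivative dS/dU = 1 / (1 + slope * |U - thr|)^2. Two losses:
//   loss_type 0: MSE spike-count, L = mean_b mean_j (C_j/T - target_j)^2
//   loss_type 1: cross-entropy on counts as logits (targets one-hot)
// [[Rcpp::export]]
List snn_grad_cpp(arma::cube X, arma::mat W, arma::rowvec thr,
                  double alpha, double beta, arma::mat targets,
                  double slope, int loss_type = 0) {
  const arma::uword T = X.n_slices, B = X.n_rows, J = W.n_cols;
  arma::cube Usav, Ssav;
  snn_run(X, W, thr, alpha, beta, Usav, Ssav);
  arma::mat counts = arma::sum(Ssav, 2);

  double loss;
  arma::mat dC;                                      // dL/dS[t] direct term
  if (loss_type == 0) {
    arma::mat err = counts / (double)T - targets;    // batch x outputs
    loss = arma::accu(err % err) / (double)(B * J);
    dC = 2.0 * err / (double)(T * B * J);
  } else {
    arma::mat z = counts.each_col() - arma::max(counts, 1);
    arma::mat ez = arma::exp(z);
    arma::mat p = ez.each_col() / arma::sum(ez, 1);
    loss = -arma::accu(targets % arma::log(p + 1e-12)) / (double)B;
    dC = (p - targets) / (double)B;
  }

  arma::mat gW(W.n_rows, J, arma::fill::zeros);
  arma::rowvec gthr(J, arma::fill::zeros);
  arma::mat lamU_next(B, J, arma::fill::zeros);
  arma::mat lamI_next(B, J, arma::fill::zeros);

  for (arma::uword tt = T; tt-- > 0;) {
    arma::mat diff = Usav.slice(tt);
    diff.each_row() -= thr;
    arma::mat surr = 1.0 / arma::square(1.0 + slope * arma::abs(diff));

    arma::mat dS = dC;
    if (tt + 1 < T) dS -= lamU_next.each_row() % thr;

    arma::mat lamU = dS % surr + beta * lamU_next;
    arma::mat lamI = lamU + alpha * lamI_next;

    gW += X.slice(tt).t() * lamI;
    gthr -= arma::sum(dS % surr, 0);
    if (tt > 0) gthr -= arma::sum(lamU % Ssav.slice(tt - 1), 0);

    lamU_next = lamU;
    lamI_next = lamI;
  }

  return List::create(_["loss"] = loss, _["counts"] = counts,
                      _["gW"] = gW, _["gthr"] = gthr);
}
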