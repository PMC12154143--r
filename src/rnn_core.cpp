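// Core numerics for the leaky recurrent network: forward simulation and the
// backpropagation-through-time gradient.  Kept in C++ because the per-timestep
// recursion cannot be vectorised in R and dominates the cost of training.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One forward pass of h_{t+1} = (1-g) h_t + g * tanh(wIn x_t + wRec h_t + b + xi_t),
// y_t = wOut . h_t + bOut.  X is T x 2, Xi is T x N (or 0 x 0 for no unit noise).
// h0 is the state *before* the first input bin.
// [[Rcpp::export]]
List cpp_rnn_forward(const arma::mat& wIn, const arma::mat& wRec,
                     const arma::vec& b, const arma::vec& wOut, double bOut,
                     double gamma, const arma::mat& X, const arma::mat& Xi,
                     const arma::vec& h0) {
  const arma::uword T = X.n_rows, N = wRec.n_rows;
  const bool noise = Xi.n_rows == T;
  arma::mat H(T, N);
  arma::vec h = h0;
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec a = wIn * X.row(t).t() + wRec * h + b;
    if (noise) a += Xi.row(t).t();
    h = (1.0 - gamma) * h + gamma * arma::tanh(a);
    H.row(t) = h.t();
  }
  arma::vec y = H * wOut + bOut;
  return List::create(_["hidden"] = H, _["output"] = y);
}

// Autonomous run with the input clamped to a fixed vector and noise off.
// [[Rcpp::export]]
arma::mat cpp_free_run(const arma::mat& wIn, const arma::mat& wRec,
                       const arma::vec& b, double gamma,
                       const arma::vec& h0, const arma::vec& x, int nSteps) {
  const arma::uword N = wRec.n_rows;
  arma::mat H(nSteps, N);
  arma::vec drive = wIn * x + b;
  arma::vec h = h0;
  for (int t = 0; t < nSteps; ++t) {
    h = (1.0 - gamma) * h + gamma * arma::tanh(drive + wRec * h);
    H.row(t) = h.t();
  }
  return H;
}

// Loss and analytic BPTT gradient for a single trial.
// loss = mean_t (y_t - z_t)^2 + lambda * mean_{t,i} h_{t,i}^2
//        + lambda * (||wIn||^2 + ||wRec||^2 + ||wOut||^2)
// The tanh pre-activation output s_t is recovered from the stored states via
// s_t = (h_t - (1-gamma) h_{t-1}) / gamma, avoiding a second T x N buffer.
// [[Rcpp::export]]
List cpp_bptt_grad(const arma::mat& wIn, const arma::mat& wRec,
                   const arma::vec& b, const arma::vec& wOut, double bOut,
                   double gamma, const arma::mat& X, const arma::mat& Xi,
                   const arma::vec& target, double lambda) {
  const arma::uword T = X.n_rows, N = wRec.n_rows;
  const bool noise = Xi.n_rows == T;

  arma::mat H(T, N);
  arma::vec h(N, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec a = wIn * X.row(t).t() + wRec * h + b;
    if (noise) a += Xi.row(t).t();
    h = (1.0 - gamma) * h + gamma * arma::tanh(a);
    H.row(t) = h.t();
  }
  arma::vec y = H * wOut + bOut;
  arma::vec err = y - target;

  double mse = arma::mean(arma::square(err));
  double actPen = arma::accu(arma::square(H)) / (double)(T * N);
  double wPen = arma::accu(arma::square(wIn)) + arma::accu(arma::square(wRec)) +
                arma::accu(arma::square(wOut));
  double loss = mse + lambda * actPen + lambda * wPen;

  arma::vec dy = 2.0 * err / (double)T;

  arma::mat gWIn(arma::size(wIn), arma::fill::zeros);
  arma::mat gWRec(arma::size(wRec), arma::fill::zeros);
  arma::vec gB(N, arma::fill::zeros);
  arma::vec gWOut = H.t() * dy + 2.0 * lambda * wOut;
  double gBOut = arma::accu(dy);

  const double actCoef = 2.0 * lambda / (double)(T * N);
  arma::vec delta(N, arma::fill::zeros);   // dL/dh_t carried backwards
  arma::mat wRecT = wRec.t();
  for (arma::uword ti = T; ti-- > 0;) {
    arma::vec ht = H.row(ti).t();
    arma::vec hprev = (ti == 0) ? arma::vec(N, arma::fill::zeros)
                                : arma::vec(H.row(ti - 1).t());
    delta += wOut * dy(ti) + actCoef * ht;
    arma::vec s = (ht - (1.0 - gamma) * hprev) / gamma;  // = tanh(a_t)
    arma::vec g = gamma * (1.0 - arma::square(s)) % delta;
    gWRec += g * hprev.t();
    gWIn += g * X.row(ti);
    gB += g;
    delta = (1.0 - gamma) * delta + wRecT * g;
  }
  gWIn += 2.0 * lambda * wIn;
  gWRec += 2.0 * lambda * wRec;

  return List::create(_["gWIn"] = gWIn, _["gWRec"] = gWRec, _["gB"] = gB,
                      _["gWOut"] = gWOut, _["gBOut"] = gBOut,
                      _["loss"] = loss, _["mse"] = mse);
}
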