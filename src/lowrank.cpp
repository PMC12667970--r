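#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Forward-Euler integration of the low-rank rate network
//   tau * dr/dt = -r + phi(U A U' r + I(t)),  phi_i(x) = rmax_i/2 (tanh(x)+1).
// The recurrent term is evaluated through the factors (U, A) so the N x N
// connectivity is never materialised.
//
// U      N x P low-rank basis
// A      P x P interaction matrix
// rmax   length-N maximum rates (spikes/s)
// r0     length-N initial rates
// alpha  dt/tau (scalar)
// Ifull  T x N external input; row t drives the step t -> t+1 (last row unused)
//
// Returns rates (T x N, row t = state at grid point t) and th (T-1 x N,
// tanh of the net input at each step; reused by the backward pass).
// [[Rcpp::export]]
Rcpp::List lr_forward_cpp(const arma::mat& U, const arma::mat& A,
                          const arma::vec& rmax, const arma::vec& r0,
                          double alpha, const arma::mat& Ifull) {
  const uword T = Ifull.n_rows, N = U.n_rows;
  mat R(T, N), TH(T > 1 ? T - 1 : 0, N);
  R.row(0) = r0.t();
  const mat UA = U * A;  // N x P
  for (uword t = 0; t + 1 < T; ++t) {
    vec m = U.t() * R.row(t).t();
    vec h = UA * m + Ifull.row(t).t();
    vec th = tanh(h);
    TH.row(t) = th.t();
    vec phi = 0.5 * rmax % (th + 1.0);
    R.row(t + 1) = (1.0 - alpha) * R.row(t) + alpha * phi.t();
  }
  return Rcpp::List::create(Rcpp::Named("rates") = R, Rcpp::Named("th") = TH);
}

// Reverse-mode gradient of a loss L(r_1, ..., r_T) through the Euler
// recursion above. Gr holds the direct derivatives dL/dr_t (T x N).
// Returns gradients with respect to U, A, rmax, the initial state r0, and
// the external input at every step (gI, T x N; last row zero). Gradients of
// inputs that are themselves parameterised (task inputs U*i, lick vectors,
// per-trial biases) are recovered in R from gI by the chain rule.
// [[Rcpp::export]]
Rcpp::List lr_backward_cpp(const arma::mat& U, const arma::mat& A,
                           const arma::vec& rmax, double alpha,
                           const arma::mat& R, const arma::mat& TH,
                           const arma::mat& Gr) {
  const uword T = R.n_rows, N = U.n_rows, P = U.n_cols;
  mat gU(N, P, fill::zeros), gA(P, P, fill::zeros), gI(T, N, fill::zeros);
  vec grmax(N, fill::zeros);
  vec g = Gr.row(T - 1).t();  // dL/dr_T
  for (sword t = T - 2; t >= 0; --t) {
    vec th = TH.row(t).t();
    // phi'(h) with respect to its argument
    vec phip = 0.5 * rmax % (1.0 - th % th);
    vec w = alpha * (phip % g);                  // dL/dh_t
    grmax += 0.5 * alpha * ((th + 1.0) % g);     // phi depends linearly on rmax
    gI.row(t) = w.t();
    vec rt = R.row(t).t();
    vec m = U.t() * rt;  // U' r_t
    vec q = U.t() * w;   // U' w
    gA += q * m.t();
    gU += w * (A * m).t() + rt * (A.t() * q).t();
    g = Gr.row(t).t() + (1.0 - alpha) * g + U * (A.t() * q);
  }
  return Rcpp::List::create(
      Rcpp::Named("gU") = gU, Rcpp::Named("gA") = gA,
      Rcpp::Named("grmax") = grmax, Rcpp::Named("gr0") = g,
      Rcpp::Named("gI") = gI);
}
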