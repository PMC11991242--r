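// Time-loop kernels for the stacked GRU: one layer's forward pass and its
// backpropagation-through-time sweep. Everything stochastic (init, dropout,
// shuffling) stays on the R side; these kernels are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Forward one layer over T steps from zero initial state.
// Xflat: (N*T) x I, time-major blocks of N rows.
// Wall: 3W x I (rows: reset, update, candidate input weights).
// Uall: 3W x W (recurrent weights, same order).
// bx: 3W input-side biases (b_r, b_z, b_h); cu: 3W recurrent-side biases
// (c_r, c_z, c_h).
// [[Rcpp::export]]
Rcpp::List gru_layer_forward_cpp(const arma::mat& Xflat, const arma::mat& Wall,
                                 const arma::mat& Uall, const arma::vec& bx,
                                 const arma::vec& cu, int N, int T,
                                 bool keep_cache) {
  const int W = Uall.n_cols;
  mat Ax = Xflat * Wall.t();          // (N*T) x 3W
  Ax.each_row() += bx.t();
  rowvec cut = cu.t();

  mat H(N, W, fill::zeros);
  mat out(N * T, W);
  mat Rc, Zc, Uc, HCc, HPc;
  if (keep_cache) {
    Rc.set_size(N * T, W); Zc.set_size(N * T, W);
    Uc.set_size(N * T, W); HCc.set_size(N * T, W);
    HPc.set_size(N * T, W);
  }
  for (int t = 0; t < T; ++t) {
    const int r0 = t * N, r1 = (t + 1) * N - 1;
    mat B = H * Uall.t();             // N x 3W
    B.each_row() += cut;
    mat pre = Ax.rows(r0, r1) + B;
    mat r = 1.0 / (1.0 + exp(-pre.cols(0, W - 1)));
    mat z = 1.0 / (1.0 + exp(-pre.cols(W, 2 * W - 1)));
    mat u = B.cols(2 * W, 3 * W - 1);
    mat hc = tanh(Ax.submat(r0, 2 * W, r1, 3 * W - 1) + r % u);
    if (keep_cache) {
      Rc.rows(r0, r1) = r; Zc.rows(r0, r1) = z;
      Uc.rows(r0, r1) = u; HCc.rows(r0, r1) = hc;
      HPc.rows(r0, r1) = H;
    }
    H = (1.0 - z) % H + z % hc;
    out.rows(r0, r1) = H;
  }
  if (keep_cache) {
    return Rcpp::List::create(
      Rcpp::Named("out") = out, Rcpp::Named("r") = Rc,
      Rcpp::Named("z") = Zc, Rcpp::Named("u") = Uc,
      Rcpp::Named("hc") = HCc, Rcpp::Named("hprev") = HPc);
  }
  return Rcpp::List::create(Rcpp::Named("out") = out);
}

// Reverse-time sweep for one layer. dOut: (N*T) x W gradient wrt the
// layer's output sequence. Returns the fused weight gradients and the
// gradient wrt the layer input.
// [[Rcpp::export]]
Rcpp::List gru_layer_backward_cpp(const arma::mat& dOut, const arma::mat& Xflat,
                                  const arma::mat& Wall, const arma::mat& Uall,
                                  const arma::mat& Rc, const arma::mat& Zc,
                                  const arma::mat& Uc, const arma::mat& HCc,
                                  const arma::mat& HPc, int N, int T) {
  const int W = Uall.n_cols;
  mat Gx(N * T, 3 * W);   // dar | daz | dah  (input-side rows)
  mat Gu(N * T, 3 * W);   // dar | daz | du   (recurrent-side rows)
  mat carry(N, W, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const int r0 = t * N, r1 = (t + 1) * N - 1;
    mat r = Rc.rows(r0, r1), z = Zc.rows(r0, r1), u = Uc.rows(r0, r1);
    mat hc = HCc.rows(r0, r1), Hprev = HPc.rows(r0, r1);
    mat dHn = dOut.rows(r0, r1) + carry;
    mat dz = dHn % (hc - Hprev);
    mat dhc = dHn % z;
    mat dah = dhc % (1.0 - hc % hc);
    mat dr = dah % u;
    mat du = dah % r;
    mat dar = dr % r % (1.0 - r);
    mat daz = dz % z % (1.0 - z);
    Gx.submat(r0, 0, r1, W - 1) = dar;
    Gx.submat(r0, W, r1, 2 * W - 1) = daz;
    Gx.submat(r0, 2 * W, r1, 3 * W - 1) = dah;
    Gu.submat(r0, 0, r1, W - 1) = dar;
    Gu.submat(r0, W, r1, 2 * W - 1) = daz;
    Gu.submat(r0, 2 * W, r1, 3 * W - 1) = du;
    carry = dHn % (1.0 - z) + Gu.rows(r0, r1) * Uall;
  }
  mat GW = Gx.t() * Xflat;            // 3W x I
  mat GU = Gu.t() * HPc;              // 3W x W
  vec bx = sum(Gx, 0).t();
  vec bu = sum(Gu, 0).t();
  mat dX = Gx * Wall;                 // (N*T) x I
  return Rcpp::List::create(
    Rcpp::Named("GW") = GW, Rcpp::Named("GU") = GU,
    Rcpp::Named("bx") = bx, Rcpp::Named("bu") = bu,
    Rcpp::Named("dX") = dX);
}
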