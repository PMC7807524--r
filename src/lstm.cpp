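// Peephole LSTM layer: batched sequence forward pass and backpropagation
// through time. One layer; stacking and the optimizer live on the R side.
//
// Cell equations (per time step, elementwise over H cells, batch in columns):
//   a_i = Wxi x_t + Whi h_{t-1} + p_i .* s_{t-1} + b_i ;  i_t = sigma(a_i)
//   a_f = Wxf x_t + Whf h_{t-1} + p_f .* s_{t-1} + b_f ;  f_t = sigma(a_f)
//   a_c = Wxc x_t + Whc h_{t-1}               + b_c    ;  g_t = tanh(a_c)
//   s_t = f_t .* s_{t-1} + i_t .* g_t
//   a_o = Wxo x_t + Who h_{t-1} + p_o .* s_t  + b_o    ;  o_t = sigma(a_o)
//   h_t = o_t .* tanh(s_t)
// The output-gate peephole reads the CURRENT cell value s_t; the input- and
// forget-gate peepholes read s_{t-1}. Peepholes are diagonal (one weight per
// cell). Biases may be zero vectors, in which case the step reproduces the
// bias-free printed form of the forward equations exactly.
//
// For speed on a single core the four gates are stacked into one 4H-row
// block (row order i, f, c, o): the input projection for every time step is
// one GEMM, and each recurrent step needs a single GEMM instead of four.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// alias the cube memory as an (R x C*T) matrix without copying
static inline arma::mat flat(const arma::cube& c) {
  return arma::mat(const_cast<double*>(c.memptr()),
                   c.n_rows, c.n_cols * c.n_slices, false, true);
}

// X: cube I x B x T (slice t = inputs at step t, batch in columns)
// h0, s0: H x B initial state. Returns all gate activations and states,
// which the backward pass consumes as its cache.
// [[Rcpp::export(name = ".lstm_layer_forward_cpp")]]
List lstm_layer_forward_cpp(const arma::cube& X,
                            const arma::mat& Wxi, const arma::mat& Whi,
                            const arma::vec& pi_, const arma::vec& bi,
                            const arma::mat& Wxf, const arma::mat& Whf,
                            const arma::vec& pf, const arma::vec& bf,
                            const arma::mat& Wxo, const arma::mat& Who,
                            const arma::vec& po, const arma::vec& bo,
                            const arma::mat& Wxc, const arma::mat& Whc,
                            const arma::vec& bc,
                            const arma::mat& h0, const arma::mat& s0) {
  const arma::uword T = X.n_slices, B = X.n_cols, H = Wxi.n_rows;

  const arma::mat Wx = arma::join_cols(Wxi, Wxf, Wxc, Wxo);   // 4H x I
  const arma::mat Wh = arma::join_cols(Whi, Whf, Whc, Who);   // 4H x H
  const arma::vec bb = arma::join_cols(bi, bf, bc, bo);       // 4H

  // input contribution for all steps at once: 4H x (B*T)
  arma::mat pre = Wx * flat(X);
  pre.each_col() += bb;

  arma::cube I_(H, B, T), F_(H, B, T), O_(H, B, T), G_(H, B, T);
  arma::cube S_(H, B, T), Hh(H, B, T);

  arma::mat a(4 * H, B);
  const arma::mat* h_prev = &h0;
  const arma::mat* s_prev = &s0;
  for (arma::uword t = 0; t < T; ++t) {
    a = pre.cols(t * B, t * B + B - 1) + Wh * (*h_prev);
    arma::mat ai = a.rows(0, H - 1);
    arma::mat af = a.rows(H, 2 * H - 1);
    arma::mat ac = a.rows(2 * H, 3 * H - 1);
    arma::mat ao = a.rows(3 * H, 4 * H - 1);
    ai += s_prev->each_col() % pi_;
    af += s_prev->each_col() % pf;

    I_.slice(t) = sigm(ai);
    F_.slice(t) = sigm(af);
    G_.slice(t) = arma::tanh(ac);
    S_.slice(t) = F_.slice(t) % (*s_prev) + I_.slice(t) % G_.slice(t);
    ao += S_.slice(t).each_col() % po;
    O_.slice(t) = sigm(ao);
    Hh.slice(t) = O_.slice(t) % arma::tanh(S_.slice(t));

    h_prev = &Hh.slice(t);
    s_prev = &S_.slice(t);
  }
  return List::create(_["i"] = I_, _["f"] = F_, _["o"] = O_, _["g"] = G_,
                      _["s"] = S_, _["h"] = Hh);
}

// dH: cube H x B x T, external dL/dh_t at every step (zero except the last
// slice when only the final hidden output feeds the readout).
// Returns weight gradients, dX (for a lower layer), and dh0/ds0.
// [[Rcpp::export(name = ".lstm_layer_backward_cpp")]]
List lstm_layer_backward_cpp(const arma::cube& X,
                             const arma::cube& I_, const arma::cube& F_,
                             const arma::cube& O_, const arma::cube& G_,
                             const arma::cube& S_, const arma::cube& Hh,
                             const arma::mat& Whi, const arma::mat& Whf,
                             const arma::mat& Who, const arma::mat& Whc,
                             const arma::mat& Wxi, const arma::mat& Wxf,
                             const arma::mat& Wxo, const arma::mat& Wxc,
                             const arma::vec& pi_, const arma::vec& pf,
                             const arma::vec& po,
                             const arma::mat& h0, const arma::mat& s0,
                             const arma::cube& dH) {
  const arma::uword T = X.n_slices, B = X.n_cols;
  const arma::uword H = Whi.n_rows, Iin = Wxi.n_cols;

  const arma::mat Wh = arma::join_cols(Whi, Whf, Whc, Who);   // 4H x H
  const arma::mat Wx = arma::join_cols(Wxi, Wxf, Wxc, Wxo);   // 4H x I

  arma::cube DA(4 * H, B, T);   // stacked gate pre-activation gradients
  arma::vec dpi(H, arma::fill::zeros), dpf(H, arma::fill::zeros),
            dpo(H, arma::fill::zeros);

  arma::mat dh_rec(H, B, arma::fill::zeros), ds_rec(H, B, arma::fill::zeros);

  for (arma::uword tt = T; tt-- > 0;) {
    const arma::mat& it = I_.slice(tt);
    const arma::mat& ft = F_.slice(tt);
    const arma::mat& ot = O_.slice(tt);
    const arma::mat& gt = G_.slice(tt);
    const arma::mat& st = S_.slice(tt);
    const arma::mat& s_prev = (tt == 0) ? s0 : S_.slice(tt - 1);

    arma::mat tanh_s = arma::tanh(st);
    arma::mat dh = dH.slice(tt) + dh_rec;

    arma::mat da_o = (dh % tanh_s) % (ot % (1.0 - ot));
    // s_t feeds h_t (through tanh), the future step, and the output gate's
    // own peephole.
    arma::mat ds = dh % ot % (1.0 - tanh_s % tanh_s) + ds_rec
                 + da_o.each_col() % po;
    arma::mat da_i = (ds % gt) % (it % (1.0 - it));
    arma::mat da_c = (ds % it) % (1.0 - gt % gt);
    arma::mat da_f = (ds % s_prev) % (ft % (1.0 - ft));

    ds_rec = ds % ft + da_i.each_col() % pi_ + da_f.each_col() % pf;

    DA.slice(tt).rows(0, H - 1) = da_i;
    DA.slice(tt).rows(H, 2 * H - 1) = da_f;
    DA.slice(tt).rows(2 * H, 3 * H - 1) = da_c;
    DA.slice(tt).rows(3 * H, 4 * H - 1) = da_o;

    dh_rec = Wh.t() * DA.slice(tt);

    dpi += arma::sum(da_i % s_prev, 1);
    dpf += arma::sum(da_f % s_prev, 1);
    dpo += arma::sum(da_o % st, 1);
  }

  // batched weight gradients: previous hidden states as one (H x B*T) block
  arma::cube Hprev(H, B, T);
  Hprev.slice(0) = h0;
  if (T > 1) {
    Hprev.slices(1, T - 1) = Hh.slices(0, T - 2);
  }
  arma::mat DAm = flat(DA);                       // 4H x B*T
  arma::mat dWx = DAm * flat(X).t();              // 4H x I
  arma::mat dWh = DAm * flat(Hprev).t();          // 4H x H
  arma::vec db = arma::sum(DAm, 1);               // 4H

  arma::mat dXm = Wx.t() * DAm;                   // I x B*T
  arma::cube dX(Iin, B, T);
  std::memcpy(dX.memptr(), dXm.memptr(), sizeof(double) * dXm.n_elem);

  return List::create(
    _["dWxi"] = dWx.rows(0, H - 1), _["dWhi"] = dWh.rows(0, H - 1),
    _["dpi"] = dpi, _["dbi"] = db.subvec(0, H - 1),
    _["dWxf"] = dWx.rows(H, 2 * H - 1), _["dWhf"] = dWh.rows(H, 2 * H - 1),
    _["dpf"] = dpf, _["dbf"] = db.subvec(H, 2 * H - 1),
    _["dWxo"] = dWx.rows(3 * H, 4 * H - 1),
    _["dWho"] = dWh.rows(3 * H, 4 * H - 1),
    _["dpo"] = dpo, _["dbo"] = db.subvec(3 * H, 4 * H - 1),
    _["dWxc"] = dWx.rows(2 * H, 3 * H - 1),
    _["dWhc"] = dWh.rows(2 * H, 3 * H - 1),
    _["dbc"] = db.subvec(2 * H, 3 * H - 1),
    _["dX"] = dX, _["dh0"] = dh_rec, _["ds0"] = ds_rec);
}
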