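// Performance-critical kernels of the network backend: 1-D same-padding
// convolution (im2col + BLAS) and the GELU activation. Array layout is
// channels x time x batch, matching the R side; convolution weights are
// F x (C*k) with kernel position fastest within each input channel block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col(const mat& xs, int k, int p1, mat& M) {
  const int C = xs.n_rows, T = xs.n_cols;
  mat xp(C, T + k - 1, fill::zeros);
  xp.cols(p1, p1 + T - 1) = xs;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      M.row(j + k * c) = xp.row(c).subvec(j, j + T - 1);
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_forward(const arma::cube& x, const arma::mat& W,
                              const arma::vec& b) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int k = W.n_cols / C;
  const int p1 = (k - 1) / 2;
  cube out(W.n_rows, T, B);
  mat M(k * C, T);
  for (int bi = 0; bi < B; ++bi) {
    im2col(x.slice(bi), k, p1, M);
    out.slice(bi) = W * M;
    out.slice(bi).each_col() += b;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_backward(const arma::cube& dout, const arma::cube& x,
                               const arma::mat& W) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int k = W.n_cols / C;
  const int p1 = (k - 1) / 2;
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_rows, fill::zeros);
  cube dx(C, T, B);
  mat M(k * C, T);
  for (int bi = 0; bi < B; ++bi) {
    im2col(x.slice(bi), k, p1, M);
    const mat& dsl = dout.slice(bi);
    dW += dsl * M.t();
    db += sum(dsl, 1);
    mat dM = W.t() * dsl;                       // (k*C) x T
    mat dxp(C, T + k - 1, fill::zeros);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < k; ++j)
        dxp.row(c).subvec(j, j + T - 1) += dM.row(j + k * c);
    dx.slice(bi) = dxp.cols(p1, p1 + T - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// tanh-approximation GELU; returns the activation and the cached tanh term
// reused by the backward pass
// [[Rcpp::export]]
Rcpp::List cpp_gelu_forward(const Rcpp::NumericVector& x) {
  const double c0 = 0.7978845608028654, c1 = 0.044715;
  Rcpp::NumericVector out(x.size()), th(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double t = std::tanh(c0 * (xi + c1 * xi * xi * xi));
    th[i] = t;
    out[i] = 0.5 * xi * (1.0 + t);
  }
  out.attr("dim") = x.attr("dim");
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("th") = th);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_gelu_backward(const Rcpp::NumericVector& dout,
                                      const Rcpp::NumericVector& x,
                                      const Rcpp::NumericVector& th) {
  const double c0 = 0.7978845608028654, c1 = 0.044715;
  Rcpp::NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double xi = x[i], t = th[i];
    double du = c0 * (1.0 + 3.0 * c1 * xi * xi);
    dx[i] = dout[i] * (0.5 * (1.0 + t) + 0.5 * xi * (1.0 - t * t) * du);
  }
  dx.attr("dim") = dout.attr("dim");
  return dx;
}

// max-pool size 2, stride 2 over time; mask marks where the first element
// of each pair won
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_forward(const arma::cube& x) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int T2 = T / 2;
  cube out(C, T2, B), mask(C, T2, B);
  for (int bi = 0; bi < B; ++bi)
    for (int t = 0; t < T2; ++t)
      for (int c = 0; c < C; ++c) {
        double a = x(c, 2 * t, bi), b = x(c, 2 * t + 1, bi);
        bool first = a >= b;
        out(c, t, bi) = first ? a : b;
        mask(c, t, bi) = first ? 1.0 : 0.0;
      }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("mask") = mask);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube& dout,
                                 const arma::cube& mask, int T) {
  const int C = dout.n_rows, T2 = dout.n_cols, B = dout.n_slices;
  cube dx(C, T, B, fill::zeros);
  for (int bi = 0; bi < B; ++bi)
    for (int t = 0; t < T2; ++t)
      for (int c = 0; c < C; ++c) {
        if (mask(c, t, bi) > 0.5) dx(c, 2 * t, bi) = dout(c, t, bi);
        else dx(c, 2 * t + 1, bi) = dout(c, t, bi);
      }
  return dx;
}

// single-head scaled dot-product self-attention over time
// [[Rcpp::export]]
Rcpp::List cpp_attention_forward(const arma::cube& x, const arma::mat& Wq,
                                 const arma::mat& Wk, const arma::mat& Wv,
                                 const arma::mat& Wo) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const double sc = 1.0 / std::sqrt((double)C);
  cube out(C, T, B), attn(T, T, B), Qc(C, T, B), Kc(C, T, B), Vc(C, T, B),
      Oc(C, T, B);
  for (int bi = 0; bi < B; ++bi) {
    const mat& X = x.slice(bi);
    mat Q = Wq * X, K = Wk * X, V = Wv * X;
    mat S = (Q.t() * K) * sc;            // rows = query positions
    vec mx = max(S, 1);
    S.each_col() -= mx;
    mat A = exp(S);
    A.each_col() /= sum(A, 1);
    mat O = V * A.t();
    out.slice(bi) = Wo * O;
    attn.slice(bi) = A;
    Qc.slice(bi) = Q; Kc.slice(bi) = K; Vc.slice(bi) = V; Oc.slice(bi) = O;
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("attn") = attn,
                            Rcpp::Named("Q") = Qc, Rcpp::Named("K") = Kc,
                            Rcpp::Named("V") = Vc, Rcpp::Named("O") = Oc);
}

// [[Rcpp::export]]
Rcpp::List cpp_attention_backward(const arma::cube& dout, const arma::cube& x,
                                  const arma::cube& Qc, const arma::cube& Kc,
                                  const arma::cube& Vc, const arma::cube& Oc,
                                  const arma::cube& attn, const arma::mat& Wq,
                                  const arma::mat& Wk, const arma::mat& Wv,
                                  const arma::mat& Wo) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const double sc = 1.0 / std::sqrt((double)C);
  mat dWq(C, C, fill::zeros), dWk(C, C, fill::zeros), dWv(C, C, fill::zeros),
      dWo(C, C, fill::zeros);
  cube dx(C, T, B);
  for (int bi = 0; bi < B; ++bi) {
    const mat& X = x.slice(bi);
    const mat& A = attn.slice(bi);
    const mat& dY = dout.slice(bi);
    dWo += dY * Oc.slice(bi).t();
    mat dO = Wo.t() * dY;
    mat dV = dO * A;
    mat dA = dO.t() * Vc.slice(bi);
    vec rs = sum(dA % A, 1);
    dA.each_col() -= rs;
    mat dS = (A % dA) * sc;
    mat dQ = Kc.slice(bi) * dS.t();
    mat dK = Qc.slice(bi) * dS;
    dWq += dQ * X.t();
    dWk += dK * X.t();
    dWv += dV * X.t();
    dx.slice(bi) = Wq.t() * dQ + Wk.t() * dK + Wv.t() * dV;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dWq") = dWq,
                            Rcpp::Named("dWk") = dWk, Rcpp::Named("dWv") = dWv,
                            Rcpp::Named("dWo") = dWo);
}
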