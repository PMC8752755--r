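// Mini-batch Adam training loop for the residual MLP.
// Architecture and optimizer settings are decided in R (mlp_train); this is
// the hot loop only: forward, backprop, Adam updates, periodic validation
// checkpointing. Weight init and the per-epoch batch orders are produced in
// R so results are reproducible from the R-level seed alone. Arithmetic is
// single precision, matching the convention of mainstream neural-network
// backends; parameters are returned in double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  fmat W1, W2, W3, W4, W5, W6;
  fvec b1, b2, b3, b4, b5, b6;
};

Params from_list(const Rcpp::List& p) {
  Params o;
  o.W1 = conv_to<fmat>::from(Rcpp::as<mat>(p["W1"]));
  o.b1 = conv_to<fvec>::from(Rcpp::as<vec>(p["b1"]));
  o.W2 = conv_to<fmat>::from(Rcpp::as<mat>(p["W2"]));
  o.b2 = conv_to<fvec>::from(Rcpp::as<vec>(p["b2"]));
  o.W3 = conv_to<fmat>::from(Rcpp::as<mat>(p["W3"]));
  o.b3 = conv_to<fvec>::from(Rcpp::as<vec>(p["b3"]));
  o.W4 = conv_to<fmat>::from(Rcpp::as<mat>(p["W4"]));
  o.b4 = conv_to<fvec>::from(Rcpp::as<vec>(p["b4"]));
  o.W5 = conv_to<fmat>::from(Rcpp::as<mat>(p["W5"]));
  o.b5 = conv_to<fvec>::from(Rcpp::as<vec>(p["b5"]));
  o.W6 = conv_to<fmat>::from(Rcpp::as<mat>(p["W6"]));
  o.b6 = conv_to<fvec>::from(Rcpp::as<vec>(p["b6"]));
  return o;
}

Rcpp::List to_list(const Params& p) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(p.W1),
      Rcpp::Named("b1") = conv_to<vec>::from(p.b1),
      Rcpp::Named("W2") = conv_to<mat>::from(p.W2),
      Rcpp::Named("b2") = conv_to<vec>::from(p.b2),
      Rcpp::Named("W3") = conv_to<mat>::from(p.W3),
      Rcpp::Named("b3") = conv_to<vec>::from(p.b3),
      Rcpp::Named("W4") = conv_to<mat>::from(p.W4),
      Rcpp::Named("b4") = conv_to<vec>::from(p.b4),
      Rcpp::Named("W5") = conv_to<mat>::from(p.W5),
      Rcpp::Named("b5") = conv_to<vec>::from(p.b5),
      Rcpp::Named("W6") = conv_to<mat>::from(p.W6),
      Rcpp::Named("b6") = conv_to<vec>::from(p.b6));
}

Params zeros_like(const Params& p) {
  Params o;
  o.W1 = zeros<fmat>(size(p.W1)); o.b1 = zeros<fvec>(size(p.b1));
  o.W2 = zeros<fmat>(size(p.W2)); o.b2 = zeros<fvec>(size(p.b2));
  o.W3 = zeros<fmat>(size(p.W3)); o.b3 = zeros<fvec>(size(p.b3));
  o.W4 = zeros<fmat>(size(p.W4)); o.b4 = zeros<fvec>(size(p.b4));
  o.W5 = zeros<fmat>(size(p.W5)); o.b5 = zeros<fvec>(size(p.b5));
  o.W6 = zeros<fmat>(size(p.W6)); o.b6 = zeros<fvec>(size(p.b6));
  return o;
}

inline fmat relu_f(fmat Z) {
  Z.transform([](float v) { return v > 0 ? v : 0.0f; });
  return Z;
}

// forward over rows of X (n x q); returns predictions
fvec forward(const Params& p, const fmat& X) {
  fmat A1 = relu_f(X * p.W1.t() + repmat(p.b1.t(), X.n_rows, 1));
  fmat A2 = relu_f(A1 * p.W2.t() + repmat(p.b2.t(), X.n_rows, 1));
  fmat A3 = relu_f(A2 * p.W3.t() + repmat(p.b3.t(), X.n_rows, 1));
  fmat A4 = relu_f(A3 * p.W4.t() + repmat(p.b4.t(), X.n_rows, 1));
  return A4 * p.W5.t() + p.b5(0) + X * p.W6.t() + p.b6(0);
}

template <typename T>
inline void adam(T& theta, T& m, T& v, const T& g, float b1, float b2,
                 float lr, float eps, float c1, float c2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  theta -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

}  // namespace

// [[Rcpp::export(name = ".mlp_train_cpp")]]
Rcpp::List mlp_train_cpp(const arma::mat& X_, const arma::vec& y_,
                         const arma::mat& Xval_, const arma::vec& yval_,
                         Rcpp::List init, const arma::umat& batch_order,
                         int batch_size, double lr_, double beta1_,
                         double beta2_, double eps_, int checkpoint_every) {
  const fmat X = conv_to<fmat>::from(X_);
  const fvec y = conv_to<fvec>::from(y_);
  const fmat Xval = conv_to<fmat>::from(Xval_);
  const fvec yval = conv_to<fvec>::from(yval_);
  const float lr = (float)lr_, beta1 = (float)beta1_, beta2 = (float)beta2_,
              eps = (float)eps_;
  const int n = X.n_rows;
  const int epochs = batch_order.n_cols;
  const int bs = std::min(batch_size, n);

  Params p = from_list(init);
  Params m = zeros_like(p), v = zeros_like(p);
  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0;
  long t_step = 0;

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    const uvec ord = batch_order.col(epoch - 1);
    for (int s = 0; s < n; s += bs) {
      const uvec idx = ord.subvec(s, std::min(s + bs, n) - 1);
      const fmat Xb = X.rows(idx);
      const fvec yb = y.elem(idx);
      const int nb = Xb.n_rows;

      fmat Z1 = Xb * p.W1.t(); Z1.each_row() += p.b1.t();
      const fmat M1 = conv_to<fmat>::from(Z1 > 0); const fmat A1 = Z1 % M1;
      fmat Z2 = A1 * p.W2.t(); Z2.each_row() += p.b2.t();
      const fmat M2 = conv_to<fmat>::from(Z2 > 0); const fmat A2 = Z2 % M2;
      fmat Z3 = A2 * p.W3.t(); Z3.each_row() += p.b3.t();
      const fmat M3 = conv_to<fmat>::from(Z3 > 0); const fmat A3 = Z3 % M3;
      fmat Z4 = A3 * p.W4.t(); Z4.each_row() += p.b4.t();
      const fmat M4 = conv_to<fmat>::from(Z4 > 0); const fmat A4 = Z4 % M4;
      const fvec out = A4 * p.W5.t() + p.b5(0) + Xb * p.W6.t() + p.b6(0);

      const fvec dout = 2.0f * (out - yb) / nb;
      const fmat gW5 = dout.t() * A4;
      fvec gb5(1); gb5(0) = accu(dout);
      const fmat gW6 = dout.t() * Xb;
      const fmat dA4 = (dout * p.W5) % M4;
      const fmat gW4 = dA4.t() * A3; const fvec gb4 = sum(dA4, 0).t();
      const fmat dA3 = (dA4 * p.W4) % M3;
      const fmat gW3 = dA3.t() * A2; const fvec gb3 = sum(dA3, 0).t();
      const fmat dA2 = (dA3 * p.W3) % M2;
      const fmat gW2 = dA2.t() * A1; const fvec gb2 = sum(dA2, 0).t();
      const fmat dA1 = (dA2 * p.W2) % M1;
      const fmat gW1 = dA1.t() * Xb; const fvec gb1 = sum(dA1, 0).t();

      ++t_step;
      const float c1 = 1.0f - std::pow(beta1, (float)t_step);
      const float c2 = 1.0f - std::pow(beta2, (float)t_step);
      adam(p.W1, m.W1, v.W1, gW1, beta1, beta2, lr, eps, c1, c2);
      adam(p.b1, m.b1, v.b1, gb1, beta1, beta2, lr, eps, c1, c2);
      adam(p.W2, m.W2, v.W2, gW2, beta1, beta2, lr, eps, c1, c2);
      adam(p.b2, m.b2, v.b2, gb2, beta1, beta2, lr, eps, c1, c2);
      adam(p.W3, m.W3, v.W3, gW3, beta1, beta2, lr, eps, c1, c2);
      adam(p.b3, m.b3, v.b3, gb3, beta1, beta2, lr, eps, c1, c2);
      adam(p.W4, m.W4, v.W4, gW4, beta1, beta2, lr, eps, c1, c2);
      adam(p.b4, m.b4, v.b4, gb4, beta1, beta2, lr, eps, c1, c2);
      adam(p.W5, m.W5, v.W5, gW5, beta1, beta2, lr, eps, c1, c2);
      adam(p.b5, m.b5, v.b5, gb5, beta1, beta2, lr, eps, c1, c2);
      adam(p.W6, m.W6, v.W6, gW6, beta1, beta2, lr, eps, c1, c2);
      fvec gb6(1); gb6(0) = gb5(0);
      adam(p.b6, m.b6, v.b6, gb6, beta1, beta2, lr, eps, c1, c2);
    }
    if (epoch % checkpoint_every == 0 || epoch == epochs) {
      const fvec pv = forward(p, Xval);
      const double val_mse = mean(square(conv_to<vec>::from(pv) -
                                         conv_to<vec>::from(yval)));
      if (!std::isfinite(val_mse))
        Rcpp::stop("mlp_train: non-finite loss at epoch %d", epoch);
      if (val_mse < best_val) {
        best_val = val_mse;
        best = p;
        best_epoch = epoch;
      }
    }
  }
  const fvec pt = forward(best, X);
  const double train_loss = mean(square(conv_to<vec>::from(pt) -
                                        conv_to<vec>::from(y)));
  if (!std::isfinite(train_loss))
    Rcpp::stop("mlp_train: non-finite training loss");
  return Rcpp::List::create(
      Rcpp::Named("params") = to_list(best),
      Rcpp::Named("best_val") = best_val,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("train_loss") = train_loss);
}
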