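// Minibatch RMSprop training loop for the binary-data VAE.
//
// The architecture and objective mirror the R-level documentation in
// R/vae.R: encoder M -> h1 -> h2 -> (mu, logvar) with LeakyReLU(0.01),
// decoder d -> h2 -> h1 -> M with sigmoid output, loss =
// mean_over_batch( masked cross-entropy + kl_weight * KL ).
// All randomness (weight init, shuffling, reparameterization noise) is
// drawn from R's RNG so that set.seed() in R makes training reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

mat r_uniform(int nr, int nc, double lim) {
  mat out(nr, nc);
  for (uword j = 0; j < out.n_cols; ++j)
    for (uword i = 0; i < out.n_rows; ++i)
      out(i, j) = R::runif(-lim, lim);
  return out;
}

mat r_normal(int nr, int nc) {
  mat out(nr, nc);
  for (uword j = 0; j < out.n_cols; ++j)
    for (uword i = 0; i < out.n_rows; ++i)
      out(i, j) = R::norm_rand();
  return out;
}

inline mat lrelu(const mat& u) {
  return u % (0.99 * conv_to<mat>::from(u > 0) + 0.01);
}

inline mat lrelu_grad(const mat& u) {
  return 0.99 * conv_to<mat>::from(u > 0) + 0.01;
}

struct Layer {
  mat W; rowvec b;
  mat cW; rowvec cb;  // RMSprop caches
  Layer(int fan_in, int fan_out) {
    double lim = std::sqrt(6.0 / fan_in);
    W = r_uniform(fan_in, fan_out, lim);
    b = zeros<rowvec>(fan_out);
    cW = zeros<mat>(fan_in, fan_out);
    cb = zeros<rowvec>(fan_out);
  }
  void step(const mat& gW, const rowvec& gb, double lr, double rho, double eps) {
    cW = rho * cW + (1.0 - rho) * square(gW);
    cb = rho * cb + (1.0 - rho) * square(gb);
    W -= lr * gW / (sqrt(cW) + eps);
    b -= lr * gb / (sqrt(cb) + eps);
  }
};

inline mat fwd(const mat& X, const Layer& l) {
  return X * l.W + repmat(l.b, X.n_rows, 1);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List vae_train_cpp(const arma::mat& X0, const arma::mat& W,
                         int h1, int h2, int d, double lam, double lr,
                         int bs, int epochs, double rho, double eps) {
  const int n = X0.n_rows;
  const int m = X0.n_cols;

  Layer e1(m, h1), e2(h1, h2), emu(h2, d), elv(h2, d);
  Layer d1(d, h2), d2(h2, h1), dout(h1, m);

  vec loss_history(epochs);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    Rcpp::IntegerVector perm = Rcpp::sample(n, n, false);  // R RNG, 1-based
    double epoch_loss = 0.0;

    for (int s = 0; s < n; s += bs) {
      int b = std::min(bs, n - s);
      uvec idx(b);
      for (int i = 0; i < b; ++i) idx[i] = perm[s + i] - 1;
      mat Xb = X0.rows(idx);
      mat Wb = W.rows(idx);

      // encoder
      mat U1 = fwd(Xb, e1), H1 = lrelu(U1);
      mat U2 = fwd(H1, e2), H2 = lrelu(U2);
      mat mu = fwd(H2, emu);
      mat lv = fwd(H2, elv);
      mat sg = exp(0.5 * lv);
      mat epsn = r_normal(b, d);
      mat Z = mu + sg % epsn;

      // decoder
      mat V1 = fwd(Z, d1), G1 = lrelu(V1);
      mat V2 = fwd(G1, d2), G2 = lrelu(V2);
      mat logits = fwd(G2, dout);
      mat xhat = 1.0 / (1.0 + exp(-logits));
      mat ph = clamp(xhat, 1e-7, 1.0 - 1e-7);

      double recon = -accu(Wb % (Xb % log(ph) + (1.0 - Xb) % log1p(-ph)));
      double kl = 0.5 * accu(square(mu) + exp(lv) - 1.0 - lv);
      double loss = (recon + lam * kl) / b;
      if (!std::isfinite(loss)) {
        Rcpp::stop("training diverged (non-finite loss at epoch %d)", epoch + 1);
      }
      epoch_loss += loss * b;

      // backward (gradients of the batch-mean loss)
      mat dlogits = Wb % (xhat - Xb) / b;
      mat gWo = G2.t() * dlogits;
      rowvec gbo = sum(dlogits, 0);
      mat dG2 = (dlogits * dout.W.t()) % lrelu_grad(V2);
      mat gWd2 = G1.t() * dG2;
      rowvec gbd2 = sum(dG2, 0);
      mat dG1 = (dG2 * d2.W.t()) % lrelu_grad(V1);
      mat gWd1 = Z.t() * dG1;
      rowvec gbd1 = sum(dG1, 0);
      mat dZ = dG1 * d1.W.t();

      mat dmu = dZ + lam * mu / b;
      mat dlv = dZ % epsn % (0.5 * sg) + lam * 0.5 * (exp(lv) - 1.0) / b;
      mat gWmu = H2.t() * dmu;
      rowvec gbmu = sum(dmu, 0);
      mat gWlv = H2.t() * dlv;
      rowvec gblv = sum(dlv, 0);
      mat dH2 = (dmu * emu.W.t() + dlv * elv.W.t()) % lrelu_grad(U2);
      mat gWe2 = H1.t() * dH2;
      rowvec gbe2 = sum(dH2, 0);
      mat dH1 = (dH2 * e2.W.t()) % lrelu_grad(U1);
      mat gWe1 = Xb.t() * dH1;
      rowvec gbe1 = sum(dH1, 0);

      e1.step(gWe1, gbe1, lr, rho, eps);
      e2.step(gWe2, gbe2, lr, rho, eps);
      emu.step(gWmu, gbmu, lr, rho, eps);
      elv.step(gWlv, gblv, lr, rho, eps);
      d1.step(gWd1, gbd1, lr, rho, eps);
      d2.step(gWd2, gbd2, lr, rho, eps);
      dout.step(gWo, gbo, lr, rho, eps);
    }
    loss_history[epoch] = epoch_loss / n;
  }

  return Rcpp::List::create(
    Rcpp::Named("params") = Rcpp::List::create(
      Rcpp::Named("We1") = e1.W, Rcpp::Named("be1") = e1.b,
      Rcpp::Named("We2") = e2.W, Rcpp::Named("be2") = e2.b,
      Rcpp::Named("Wmu") = emu.W, Rcpp::Named("bmu") = emu.b,
      Rcpp::Named("Wlv") = elv.W, Rcpp::Named("blv") = elv.b,
      Rcpp::Named("Wd1") = d1.W, Rcpp::Named("bd1") = d1.b,
      Rcpp::Named("Wd2") = d2.W, Rcpp::Named("bd2") = d2.b,
      Rcpp::Named("Wo") = dout.W, Rcpp::Named("bo") = dout.b),
    Rcpp::Named("loss_history") = loss_history);
}
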