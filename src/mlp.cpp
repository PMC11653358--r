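// Small fully-connected classifier: ReLU hidden layers, softmax output,
// mini-batch SGD with momentum on the cross-entropy loss. Weights are
// initialized on the R side (seeded there), so training is deterministic:
// batches are taken in fixed cyclic order over the rows as given.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat softmax_cols(const arma::mat& Z) {
  arma::rowvec mx = arma::max(Z, 0);
  arma::mat E = arma::exp(Z.each_row() - mx);
  return E.each_row() / arma::sum(E, 0);
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const IntegerVector& y, List weights,
                   int epochs, double lr, double momentum, int batch) {
  const int n = (int)X.n_cols;
  const int nlayers = weights.size() / 2;
  std::vector<arma::mat> W(nlayers);
  std::vector<arma::vec> b(nlayers);
  std::vector<arma::mat> vW(nlayers);
  std::vector<arma::vec> vb(nlayers);
  for (int l = 0; l < nlayers; ++l) {
    W[l] = as<arma::mat>(weights[2 * l]);
    b[l] = as<arma::vec>(weights[2 * l + 1]);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    vb[l].zeros(b[l].n_elem);
  }
  std::vector<double> epoch_loss(epochs);
  std::vector<arma::mat> A(nlayers + 1), Z(nlayers);
  for (int e = 0; e < epochs; ++e) {
    double eloss = 0.0;
    for (int b0 = 0; b0 < n; b0 += batch) {
      const int nb = std::min(batch, n - b0);
      A[0] = X.cols(b0, b0 + nb - 1);
      for (int l = 0; l < nlayers; ++l) {
        Z[l] = W[l] * A[l];
        Z[l].each_col() += b[l];
        A[l + 1] = (l == nlayers - 1) ? Z[l]
                 : arma::clamp(Z[l], 0.0, arma::datum::inf);
      }
      arma::mat P = softmax_cols(A[nlayers]);
      arma::mat G = P;
      for (int i = 0; i < nb; ++i) {
        const int yi = y[b0 + i];
        eloss -= std::log(std::max(P(yi, i), 1e-300));
        G(yi, i) -= 1.0;
      }
      G /= nb;
      for (int l = nlayers - 1; l >= 0; --l) {
        arma::mat dW = G * A[l].t();
        arma::vec db = arma::sum(G, 1);
        if (l > 0) {
          G = W[l].t() * G;
          G %= arma::conv_to<arma::mat>::from(Z[l - 1] > 0.0);
        }
        vW[l] = momentum * vW[l] - lr * dW;  W[l] += vW[l];
        vb[l] = momentum * vb[l] - lr * db;  b[l] += vb[l];
      }
    }
    epoch_loss[e] = eloss / n;
  }
  List out(2 * nlayers);
  for (int l = 0; l < nlayers; ++l) { out[2 * l] = W[l]; out[2 * l + 1] = b[l]; }
  out.names() = weights.names();
  return List::create(_["weights"] = out, _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
arma::mat mlp_predict_cpp(const arma::mat& X, List weights) {
  const int nlayers = weights.size() / 2;
  arma::mat A = X;
  for (int l = 0; l < nlayers; ++l) {
    arma::mat Z = as<arma::mat>(weights[2 * l]) * A;
    Z.each_col() += as<arma::vec>(weights[2 * l + 1]);
    A = (l == nlayers - 1) ? Z : arma::clamp(Z, 0.0, arma::datum::inf);
  }
  return softmax_cols(A);
}
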