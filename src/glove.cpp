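// GloVe-style embedding fit: AdaGrad SGD over nonzero co-occurrences.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ii, jj: 0-based indices of the upper-triangle nonzero pairs; each pair is
// visited in both orientations every epoch.
// [[Rcpp::export]]
List glove_fit_cpp(const arma::uvec& ii, const arma::uvec& jj,
                   const arma::vec& xx, int vocab, int dim,
                   double x_max, double alpha, double lr,
                   int epochs, int seed) {
  const arma::uword n = ii.n_elem;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(-0.5, 0.5);

  arma::mat W(dim, vocab), Wc(dim, vocab);
  arma::vec b(vocab), bc(vocab);
  for (arma::uword k = 0; k < W.n_elem; ++k) W(k) = unif(rng) / dim;
  for (arma::uword k = 0; k < Wc.n_elem; ++k) Wc(k) = unif(rng) / dim;
  for (int k = 0; k < vocab; ++k) { b(k) = unif(rng) / dim; bc(k) = unif(rng) / dim; }

  // AdaGrad accumulators (initialized at 1, the canonical choice)
  arma::mat GW(dim, vocab, arma::fill::ones), GWc(dim, vocab, arma::fill::ones);
  arma::vec Gb(vocab, arma::fill::ones), Gbc(vocab, arma::fill::ones);

  arma::vec fw(n), logx(n);
  for (arma::uword k = 0; k < n; ++k) {
    fw(k) = xx(k) < x_max ? std::pow(xx(k) / x_max, alpha) : 1.0;
    logx(k) = std::log(xx(k));
  }

  std::vector<arma::uword> order(2 * n);
  for (arma::uword k = 0; k < 2 * n; ++k) order[k] = k;

  arma::vec loss_hist(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss = 0.0;
    for (arma::uword t = 0; t < 2 * n; ++t) {
      arma::uword k = order[t] % n;
      bool swap = order[t] >= n;
      arma::uword i = swap ? jj(k) : ii(k);
      arma::uword j = swap ? ii(k) : jj(k);

      double diff = arma::dot(W.col(i), Wc.col(j)) + b(i) + bc(j) - logx(k);
      double fk = fw(k);
      loss += fk * diff * diff;
      double g = 2.0 * fk * diff;

      for (int d = 0; d < dim; ++d) {
        double gw = g * Wc(d, j);
        double gc = g * W(d, i);
        W(d, i) -= lr * gw / std::sqrt(GW(d, i));
        Wc(d, j) -= lr * gc / std::sqrt(GWc(d, j));
        GW(d, i) += gw * gw;
        GWc(d, j) += gc * gc;
      }
      b(i) -= lr * g / std::sqrt(Gb(i));
      bc(j) -= lr * g / std::sqrt(Gbc(j));
      Gb(i) += g * g;
      Gbc(j) += g * g;
    }
    if (!std::isfinite(loss)) {
      stop("GloVe training diverged (non-finite loss); reduce learning_rate (currently %f).",
           lr);
    }
    loss_hist(ep) = loss;
  }

  return List::create(
    _["W"] = W.t(), _["Wc"] = Wc.t(),
    _["b"] = b, _["bc"] = bc, _["loss"] = loss_hist
  );
}
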