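// Two-hidden-layer feed-forward classifier: relu activations, dropout,
// 2-unit softmax with cross-entropy, ADAM, early stopping on validation
// loss. Records are columns of a sparse feature matrix (code indicator
// features are very sparse); the caller pre-shuffles record order so
// minibatches can be contiguous column blocks.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Adam {
  arma::mat m, v;
  explicit Adam(const arma::mat& w) : m(arma::size(w), arma::fill::zeros),
                                      v(arma::size(w), arma::fill::zeros) {}
  void step(arma::mat& w, const arma::mat& g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

arma::mat glorot(int r, int c, std::mt19937& rng) {
  std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (r + c)));
  arma::mat w(r, c);
  for (arma::uword k = 0; k < w.n_elem; ++k) w(k) = nd(rng);
  return w;
}

// columns are records; returns mean cross-entropy and fills prob1
double mlp_forward_loss(const arma::sp_mat& X, const arma::ivec& y,
                        const arma::mat& W1, const arma::vec& b1,
                        const arma::mat& W2, const arma::vec& b2,
                        const arma::mat& W3, const arma::vec& b3,
                        arma::vec* prob1 = nullptr) {
  arma::mat A1 = W1.t() * X;
  A1.each_col() += b1;
  A1 = arma::clamp(A1, 0.0, arma::datum::inf);
  arma::mat A2 = W2.t() * A1;
  A2.each_col() += b2;
  A2 = arma::clamp(A2, 0.0, arma::datum::inf);
  arma::mat Z = W3.t() * A2;
  Z.each_col() += b3;
  arma::rowvec zmax = arma::max(Z, 0);
  Z.each_row() -= zmax;
  arma::mat E = arma::exp(Z);
  arma::rowvec den = arma::sum(E, 0);
  double loss = 0.0;
  arma::uword nobs = X.n_cols;
  if (prob1) prob1->set_size(nobs);
  for (arma::uword c = 0; c < nobs; ++c) {
    double p1 = E(1, c) / den(c);
    if (prob1) (*prob1)(c) = p1;
    double py = y(c) == 1 ? p1 : E(0, c) / den(c);
    loss -= std::log(std::max(py, 1e-12));
  }
  return loss / nobs;
}

}  // namespace

// [[Rcpp::export]]
List mlp_fit_cpp(const arma::sp_mat& X, const arma::ivec& y,
                 const arma::sp_mat& Xval, const arma::ivec& yval,
                 int h1, int h2, double dropout, double lr,
                 int batch, int max_epochs, int patience, int seed) {
  const int d = X.n_rows;
  const arma::uword n = X.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  arma::mat W1 = glorot(d, h1, rng), W2 = glorot(h1, h2, rng),
            W3 = glorot(h2, 2, rng);
  arma::vec b1(h1, arma::fill::zeros), b2(h2, arma::fill::zeros),
            b3(2, arma::fill::zeros);
  Adam aW1(W1), aW2(W2), aW3(W3), ab1(b1), ab2(b2), ab3(b3);

  const arma::uword nb = (n + batch - 1) / batch;
  std::vector<arma::uword> border(nb);
  for (arma::uword k = 0; k < nb; ++k) border[k] = k;

  arma::mat bestW1 = W1, bestW2 = W2, bestW3 = W3;
  arma::vec bestb1 = b1, bestb2 = b2, bestb3 = b3;
  double best_val = arma::datum::inf;
  int best_epoch = 0, bad = 0;
  std::vector<double> train_loss, val_loss;
  double t_adam = 0.0;

  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(border.begin(), border.end(), rng);
    double ep_loss = 0.0;
    arma::uword ep_n = 0;
    for (arma::uword bi = 0; bi < nb; ++bi) {
      arma::uword a = border[bi] * batch;
      arma::uword b = std::min(n - 1, a + batch - 1);
      arma::uword B = b - a + 1;
      arma::sp_mat Xb(X.cols(a, b));

      arma::mat Z1 = W1.t() * Xb;
      Z1.each_col() += b1;
      arma::mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
      arma::mat Z2 = W2.t() * A1;
      Z2.each_col() += b2;
      arma::mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);

      arma::mat mask(h2, B);
      if (dropout > 0) {
        for (arma::uword k = 0; k < mask.n_elem; ++k) {
          mask(k) = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
        }
        A2 %= mask;
      }

      arma::mat Z3 = W3.t() * A2;
      Z3.each_col() += b3;
      arma::rowvec zmax = arma::max(Z3, 0);
      Z3.each_row() -= zmax;
      arma::mat P = arma::exp(Z3);
      arma::rowvec den = arma::sum(P, 0);
      P.each_row() /= den;

      double bl = 0.0;
      arma::mat dZ3 = P;
      for (arma::uword c = 0; c < B; ++c) {
        int yc = y(a + c);
        bl -= std::log(std::max(P(yc, c), 1e-12));
        dZ3(yc, c) -= 1.0;
      }
      ep_loss += bl;
      ep_n += B;
      dZ3 /= static_cast<double>(B);

      arma::mat dW3 = A2 * dZ3.t();
      arma::vec db3 = arma::sum(dZ3, 1);
      arma::mat dA2 = W3 * dZ3;
      if (dropout > 0) dA2 %= mask;
      arma::mat dZ2 = dA2 % (Z2 > 0);
      arma::mat dW2 = A1 * dZ2.t();
      arma::vec db2 = arma::sum(dZ2, 1);
      arma::mat dA1 = W2 * dZ2;
      arma::mat dZ1 = dA1 % (Z1 > 0);
      arma::mat dW1 = Xb * dZ1.t();
      arma::vec db1 = arma::sum(dZ1, 1);

      t_adam += 1.0;
      aW3.step(W3, dW3, lr, t_adam);
      ab3.step(b3, db3, lr, t_adam);
      aW2.step(W2, dW2, lr, t_adam);
      ab2.step(b2, db2, lr, t_adam);
      aW1.step(W1, dW1, lr, t_adam);
      ab1.step(b1, db1, lr, t_adam);
    }
    double tl = ep_loss / ep_n;
    if (!std::isfinite(tl)) {
      stop("network training diverged (non-finite loss at epoch %d)", ep + 1);
    }
    train_loss.push_back(tl);

    double vl = mlp_forward_loss(Xval, yval, W1, b1, W2, b2, W3, b3);
    val_loss.push_back(vl);
    if (vl < best_val - 1e-6) {
      best_val = vl;
      best_epoch = ep + 1;
      bestW1 = W1; bestW2 = W2; bestW3 = W3;
      bestb1 = b1; bestb2 = b2; bestb3 = b3;
      bad = 0;
    } else if (++bad >= patience) {
      break;
    }
  }

  return List::create(
    _["W1"] = bestW1, _["b1"] = bestb1, _["W2"] = bestW2, _["b2"] = bestb2,
    _["W3"] = bestW3, _["b3"] = bestb3,
    _["train_loss"] = train_loss, _["val_loss"] = val_loss,
    _["best_epoch"] = best_epoch, _["best_val_loss"] = best_val
  );
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const arma::sp_mat& X,
                          const arma::mat& W1, const arma::vec& b1,
                          const arma::mat& W2, const arma::vec& b2,
                          const arma::mat& W3, const arma::vec& b3) {
  arma::vec p;
  arma::ivec dummy(X.n_cols, arma::fill::zeros);
  mlp_forward_loss(X, dummy, W1, b1, W2, b2, W3, b3, &p);
  return p;
}
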