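// Permutation-invariant deep-set readmission classifier on frozen code
// embeddings. Secondary-diagnosis and procedure code sets enter through a
// shared per-code encoder phi (dense + relu, applied to every vocabulary
// code once per minibatch), sum pooling via the record-by-code indicator
// matrix, and a post-pool map rho (dense + relu). The head combines
// [principal-dx embedding, pooled dx, pooled proc, 1-d hospital embedding,
// age, sex] through one relu layer with dropout into a 2-unit softmax.
// Sum pooling over an indicator matrix makes permutation invariance exact
// and the pool of an empty set a zero vector.
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

struct DSParams {
  arma::mat Wpd, Wpp, Wrd, Wrp, Whead, Wout;
  arma::vec bpd, bpp, brd, brp, bhead, bout, eh;
};

// rows of the head feature matrix for records [a, b]
arma::mat ds_features(const DSParams& P,
                      const arma::mat& Edx, const arma::mat& Eproc,
                      const arma::sp_mat& Adx, const arma::sp_mat& Aproc,
                      const arma::ivec& prin, const arma::ivec& hosp,
                      const arma::vec& age, const arma::vec& female,
                      arma::uword a, arma::uword b,
                      arma::mat* PhiDpre = nullptr, arma::mat* PhiPpre = nullptr,
                      arma::mat* PoolD = nullptr, arma::mat* PoolP = nullptr,
                      arma::mat* RhoDpre = nullptr, arma::mat* RhoPpre = nullptr) {
  arma::uword B = b - a + 1;
  arma::mat phiD = Edx * P.Wpd;
  phiD.each_row() += P.bpd.t();
  if (PhiDpre) *PhiDpre = phiD;
  arma::mat PhiD = arma::clamp(phiD, 0.0, arma::datum::inf);
  arma::mat poolD(arma::sp_mat(Adx.cols(a, b)).t() * PhiD);
  if (PoolD) *PoolD = poolD;
  arma::mat rhoDpre = poolD * P.Wrd;
  rhoDpre.each_row() += P.brd.t();
  if (RhoDpre) *RhoDpre = rhoDpre;
  arma::mat RhoD = arma::clamp(rhoDpre, 0.0, arma::datum::inf);

  arma::mat phiP = Eproc * P.Wpp;
  phiP.each_row() += P.bpp.t();
  if (PhiPpre) *PhiPpre = phiP;
  arma::mat PhiP = arma::clamp(phiP, 0.0, arma::datum::inf);
  arma::mat poolP(arma::sp_mat(Aproc.cols(a, b)).t() * PhiP);
  if (PoolP) *PoolP = poolP;
  arma::mat rhoPpre = poolP * P.Wrp;
  rhoPpre.each_row() += P.brp.t();
  if (RhoPpre) *RhoPpre = rhoPpre;
  arma::mat RhoP = arma::clamp(rhoPpre, 0.0, arma::datum::inf);

  arma::uword ddx = Edx.n_cols;
  arma::mat prinE(B, ddx, arma::fill::zeros);
  for (arma::uword r = 0; r < B; ++r) {
    int pi = prin(a + r);
    if (pi > 0) prinE.row(r) = Edx.row(pi - 1);
  }
  arma::vec ehb(B), ageb(B), femb(B);
  for (arma::uword r = 0; r < B; ++r) {
    ehb(r) = P.eh(hosp(a + r) - 1);
    ageb(r) = age(a + r);
    femb(r) = female(a + r);
  }
  return arma::join_rows(arma::join_rows(prinE, RhoD),
                         arma::join_rows(RhoP,
                                         arma::join_rows(ehb, arma::join_rows(ageb, femb))));
}

// softmax probabilities of class 1 from head features (no dropout)
arma::vec head_prob(const DSParams& P, const arma::mat& feat) {
  arma::mat H = feat * P.Whead;
  H.each_row() += P.bhead.t();
  H = arma::clamp(H, 0.0, arma::datum::inf);
  arma::mat Z = H * P.Wout;
  Z.each_row() += P.bout.t();
  arma::vec zmax = arma::max(Z, 1);
  Z.each_col() -= zmax;
  arma::mat E = arma::exp(Z);
  return E.col(1) / (E.col(0) + E.col(1));
}

double mean_ce(const arma::vec& p1, const arma::ivec& y) {
  double loss = 0.0;
  for (arma::uword i = 0; i < p1.n_elem; ++i) {
    double py = y(i) == 1 ? p1(i) : 1.0 - p1(i);
    loss -= std::log(std::max(py, 1e-12));
  }
  return loss / p1.n_elem;
}

DSParams unpack(const List& par) {
  DSParams P;
  P.Wpd = as<arma::mat>(par["Wpd"]); P.bpd = as<arma::vec>(par["bpd"]);
  P.Wpp = as<arma::mat>(par["Wpp"]); P.bpp = as<arma::vec>(par["bpp"]);
  P.Wrd = as<arma::mat>(par["Wrd"]); P.brd = as<arma::vec>(par["brd"]);
  P.Wrp = as<arma::mat>(par["Wrp"]); P.brp = as<arma::vec>(par["brp"]);
  P.Whead = as<arma::mat>(par["Whead"]); P.bhead = as<arma::vec>(par["bhead"]);
  P.Wout = as<arma::mat>(par["Wout"]); P.bout = as<arma::vec>(par["bout"]);
  P.eh = as<arma::vec>(par["eh"]);
  return P;
}

List pack(const DSParams& P) {
  return List::create(
    _["Wpd"] = P.Wpd, _["bpd"] = P.bpd, _["Wpp"] = P.Wpp, _["bpp"] = P.bpp,
    _["Wrd"] = P.Wrd, _["brd"] = P.brd, _["Wrp"] = P.Wrp, _["brp"] = P.brp,
    _["Whead"] = P.Whead, _["bhead"] = P.bhead,
    _["Wout"] = P.Wout, _["bout"] = P.bout, _["eh"] = P.eh
  );
}

}  // namespace

// [[Rcpp::export]]
List deepset_fit_cpp(const arma::mat& Edx, const arma::mat& Eproc,
                     const arma::sp_mat& Adx, const arma::sp_mat& Aproc,
                     const arma::ivec& prin, const arma::ivec& hosp,
                     const arma::vec& age, const arma::vec& female,
                     const arma::ivec& y,
                     const arma::sp_mat& Adx_v, const arma::sp_mat& Aproc_v,
                     const arma::ivec& prin_v, const arma::ivec& hosp_v,
                     const arma::vec& age_v, const arma::vec& female_v,
                     const arma::ivec& yval,
                     int n_hosp, int h, int h_head, double dropout,
                     double lr, int batch, int max_epochs, int patience,
                     int seed) {
  const arma::uword n = Adx.n_cols;
  const int ddx = Edx.n_cols, dproc = Eproc.n_cols;
  const int D = ddx + 2 * h + 3;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> nd01(0.0, 0.1);

  DSParams P;
  P.Wpd = glorot(ddx, h, rng); P.bpd = arma::vec(h, arma::fill::zeros);
  P.Wpp = glorot(dproc, h, rng); P.bpp = arma::vec(h, arma::fill::zeros);
  P.Wrd = glorot(h, h, rng); P.brd = arma::vec(h, arma::fill::zeros);
  P.Wrp = glorot(h, h, rng); P.brp = arma::vec(h, arma::fill::zeros);
  P.Whead = glorot(D, h_head, rng); P.bhead = arma::vec(h_head, arma::fill::zeros);
  P.Wout = glorot(h_head, 2, rng); P.bout = arma::vec(2, arma::fill::zeros);
  P.eh = arma::vec(n_hosp);
  for (int k = 0; k < n_hosp; ++k) P.eh(k) = nd01(rng);

  Adam aWpd(P.Wpd), aWpp(P.Wpp), aWrd(P.Wrd), aWrp(P.Wrp), aWhead(P.Whead),
      aWout(P.Wout), abpd(P.bpd), abpp(P.bpp), abrd(P.brd), abrp(P.brp),
      abhead(P.bhead), about(P.bout), aeh(P.eh);

  const arma::uword nb = (n + batch - 1) / batch;
  std::vector<arma::uword> border(nb);
  for (arma::uword k = 0; k < nb; ++k) border[k] = k;

  DSParams best = P;
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

      arma::mat PhiDpre, PhiPpre, PoolD, PoolP, RhoDpre, RhoPpre;
      arma::mat feat = ds_features(P, Edx, Eproc, Adx, Aproc, prin, hosp,
                                   age, female, a, b,
                                   &PhiDpre, &PhiPpre, &PoolD, &PoolP,
                                   &RhoDpre, &RhoPpre);

      arma::mat Hpre = feat * P.Whead;
      Hpre.each_row() += P.bhead.t();
      arma::mat H = arma::clamp(Hpre, 0.0, arma::datum::inf);
      arma::mat mask(B, h_head);
      if (dropout > 0) {
        for (arma::uword k = 0; k < mask.n_elem; ++k) {
          mask(k) = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
        }
        H %= mask;
      }
      arma::mat Z = H * P.Wout;
      Z.each_row() += P.bout.t();
      arma::vec zmax = arma::max(Z, 1);
      Z.each_col() -= zmax;
      arma::mat Pm = arma::exp(Z);
      arma::vec den = arma::sum(Pm, 1);
      Pm.each_col() /= den;

      arma::mat dZ = Pm;
      double bl = 0.0;
      for (arma::uword r = 0; r < B; ++r) {
        int yr = y(a + r);
        bl -= std::log(std::max(Pm(r, yr), 1e-12));
        dZ(r, yr) -= 1.0;
      }
      ep_loss += bl;
      ep_n += B;
      dZ /= static_cast<double>(B);

      arma::mat dWout = H.t() * dZ;
      arma::vec dbout = arma::sum(dZ, 0).t();
      arma::mat dH = dZ * P.Wout.t();
      if (dropout > 0) dH %= mask;
      arma::mat dHpre = dH % (Hpre > 0);
      arma::mat dWhead = feat.t() * dHpre;
      arma::vec dbhead = arma::sum(dHpre, 0).t();
      arma::mat dfeat = dHpre * P.Whead.t();

      arma::mat dRhoD = dfeat.cols(ddx, ddx + h - 1);
      arma::mat dRhoP = dfeat.cols(ddx + h, ddx + 2 * h - 1);
      arma::vec deh_col = dfeat.col(ddx + 2 * h);

      arma::mat dRhoDpre = dRhoD % (RhoDpre > 0);
      arma::mat dWrd = PoolD.t() * dRhoDpre;
      arma::vec dbrd = arma::sum(dRhoDpre, 0).t();
      arma::mat dPoolD = dRhoDpre * P.Wrd.t();
      arma::mat dPhiD(arma::sp_mat(Adx.cols(a, b)) * dPoolD);
      dPhiD = dPhiD % (PhiDpre > 0);
      arma::mat dWpd = Edx.t() * dPhiD;
      arma::vec dbpd = arma::sum(dPhiD, 0).t();

      arma::mat dRhoPpre = dRhoP % (RhoPpre > 0);
      arma::mat dWrp = PoolP.t() * dRhoPpre;
      arma::vec dbrp = arma::sum(dRhoPpre, 0).t();
      arma::mat dPoolP = dRhoPpre * P.Wrp.t();
      arma::mat dPhiP(arma::sp_mat(Aproc.cols(a, b)) * dPoolP);
      dPhiP = dPhiP % (PhiPpre > 0);
      arma::mat dWpp = Eproc.t() * dPhiP;
      arma::vec dbpp = arma::sum(dPhiP, 0).t();

      arma::vec deh(n_hosp, arma::fill::zeros);
      for (arma::uword r = 0; r < B; ++r) deh(hosp(a + r) - 1) += deh_col(r);

      t_adam += 1.0;
      aWout.step(P.Wout, dWout, lr, t_adam);
      about.step(P.bout, dbout, lr, t_adam);
      aWhead.step(P.Whead, dWhead, lr, t_adam);
      abhead.step(P.bhead, dbhead, lr, t_adam);
      aWrd.step(P.Wrd, dWrd, lr, t_adam);
      abrd.step(P.brd, dbrd, lr, t_adam);
      aWrp.step(P.Wrp, dWrp, lr, t_adam);
      abrp.step(P.brp, dbrp, lr, t_adam);
      aWpd.step(P.Wpd, dWpd, lr, t_adam);
      abpd.step(P.bpd, dbpd, lr, t_adam);
      aWpp.step(P.Wpp, dWpp, lr, t_adam);
      abpp.step(P.bpp, dbpp, lr, t_adam);
      aeh.step(P.eh, deh, lr, t_adam);
    }
    double tl = ep_loss / ep_n;
    if (!std::isfinite(tl)) {
      stop("deep-set training diverged (non-finite loss at epoch %d)", ep + 1);
    }
    train_loss.push_back(tl);

    arma::mat featv = ds_features(P, Edx, Eproc, Adx_v, Aproc_v, prin_v,
                                  hosp_v, age_v, female_v, 0,
                                  Adx_v.n_cols - 1);
    double vl = mean_ce(head_prob(P, featv), yval);
    val_loss.push_back(vl);
    if (vl < best_val - 1e-6) {
      best_val = vl;
      best_epoch = ep + 1;
      best = P;
      bad = 0;
    } else if (++bad >= patience) {
      break;
    }
  }

  List out = pack(best);
  out["train_loss"] = train_loss;
  out["val_loss"] = val_loss;
  out["best_epoch"] = best_epoch;
  out["best_val_loss"] = best_val;
  return out;
}

// eh_mode: 0 = each record's own hospital embedding; 1 = override every
// record's hospital embedding with eh_value (forced hospital or the mean
// embedding for population-average prediction).
// [[Rcpp::export]]
arma::vec deepset_predict_cpp(const List& par,
                              const arma::mat& Edx, const arma::mat& Eproc,
                              const arma::sp_mat& Adx, const arma::sp_mat& Aproc,
                              const arma::ivec& prin, const arma::ivec& hosp,
                              const arma::vec& age, const arma::vec& female,
                              int eh_mode, double eh_value) {
  DSParams P = unpack(par);
  if (eh_mode == 1) P.eh.fill(eh_value);
  arma::mat feat = ds_features(P, Edx, Eproc, Adx, Aproc, prin, hosp, age,
                               female, 0, Adx.n_cols - 1);
  return head_prob(P, feat);
}

// Predictive margins: for each value e in eh_values, the mean predicted
// probability over all records when every record's hospital embedding is
// forced to e. The expensive record representation is built once; only the
// head is re-evaluated per hospital (the hospital embedding enters the head
// pre-activations as a rank-1 term).
// [[Rcpp::export]]
arma::vec deepset_margins_cpp(const List& par,
                              const arma::mat& Edx, const arma::mat& Eproc,
                              const arma::sp_mat& Adx, const arma::sp_mat& Aproc,
                              const arma::ivec& prin, const arma::ivec& hosp,
                              const arma::vec& age, const arma::vec& female,
                              const arma::vec& eh_values) {
  DSParams P = unpack(par);
  const int ddx = Edx.n_cols;
  const int h = P.Wrd.n_cols;
  arma::mat feat = ds_features(P, Edx, Eproc, Adx, Aproc, prin, hosp, age,
                               female, 0, Adx.n_cols - 1);
  feat.col(ddx + 2 * h).zeros();  // remove the hospital-embedding feature
  arma::mat H0 = feat * P.Whead;
  H0.each_row() += P.bhead.t();
  arma::rowvec we = P.Whead.row(ddx + 2 * h);

  arma::vec out(eh_values.n_elem);
  for (arma::uword k = 0; k < eh_values.n_elem; ++k) {
    arma::mat Hpre = H0;
    Hpre.each_row() += eh_values(k) * we;
    arma::mat H = arma::clamp(Hpre, 0.0, arma::datum::inf);
    arma::mat Z = H * P.Wout;
    Z.each_row() += P.bout.t();
    arma::vec zmax = arma::max(Z, 1);
    Z.each_col() -= zmax;
    arma::mat E = arma::exp(Z);
    arma::vec p1 = E.col(1) / (E.col(0) + E.col(1));
    out(k) = arma::mean(p1);
  }
  return out;
}
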