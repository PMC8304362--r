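// Joint training of per-source softmax MLP decoders under an L1 agreement
// penalty. The objective, in bits, is
//   (1/n) * sum_i CE(f_i) + beta * sum_{i<j} E || f_i - f_j ||_1
// with beta following a linear reverse-annealing ramp. All randomness
// (weight initialization, epoch shuffles) is drawn from R's RNG so that a
// set.seed() on the R side makes training fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;

namespace {

const double LN2 = 0.6931471805599453;
const double PROB_FLOOR = 1e-12;

struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
  // optimizer state (Adam first/second moments, or SGD velocity in mW/mb)
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb;

  void init(int d_in, const std::vector<int>& hidden, int K) {
    std::vector<int> dims;
    dims.push_back(d_in);
    for (int h : hidden) dims.push_back(h);
    dims.push_back(K);
    int L = (int)dims.size() - 1;
    W.resize(L); b.resize(L);
    mW.resize(L); vW.resize(L); mb.resize(L); vb.resize(L);
    for (int l = 0; l < L; ++l) {
      W[l].set_size(dims[l], dims[l + 1]);
      double scale = std::sqrt(2.0 / std::max(1, dims[l]));
      for (arma::uword j = 0; j < W[l].n_elem; ++j) W[l](j) = norm_rand() * scale;
      b[l].zeros(dims[l + 1]);
      mW[l].zeros(dims[l], dims[l + 1]);
      vW[l].zeros(dims[l], dims[l + 1]);
      mb[l].zeros(dims[l + 1]);
      vb[l].zeros(dims[l + 1]);
    }
  }
};

inline mat activate(const mat& z, bool relu) {
  if (relu) {
    mat out = z;
    out.transform([](double v) { return v > 0.0 ? v : 0.0; });
    return out;
  }
  return arma::tanh(z);
}

inline mat activate_grad(const mat& z, bool relu) {
  if (relu) return arma::conv_to<mat>::from(z > 0.0);
  mat t = arma::tanh(z);
  return 1.0 - t % t;
}

// Forward pass; fills per-layer inputs A (A[0] = X) and pre-activations Z.
mat forward(const Net& net, const mat& X, std::vector<mat>& A,
            std::vector<mat>& Z, bool relu) {
  int L = (int)net.W.size();
  A.assign(L + 1, mat());
  Z.assign(L, mat());
  A[0] = X;
  for (int l = 0; l < L; ++l) {
    Z[l] = A[l] * net.W[l];
    Z[l].each_row() += net.b[l];
    A[l + 1] = (l < L - 1) ? activate(Z[l], relu) : Z[l];
  }
  // row-stable softmax on the last layer
  mat logits = A[L];
  arma::colvec mx = arma::max(logits, 1);
  logits.each_col() -= mx;
  mat P = arma::exp(logits);
  arma::colvec s = arma::sum(P, 1);
  P.each_col() /= s;
  return P;
}

void backprop_update(Net& net, const std::vector<mat>& A,
                     const std::vector<mat>& Z, mat G, bool relu,
                     const std::string& optimizer, double lr,
                     double momentum, long adam_t) {
  int L = (int)net.W.size();
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  for (int l = L - 1; l >= 0; --l) {
    mat dW = A[l].t() * G;
    rowvec db = arma::sum(G, 0);
    if (l > 0) {
      G = (G * net.W[l].t()) % activate_grad(Z[l - 1], relu);
    }
    if (optimizer == "adam") {
      net.mW[l] = b1 * net.mW[l] + (1 - b1) * dW;
      net.vW[l] = b2 * net.vW[l] + (1 - b2) * (dW % dW);
      net.mb[l] = b1 * net.mb[l] + (1 - b1) * db;
      net.vb[l] = b2 * net.vb[l] + (1 - b2) * (db % db);
      double c1 = 1.0 - std::pow(b1, (double)adam_t);
      double c2 = 1.0 - std::pow(b2, (double)adam_t);
      net.W[l] -= lr * (net.mW[l] / c1) / (arma::sqrt(net.vW[l] / c2) + eps);
      net.b[l] -= lr * (net.mb[l] / c1) / (arma::sqrt(net.vb[l] / c2) + eps);
    } else { // sgd with momentum
      net.mW[l] = momentum * net.mW[l] - lr * dW;
      net.mb[l] = momentum * net.mb[l] - lr * db;
      net.W[l] += net.mW[l];
      net.b[l] += net.mb[l];
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_train_decoders(List X_list, IntegerVector y, int n_classes,
                        List hidden_list, std::string activation,
                        int epochs, int batch_size, double lr,
                        std::string optimizer, double sgd_momentum,
                        double beta_start, double beta_final,
                        double ramp_fraction) {
  RNGScope scope;
  const int n_src = X_list.size();
  const bool relu = (activation == "relu");

  std::vector<mat> X(n_src);
  for (int i = 0; i < n_src; ++i) X[i] = as<mat>(X_list[i]);
  const int N = (int)X[0].n_rows;
  if (N < 1) stop("training data must contain at least one observation");

  uvec yv(N);
  for (int r = 0; r < N; ++r) yv(r) = (arma::uword)y[r];

  std::vector<Net> nets(n_src);
  std::vector<std::vector<int>> hidden(n_src);
  for (int i = 0; i < n_src; ++i) {
    IntegerVector h = hidden_list[i];
    hidden[i].assign(h.begin(), h.end());
    nets[i].init((int)X[i].n_cols, hidden[i], n_classes);
  }

  const int B = std::min(batch_size, N);
  const int n_batches = (N + B - 1) / B;
  const long total_steps = (long)epochs * n_batches;
  long step = 0, adam_t = 0;

  std::vector<arma::uword> order(N);
  for (int r = 0; r < N; ++r) order[r] = r;

  NumericMatrix history(epochs, 5); // epoch, ce_bits, distance, beta, objective
  colnames(history) = CharacterVector::create("epoch", "ce_bits", "distance",
                                              "beta", "objective_bits");

  std::vector<std::vector<mat>> A(n_src), Z(n_src);
  std::vector<mat> P(n_src), Glogit(n_src);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from R's RNG
    for (int r = N - 1; r > 0; --r) {
      int j = (int)std::floor(unif_rand() * (r + 1));
      if (j > r) j = r;
      std::swap(order[r], order[j]);
    }
    double ep_ce = 0.0, ep_d = 0.0, ep_obj = 0.0, beta = 0.0;

    for (int bi = 0; bi < n_batches; ++bi) {
      double progress = total_steps > 1 ? (double)step / (double)(total_steps - 1)
                                        : 1.0;
      double frac = ramp_fraction > 0
        ? std::min(progress / ramp_fraction, 1.0) : 1.0;
      beta = beta_start + (beta_final - beta_start) * frac;

      int lo = bi * B;
      int hi = std::min(lo + B, N);
      int nb = hi - lo;
      uvec rows(nb);
      for (int r = 0; r < nb; ++r) rows(r) = order[lo + r];
      uvec yb = yv.elem(rows);

      // forward all decoders
      double batch_ce = 0.0;
      for (int i = 0; i < n_src; ++i) {
        P[i] = forward(nets[i], X[i].rows(rows), A[i], Z[i], relu);
        double ce = 0.0;
        for (int r = 0; r < nb; ++r) {
          ce += -std::log(std::max(P[i](r, yb(r)), PROB_FLOOR));
        }
        batch_ce += ce / nb / LN2;
        // cross-entropy gradient at the logits, bits scale, averaged over
        // sources and batch
        Glogit[i] = P[i];
        for (int r = 0; r < nb; ++r) Glogit[i](r, yb(r)) -= 1.0;
        Glogit[i] /= (double)n_src * nb * LN2;
      }
      batch_ce /= n_src;

      // pairwise L1 agreement penalty
      double batch_d = 0.0;
      if (n_src > 1 ) {
        for (int i = 0; i < n_src; ++i) {
          for (int j = i + 1; j < n_src; ++j) {
            mat diff = P[i] - P[j];
            batch_d += arma::accu(arma::abs(diff)) / nb;
            if (beta > 0) {
              mat S = arma::sign(diff);
              arma::colvec ri = arma::sum(S % P[i], 1);
              arma::colvec rj = arma::sum(S % P[j], 1);
              mat Si = S; Si.each_col() -= ri;
              mat Sj = S; Sj.each_col() -= rj;
              Glogit[i] += (beta / nb) * (P[i] % Si);
              Glogit[j] -= (beta / nb) * (P[j] % Sj);
            }
          }
        }
      }

      ++adam_t;
      for (int i = 0; i < n_src; ++i) {
        backprop_update(nets[i], A[i], Z[i], Glogit[i], relu, optimizer, lr,
                        sgd_momentum, adam_t);
      }

      ep_ce += batch_ce;
      ep_d += batch_d;
      ep_obj += batch_ce + beta * batch_d;
      ++step;
    }

    history(ep, 0) = ep + 1;
    history(ep, 1) = ep_ce / n_batches;
    history(ep, 2) = ep_d / n_batches;
    history(ep, 3) = beta;
    history(ep, 4) = ep_obj / n_batches;
    if ((ep & 7) == 0) Rcpp::checkUserInterrupt();
  }

  List decoders(n_src);
  for (int i = 0; i < n_src; ++i) {
    int L = (int)nets[i].W.size();
    List Ws(L), bs(L);
    for (int l = 0; l < L; ++l) {
      Ws[l] = wrap(nets[i].W[l]);
      bs[l] = wrap(nets[i].b[l]);
    }
    decoders[i] = List::create(_["weights"] = Ws, _["biases"] = bs);
  }
  return List::create(_["decoders"] = decoders, _["history"] = history);
}
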