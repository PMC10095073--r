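// Feed-forward binary classifier: 3 hidden ReLU layers, sigmoid output,
// binary cross-entropy loss, Adam, mini-batch SGD. Deterministic given the
// seed (std::mt19937 drives both weight init and epoch shuffling).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat he_init(int rows, int cols, std::mt19937 &rng, double scale) {
  std::normal_distribution<double> norm(0.0, scale);
  mat w(rows, cols);
  for (uword j = 0; j < w.n_cols; ++j)
    for (uword i = 0; i < w.n_rows; ++i)
      w(i, j) = norm(rng);
  return w;
}

// [[Rcpp::export(name = ".mlp_train")]]
Rcpp::List mlp_train(const arma::mat &X,      // p x n (features in rows)
                     const arma::vec &y,      // n, in {0,1}
                     const arma::ivec &hidden,
                     double lr, int batch_size, int max_epochs,
                     double early_stop_loss, int early_stop_count,
                     bool consecutive, int seed) {
  const int n = X.n_cols;
  const int L = hidden.n_elem + 1;  // weight layers
  std::vector<int> sizes;
  sizes.push_back(X.n_rows);
  for (uword i = 0; i < hidden.n_elem; ++i) sizes.push_back(hidden(i));
  sizes.push_back(1);

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<mat> W(L);
  std::vector<vec> b(L);
  std::vector<mat> mW(L), vW(L);
  std::vector<vec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    double scale = std::sqrt(2.0 / sizes[l]);
    W[l] = he_init(sizes[l + 1], sizes[l], rng, scale);
    b[l] = zeros<vec>(sizes[l + 1]);
    mW[l] = zeros<mat>(sizes[l + 1], sizes[l]);
    vW[l] = zeros<mat>(sizes[l + 1], sizes[l]);
    mb[l] = zeros<vec>(sizes[l + 1]);
    vb[l] = zeros<vec>(sizes[l + 1]);
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 1e-12;
  int t_adam = 0, low_loss_epochs = 0, epochs_run = 0;
  std::vector<double> epoch_losses;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int bsz = std::min(batch_size, n - start);
      mat Xb(X.n_rows, bsz);
      rowvec yb(bsz);
      for (int k = 0; k < bsz; ++k) {
        Xb.col(k) = X.col(order[start + k]);
        yb(k) = y(order[start + k]);
      }
      // forward
      std::vector<mat> a(L + 1);
      a[0] = Xb;
      for (int l = 0; l < L; ++l) {
        mat z = W[l] * a[l];
        z.each_col() += b[l];
        if (l < L - 1) {
          a[l + 1] = clamp(z, 0.0, datum::inf);        // ReLU
        } else {
          a[l + 1] = 1.0 / (1.0 + exp(-z));            // sigmoid
        }
      }
      rowvec p = clamp(a[L].row(0), clip, 1.0 - clip);
      loss_sum += -accu(yb % log(p) + (1.0 - yb) % log(1.0 - p));

      // backward (BCE + sigmoid): dL/dz_out = (p - y)/bsz
      mat delta = (a[L] - conv_to<mat>::from(yb)) / double(bsz);
      ++t_adam;
      double bc1 = 1.0 - std::pow(beta1, t_adam);
      double bc2 = 1.0 - std::pow(beta2, t_adam);
      for (int l = L - 1; l >= 0; --l) {
        mat gW = delta * a[l].t();
        vec gb = sum(delta, 1);
        if (l > 0) {
          mat da = W[l].t() * delta;
          delta = da % conv_to<mat>::from(a[l] > 0.0);  // ReLU'
        }
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * square(gW);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * square(gb);
        W[l] -= lr * (mW[l] / bc1) / (sqrt(vW[l] / bc2) + eps);
        b[l] -= lr * (mb[l] / bc1) / (sqrt(vb[l] / bc2) + eps);
      }
    }
    double epoch_loss = loss_sum / n;
    epoch_losses.push_back(epoch_loss);
    epochs_run = epoch + 1;
    if (epoch_loss < early_stop_loss) {
      ++low_loss_epochs;
    } else if (consecutive) {
      low_loss_epochs = 0;
    }
    if (low_loss_epochs > early_stop_count) break;
  }

  Rcpp::List Wl(L), bl(L);
  for (int l = 0; l < L; ++l) {
    Wl[l] = Rcpp::wrap(W[l]);
    bl[l] = Rcpp::wrap(b[l]);
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Wl, Rcpp::Named("biases") = bl,
      Rcpp::Named("loss") = epoch_losses,
      Rcpp::Named("epochs") = epochs_run);
}
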