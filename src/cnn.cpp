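// Compact 1D convolutional network for short spectral feature vectors.
// Architecture: Conv(k,ks,same) -> ReLU -> MaxPool(2,2) -> Conv(k,ks,same)
// -> ReLU -> MaxPool(2,2) -> Dropout -> Flatten -> FC -> ReLU -> Linear(1).
// Loss: MSE + lambda * sum(weights^2). Optimiser: Adam with plateau decay of
// the learning rate and early stopping on a validation fold.
// All randomness (init, shuffling, dropout) is drawn from R's RNG so results
// are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Net {
  mat W1;   // ks x k
  vec b1;   // k
  cube W2;  // ks x k x k (tap, in channel, out channel)
  vec b2;   // k
  mat W3;   // F x fcw
  vec b3;   // fcw
  vec W4;   // fcw
  double b4;
};

struct Dims {
  int p, k, ks, pad, p1, p2, F, fcw;
};

struct Cache {
  mat z1, a1, m1;   // p x k, p x k, p1 x k
  umat am1;         // argmax offsets (0/1), p1 x k
  mat z2, a2, m2;   // p1 x k, p1 x k, p2 x k
  umat am2;
  vec v, vd, mask, zh, h;
  double yhat;
};

double r_norm() { return R::norm_rand(); }
double r_unif() { return R::unif_rand(); }

Net init_net(const Dims& d) {
  Net w;
  w.W1.set_size(d.ks, d.k);
  for (int f = 0; f < d.k; ++f)
    for (int t = 0; t < d.ks; ++t) w.W1(t, f) = r_norm() * std::sqrt(2.0 / d.ks);
  w.b1.zeros(d.k);
  w.W2.set_size(d.ks, d.k, d.k);
  for (int f = 0; f < d.k; ++f)
    for (int c = 0; c < d.k; ++c)
      for (int t = 0; t < d.ks; ++t)
        w.W2(t, c, f) = r_norm() * std::sqrt(2.0 / (d.ks * d.k));
  w.b2.zeros(d.k);
  w.W3.set_size(d.F, d.fcw);
  for (int j = 0; j < d.fcw; ++j)
    for (int i = 0; i < d.F; ++i) w.W3(i, j) = r_norm() * std::sqrt(2.0 / d.F);
  w.b3.zeros(d.fcw);
  w.W4.set_size(d.fcw);
  for (int j = 0; j < d.fcw; ++j) w.W4(j) = r_norm() * std::sqrt(2.0 / d.fcw);
  w.b4 = 0.0;
  return w;
}

// forward pass for one sample; dropout applied only when mask has entries
void forward(const Net& w, const Dims& d, const rowvec& x, Cache& c,
             bool use_mask) {
  c.z1.set_size(d.p, d.k);
  for (int f = 0; f < d.k; ++f)
    for (int t = 0; t < d.p; ++t) {
      double s = w.b1(f);
      for (int dd = 0; dd < d.ks; ++dd) {
        int idx = t + dd - d.pad;
        if (idx >= 0 && idx < d.p) s += w.W1(dd, f) * x(idx);
      }
      c.z1(t, f) = s;
    }
  c.a1 = c.z1;
  c.a1.elem(find(c.a1 < 0)).zeros();
  c.m1.set_size(d.p1, d.k); c.am1.set_size(d.p1, d.k);
  for (int f = 0; f < d.k; ++f)
    for (int u = 0; u < d.p1; ++u) {
      double v0 = c.a1(2 * u, f), v1 = c.a1(2 * u + 1, f);
      c.am1(u, f) = v1 > v0 ? 1 : 0;
      c.m1(u, f) = std::max(v0, v1);
    }
  c.z2.set_size(d.p1, d.k);
  for (int f = 0; f < d.k; ++f)
    for (int t = 0; t < d.p1; ++t) {
      double s = w.b2(f);
      for (int dd = 0; dd < d.ks; ++dd) {
        int idx = t + dd - d.pad;
        if (idx >= 0 && idx < d.p1)
          for (int ch = 0; ch < d.k; ++ch)
            s += w.W2(dd, ch, f) * c.m1(idx, ch);
      }
      c.z2(t, f) = s;
    }
  c.a2 = c.z2;
  c.a2.elem(find(c.a2 < 0)).zeros();
  c.m2.set_size(d.p2, d.k); c.am2.set_size(d.p2, d.k);
  for (int f = 0; f < d.k; ++f)
    for (int u = 0; u < d.p2; ++u) {
      double v0 = c.a2(2 * u, f), v1 = c.a2(2 * u + 1, f);
      c.am2(u, f) = v1 > v0 ? 1 : 0;
      c.m2(u, f) = std::max(v0, v1);
    }
  c.v = vectorise(c.m2);          // index t + p2 * channel
  c.vd = use_mask ? vec(c.v % c.mask) : c.v;
  c.zh = w.W3.t() * c.vd + w.b3;
  c.h = c.zh;
  c.h.elem(find(c.h < 0)).zeros();
  c.yhat = dot(w.W4, c.h) + w.b4;
}

struct Grads {
  mat W1; vec b1; cube W2; vec b2; mat W3; vec b3; vec W4; double b4;
  void zero(const Dims& d) {
    W1.zeros(d.ks, d.k); b1.zeros(d.k);
    W2.zeros(d.ks, d.k, d.k); b2.zeros(d.k);
    W3.zeros(d.F, d.fcw); b3.zeros(d.fcw);
    W4.zeros(d.fcw); b4 = 0.0;
  }
};

void backward(const Net& w, const Dims& d, const rowvec& x, const Cache& c,
              double g, bool use_mask, Grads& gr) {
  gr.W4 += g * c.h;
  gr.b4 += g;
  vec dzh = (g * w.W4) % conv_to<vec>::from(c.zh > 0);
  gr.W3 += c.vd * dzh.t();
  gr.b3 += dzh;
  vec dv = w.W3 * dzh;
  if (use_mask) dv %= c.mask;
  mat dm2(d.p2, d.k);
  for (int f = 0; f < d.k; ++f)
    for (int u = 0; u < d.p2; ++u) dm2(u, f) = dv(u + d.p2 * f);
  mat dz2(d.p1, d.k, fill::zeros);
  for (int f = 0; f < d.k; ++f)
    for (int u = 0; u < d.p2; ++u) {
      int t = 2 * u + c.am2(u, f);
      if (c.z2(t, f) > 0) dz2(t, f) = dm2(u, f);
    }
  mat dm1(d.p1, d.k, fill::zeros);
  for (int f = 0; f < d.k; ++f)
    for (int t = 0; t < d.p1; ++t) {
      double dz = dz2(t, f);
      if (dz == 0.0) continue;
      gr.b2(f) += dz;
      for (int dd = 0; dd < d.ks; ++dd) {
        int idx = t + dd - d.pad;
        if (idx >= 0 && idx < d.p1)
          for (int ch = 0; ch < d.k; ++ch) {
            gr.W2(dd, ch, f) += dz * c.m1(idx, ch);
            dm1(idx, ch) += dz * w.W2(dd, ch, f);
          }
      }
    }
  for (int f = 0; f < d.k; ++f)
    for (int u = 0; u < d.p1; ++u) {
      double dm = dm1(u, f);
      if (dm == 0.0) continue;
      int t = 2 * u + c.am1(u, f);
      if (c.z1(t, f) <= 0) continue;
      gr.b1(f) += dm;
      for (int dd = 0; dd < d.ks; ++dd) {
        int idx = t + dd - d.pad;
        if (idx >= 0 && idx < d.p) gr.W1(dd, f) += dm * x(idx);
      }
    }
}

struct Adam {
  mat mW1, vW1, mW3, vW3;
  vec mb1, vb1, mb2, vb2, mb3, vb3, mW4, vW4;
  cube mW2, vW2;
  double mb4, vb4;
  long t;
  void zero(const Dims& d) {
    mW1.zeros(d.ks, d.k); vW1.zeros(d.ks, d.k);
    mb1.zeros(d.k); vb1.zeros(d.k);
    mW2.zeros(d.ks, d.k, d.k); vW2.zeros(d.ks, d.k, d.k);
    mb2.zeros(d.k); vb2.zeros(d.k);
    mW3.zeros(d.F, d.fcw); vW3.zeros(d.F, d.fcw);
    mb3.zeros(d.fcw); vb3.zeros(d.fcw);
    mW4.zeros(d.fcw); vW4.zeros(d.fcw);
    mb4 = vb4 = 0.0; t = 0;
  }
};

template <typename T>
void adam_step(T& w, const T& g, T& m, T& v, double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}

void adam_scalar(double& w, double g, double& m, double& v, double lr,
                 double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * g * g;
  w -= lr * (m / bc1) / (std::sqrt(v / bc2) + 1e-8);
}

double eval_rmse(const Net& w, const Dims& d, const mat& X, const vec& y) {
  Cache c;
  double sse = 0.0;
  for (uword i = 0; i < X.n_rows; ++i) {
    forward(w, d, X.row(i), c, false);
    double e = c.yhat - y(i);
    sse += e * e;
  }
  return std::sqrt(sse / X.n_rows);
}

Rcpp::List net_to_list(const Net& w) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = w.W1, Rcpp::Named("b1") = w.b1,
      Rcpp::Named("W2") = w.W2, Rcpp::Named("b2") = w.b2,
      Rcpp::Named("W3") = w.W3, Rcpp::Named("b3") = w.b3,
      Rcpp::Named("W4") = w.W4, Rcpp::Named("b4") = w.b4);
}

Net net_from_list(const Rcpp::List& l) {
  Net w;
  w.W1 = Rcpp::as<mat>(l["W1"]); w.b1 = Rcpp::as<vec>(l["b1"]);
  w.W2 = Rcpp::as<cube>(l["W2"]); w.b2 = Rcpp::as<vec>(l["b2"]);
  w.W3 = Rcpp::as<mat>(l["W3"]); w.b3 = Rcpp::as<vec>(l["b3"]);
  w.W4 = Rcpp::as<vec>(l["W4"]); w.b4 = Rcpp::as<double>(l["b4"]);
  return w;
}

Dims make_dims(int p, int k, int ks, int fcw) {
  Dims d;
  d.p = p; d.k = k; d.ks = ks; d.pad = ks / 2;
  d.p1 = p / 2; d.p2 = d.p1 / 2;
  d.F = d.p2 * k; d.fcw = fcw;
  if (d.p2 < 1)
    Rcpp::stop("input length %d too short for two pooling layers (need >= 8 features)", p);
  return d;
}

} // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::mat& Xval, const arma::vec& yval,
                         Rcpp::List cfg) {
  const int k = cfg["kernels_per_layer"], ks = cfg["kernel_size"],
            fcw = cfg["fc_width"];
  const double dropout = cfg["dropout"], lambda = cfg["l2_lambda"];
  double lr = cfg["learning_rate"];
  const double decay = cfg["lr_decay_factor"], min_delta = cfg["min_delta"];
  const int max_epochs = cfg["max_iterations"],
            lr_patience = cfg["lr_patience"],
            early_patience = cfg["early_stop_patience"];
  int batch = cfg["batch_size"];
  const int n = X.n_rows, p = X.n_cols;
  if (batch > n) batch = n;
  const bool has_val = Xval.n_rows > 0;
  const bool use_dropout = dropout > 0.0;

  Dims d = make_dims(p, k, ks, fcw);
  Net w = init_net(d);
  Adam opt; opt.zero(d);
  Grads gr;
  Cache c;

  std::vector<double> train_hist, val_hist;
  Net best = w;
  double best_monitor = datum::inf;
  int best_epoch = 0, lr_wait = 0, stop_wait = 0;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  int epoch = 0;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(r_unif() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double sse = 0.0;
    for (int off = 0; off < n; off += batch) {
      int bsz = std::min(batch, n - off);
      gr.zero(d);
      for (int b = 0; b < bsz; ++b) {
        int i = idx[off + b];
        if (use_dropout) {
          c.mask.set_size(d.F);
          for (int jf = 0; jf < d.F; ++jf)
            c.mask(jf) = r_unif() >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
        }
        forward(w, d, X.row(i), c, use_dropout);
        double e = c.yhat - y(i);
        sse += e * e;
        backward(w, d, X.row(i), c, 2.0 * e / bsz, use_dropout, gr);
      }
      // L2 penalty gradient on weights (not biases)
      gr.W1 += 2.0 * lambda * w.W1;
      gr.W2 += 2.0 * lambda * w.W2;
      gr.W3 += 2.0 * lambda * w.W3;
      gr.W4 += 2.0 * lambda * w.W4;
      opt.t += 1;
      double bc1 = 1.0 - std::pow(0.9, (double)opt.t);
      double bc2 = 1.0 - std::pow(0.999, (double)opt.t);
      adam_step(w.W1, gr.W1, opt.mW1, opt.vW1, lr, bc1, bc2);
      adam_step(w.b1, gr.b1, opt.mb1, opt.vb1, lr, bc1, bc2);
      adam_step(w.W2, gr.W2, opt.mW2, opt.vW2, lr, bc1, bc2);
      adam_step(w.b2, gr.b2, opt.mb2, opt.vb2, lr, bc1, bc2);
      adam_step(w.W3, gr.W3, opt.mW3, opt.vW3, lr, bc1, bc2);
      adam_step(w.b3, gr.b3, opt.mb3, opt.vb3, lr, bc1, bc2);
      adam_step(w.W4, gr.W4, opt.mW4, opt.vW4, lr, bc1, bc2);
      adam_scalar(w.b4, gr.b4, opt.mb4, opt.vb4, lr, bc1, bc2);
    }
    double train_rmse = std::sqrt(sse / n);
    train_hist.push_back(train_rmse);
    double monitor = train_rmse;
    if (has_val) {
      double val_rmse = eval_rmse(w, d, Xval, yval);
      val_hist.push_back(val_rmse);
      monitor = val_rmse;
    }
    if (!std::isfinite(monitor))
      Rcpp::stop("non-finite loss at epoch %d (lr = %g); training aborted",
                 epoch, lr);
    if (monitor < best_monitor - min_delta) {
      best_monitor = monitor;
      best = w;
      best_epoch = epoch;
      lr_wait = 0; stop_wait = 0;
    } else {
      ++lr_wait; ++stop_wait;
      if (lr_wait >= lr_patience) { lr *= decay; lr_wait = 0; }
      if (stop_wait >= early_patience) break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = net_to_list(best),
      Rcpp::Named("train_history") = train_hist,
      Rcpp::Named("val_history") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("epochs_run") = std::min(epoch, max_epochs),
      Rcpp::Named("best_monitor") = best_monitor,
      Rcpp::Named("final_lr") = lr);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::vec cnn_predict_cpp(Rcpp::List weights, const arma::mat& X,
                          int kernel_size, int kernels_per_layer,
                          int fc_width) {
  Net w = net_from_list(weights);
  Dims d = make_dims(X.n_cols, kernels_per_layer, kernel_size, fc_width);
  Cache c;
  vec out(X.n_rows);
  for (uword i = 0; i < X.n_rows; ++i) {
    forward(w, d, X.row(i), c, false);
    out(i) = c.yhat;
  }
  return out;
}
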