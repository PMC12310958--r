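// Stacked-LSTM engine: forward pass, backpropagation through time,
// inverted dropout, RMSprop/Adam, gradient-norm clipping and early
// stopping. Sequences are variable-length (padding is handled upstream by
// passing only the valid prefix, which is equivalent to masking the
// all-zero tail). Two heads are supported: a per-time-step dense layer with
// sigmoid output trained with MSE (outcome regression), and a dense softmax
// on the last hidden state trained with cross-entropy (next-session
// classification). All randomness comes from a private seeded generator so
// training is bit-reproducible on a single thread.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct Params {
  std::vector<mat> W;   // per layer, 4u x d_in
  std::vector<mat> U;   // per layer, 4u x u
  std::vector<vec> b;   // per layer, 4u
  mat Wo;               // n_out x u_top
  vec bo;               // n_out
};

struct Grads {
  std::vector<mat> W, U;
  std::vector<vec> b;
  mat Wo;
  vec bo;
  void zero_like(const Params& p) {
    W.clear(); U.clear(); b.clear();
    for (size_t l = 0; l < p.W.size(); ++l) {
      W.push_back(arma::zeros<mat>(p.W[l].n_rows, p.W[l].n_cols));
      U.push_back(arma::zeros<mat>(p.U[l].n_rows, p.U[l].n_cols));
      b.push_back(arma::zeros<vec>(p.b[l].n_elem));
    }
    Wo = arma::zeros<mat>(p.Wo.n_rows, p.Wo.n_cols);
    bo = arma::zeros<vec>(p.bo.n_elem);
  }
};

inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

Params init_params(int n_in, const std::vector<int>& units, int n_out,
                   std::mt19937_64& rng) {
  Params p;
  int d = n_in;
  std::normal_distribution<double> norm(0.0, 1.0);
  for (size_t l = 0; l < units.size(); ++l) {
    int u = units[l];
    auto glorot = [&](int rows, int cols) {
      double r = std::sqrt(6.0 / (rows + cols));
      std::uniform_real_distribution<double> dist(-r, r);
      mat m(rows, cols);
      for (arma::uword j = 0; j < m.n_cols; ++j)
        for (arma::uword i = 0; i < m.n_rows; ++i) m(i, j) = dist(rng);
      return m;
    };
    // recurrent weights: orthogonal per gate (preserves signal through
    // depth and time, the standard recurrent initializer)
    auto orthogonal = [&](int n) {
      mat a(n, n);
      for (arma::uword j = 0; j < a.n_cols; ++j)
        for (arma::uword i = 0; i < a.n_rows; ++i) a(i, j) = norm(rng);
      mat Q, R;
      arma::qr(Q, R, a);
      // sign-correct so the distribution is uniform over orthogonal mats
      for (int j = 0; j < n; ++j) if (R(j, j) < 0) Q.col(j) *= -1.0;
      return Q;
    };
    p.W.push_back(glorot(4 * u, d));
    mat U(4 * u, u);
    for (int gate = 0; gate < 4; ++gate)
      U.rows(gate * u, (gate + 1) * u - 1) = orthogonal(u);
    p.U.push_back(U);
    vec b = arma::zeros<vec>(4 * u);
    b.subvec(u, 2 * u - 1).fill(1.0);  // forget-gate bias
    p.b.push_back(b);
    d = u;
  }
  double r = std::sqrt(6.0 / (n_out + d));
  std::uniform_real_distribution<double> dist(-r, r);
  p.Wo = mat(n_out, d);
  for (arma::uword j = 0; j < p.Wo.n_cols; ++j)
    for (arma::uword i = 0; i < p.Wo.n_rows; ++i) p.Wo(i, j) = dist(rng);
  p.bo = arma::zeros<vec>(n_out);
  return p;
}

// Cache of one layer's forward pass over a sequence (columns = time).
struct LayerCache {
  mat x;               // d_in x T (input after lower dropout)
  mat i, f, g, o, c, tc, h;  // u x T each; tc = tanh(c)
  mat drop;            // u x T dropout mask (already scaled), or empty
};

// Forward one sequence through the stack. X: F x T. Returns per-layer
// caches; hd_top is the (possibly dropped) top-layer output fed to the head.
void forward_stack(const Params& p, const mat& X, double dropout,
                   bool training, std::mt19937_64& rng,
                   std::vector<LayerCache>& caches, mat& hd_top) {
  int T = X.n_cols;
  mat input = X;
  caches.clear();
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (size_t l = 0; l < p.W.size(); ++l) {
    int u = p.U[l].n_cols;
    LayerCache cc;
    cc.x = input;
    cc.i.set_size(u, T); cc.f.set_size(u, T); cc.g.set_size(u, T);
    cc.o.set_size(u, T); cc.c.set_size(u, T); cc.tc.set_size(u, T);
    cc.h.set_size(u, T);
    vec h_prev = arma::zeros<vec>(u), c_prev = arma::zeros<vec>(u);
    mat WX = p.W[l] * input;  // all time-steps in one GEMM
    WX.each_col() += p.b[l];
    for (int t = 0; t < T; ++t) {
      vec z = WX.col(t) + p.U[l] * h_prev;
      vec zi = z.subvec(0, u - 1), zf = z.subvec(u, 2 * u - 1),
          zg = z.subvec(2 * u, 3 * u - 1), zo = z.subvec(3 * u, 4 * u - 1);
      vec gi = 1.0 / (1.0 + arma::exp(-zi));
      vec gf = 1.0 / (1.0 + arma::exp(-zf));
      vec gg = arma::tanh(zg);
      vec go = 1.0 / (1.0 + arma::exp(-zo));
      vec c = gf % c_prev + gi % gg;
      vec tc = arma::tanh(c);
      vec h = go % tc;
      cc.i.col(t) = gi; cc.f.col(t) = gf; cc.g.col(t) = gg;
      cc.o.col(t) = go; cc.c.col(t) = c; cc.tc.col(t) = tc;
      cc.h.col(t) = h;
      h_prev = h; c_prev = c;
    }
    mat out = cc.h;
    if (training && dropout > 0.0) {
      cc.drop.set_size(u, T);
      double keep = 1.0 - dropout;
      for (int t = 0; t < T; ++t)
        for (int k = 0; k < u; ++k)
          cc.drop(k, t) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
      out %= cc.drop;
    }
    caches.push_back(std::move(cc));
    input = out;
  }
  hd_top = input;
}

// Backprop a gradient wrt the (post-dropout) top output down the stack,
// accumulating into g.
void backward_stack(const Params& p, const std::vector<LayerCache>& caches,
                    mat dH, Grads& g) {
  int nl = p.W.size();
  for (int l = nl - 1; l >= 0; --l) {
    const LayerCache& cc = caches[l];
    if (cc.drop.n_elem > 0) dH %= cc.drop;  // through dropout
    int T = cc.h.n_cols;
    int u = cc.h.n_rows;
    vec dh_next = arma::zeros<vec>(u), dc_next = arma::zeros<vec>(u);
    mat DZ(4 * u, T, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      vec dh = dH.col(t) + dh_next;
      vec o = cc.o.col(t), i = cc.i.col(t), f = cc.f.col(t),
          gg = cc.g.col(t), tc = cc.tc.col(t);
      vec dzo = (dh % tc) % (o % (1.0 - o));
      vec dc = dh % o % (1.0 - tc % tc) + dc_next;
      vec c_prev = (t > 0) ? vec(cc.c.col(t - 1))
                           : arma::zeros<vec>(u);
      vec dzi = (dc % gg) % (i % (1.0 - i));
      vec dzf = (dc % c_prev) % (f % (1.0 - f));
      vec dzg = (dc % i) % (1.0 - gg % gg);
      vec dz = arma::join_cols(arma::join_cols(dzi, dzf),
                               arma::join_cols(dzg, dzo));
      DZ.col(t) = dz;
      dh_next = p.U[l].t() * dz;
      dc_next = dc % f;
    }
    g.W[l] += DZ * cc.x.t();
    if (T > 1)
      g.U[l] += DZ.cols(1, T - 1) * cc.h.cols(0, T - 2).t();
    g.b[l] += arma::sum(DZ, 1);
    dH = p.W[l].t() * DZ;
  }
}

// Loss (and grads if g != nullptr) of one regression sequence.
double seq_loss_regression(const Params& p, const mat& X, const mat& Y,
                           double dropout, bool training,
                           std::mt19937_64& rng, Grads* g) {
  std::vector<LayerCache> caches;
  mat hd;
  forward_stack(p, X, dropout, training, rng, caches, hd);
  mat Z = p.Wo * hd;
  Z.each_col() += p.bo;
  mat Yhat = sigm(Z);
  mat diff = Yhat - Y;
  double n = (double)diff.n_elem;
  double loss = arma::accu(diff % diff) / n;
  if (g) {
    mat dZ = (2.0 / n) * diff % (Yhat % (1.0 - Yhat));
    g->Wo += dZ * hd.t();
    g->bo += arma::sum(dZ, 1);
    mat dH = p.Wo.t() * dZ;
    backward_stack(p, caches, dH, *g);
  }
  return loss;
}

// Loss (and grads) of one classification sequence; label is 0-based.
double seq_loss_classification(const Params& p, const mat& X, int label,
                               double dropout, bool training,
                               std::mt19937_64& rng, Grads* g) {
  std::vector<LayerCache> caches;
  mat hd;
  forward_stack(p, X, dropout, training, rng, caches, hd);
  int T = hd.n_cols;
  vec z = p.Wo * hd.col(T - 1) + p.bo;
  z -= z.max();
  vec e = arma::exp(z);
  vec prob = e / arma::accu(e);
  double loss = -std::log(std::max(prob(label), 1e-12));
  if (g) {
    vec dz = prob;
    dz(label) -= 1.0;
    g->Wo += dz * hd.col(T - 1).t();
    g->bo += dz;
    mat dH(hd.n_rows, T, arma::fill::zeros);
    dH.col(T - 1) = p.Wo.t() * dz;
    backward_stack(p, caches, dH, *g);
  }
  return loss;
}

void clip_and_update(Params& p, Grads& g, double scale,
                     const std::string& optimizer, double lr, double clipnorm,
                     std::vector<mat>& cache1, std::vector<mat>& cache2,
                     long& step) {
  // collect pointers in a fixed order
  std::vector<mat*> ws; std::vector<mat> gs;
  int nl = p.W.size();
  for (int l = 0; l < nl; ++l) {
    ws.push_back(&p.W[l]); gs.push_back(g.W[l] * scale);
    ws.push_back(&p.U[l]); gs.push_back(g.U[l] * scale);
    mat bm(g.b[l] * scale); ws.push_back(nullptr); gs.push_back(bm);
  }
  ws.push_back(&p.Wo); gs.push_back(g.Wo * scale);
  mat bo(g.bo * scale); ws.push_back(nullptr); gs.push_back(bo);

  double norm2 = 0.0;
  for (auto& gm : gs) norm2 += arma::accu(gm % gm);
  double norm = std::sqrt(norm2);
  if (clipnorm > 0.0 && norm > clipnorm)
    for (auto& gm : gs) gm *= clipnorm / norm;

  if (cache1.empty())
    for (auto& gm : gs) {
      cache1.push_back(arma::zeros<mat>(gm.n_rows, gm.n_cols));
      cache2.push_back(arma::zeros<mat>(gm.n_rows, gm.n_cols));
    }
  ++step;
  const double eps = 1e-8;
  for (size_t k = 0; k < gs.size(); ++k) {
    mat upd;
    if (optimizer == "rmsprop") {
      cache1[k] = 0.9 * cache1[k] + 0.1 * (gs[k] % gs[k]);
      upd = lr * gs[k] / (arma::sqrt(cache1[k]) + eps);
    } else {  // adam
      cache1[k] = 0.9 * cache1[k] + 0.1 * gs[k];
      cache2[k] = 0.999 * cache2[k] + 0.001 * (gs[k] % gs[k]);
      mat mhat = cache1[k] / (1.0 - std::pow(0.9, (double)step));
      mat vhat = cache2[k] / (1.0 - std::pow(0.999, (double)step));
      upd = lr * mhat / (arma::sqrt(vhat) + eps);
    }
    // apply: even entries are W/U/Wo (pointer), b-vectors handled below
    int l = k / 3, which = k % 3;
    if ((int)k == 3 * nl) p.Wo -= upd;
    else if ((int)k == 3 * nl + 1) p.bo -= upd.col(0);
    else if (which == 0) p.W[l] -= upd;
    else if (which == 1) p.U[l] -= upd;
    else p.b[l] -= upd.col(0);
  }
}

List params_to_list(const Params& p) {
  List layers(p.W.size());
  for (size_t l = 0; l < p.W.size(); ++l)
    layers[l] = List::create(Named("W") = wrap(p.W[l]),
                             Named("U") = wrap(p.U[l]),
                             Named("b") = wrap(p.b[l]));
  return List::create(Named("layers") = layers,
                      Named("Wo") = wrap(p.Wo),
                      Named("bo") = wrap(p.bo));
}

Params params_from_list(const List& wl) {
  Params p;
  List layers = wl["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List ll = layers[l];
    p.W.push_back(as<mat>(ll["W"]));
    p.U.push_back(as<mat>(ll["U"]));
    p.b.push_back(as<vec>(ll["b"]));
  }
  p.Wo = as<mat>(wl["Wo"]);
  p.bo = as<vec>(wl["bo"]);
  return p;
}

}  // namespace

// [[Rcpp::export]]
List cpp_lstm_train(List xs, List ys, IntegerVector labels,
                    std::string task, IntegerVector units, double dropout,
                    std::string optimizer, double lr, int batch_size,
                    int max_epochs, int patience, double val_frac,
                    int n_out, int seed, double clipnorm,
                    int min_epochs, int lr_decay_every,
                    double lr_decay_factor) {
  int n = xs.size();
  std::vector<mat> X(n);
  for (int i = 0; i < n; ++i)
    X[i] = arma::trans(as<mat>(xs[i]));  // F x T
  std::vector<mat> Y;
  std::vector<int> lab;
  bool regression = (task == "regression");
  if (regression) {
    for (int i = 0; i < n; ++i)
      Y.push_back(arma::trans(as<mat>(ys[i])));  // K x T
  } else {
    for (int i = 0; i < n; ++i) lab.push_back(labels[i] - 1);
  }

  std::vector<int> uvec(units.begin(), units.end());
  std::mt19937_64 rng(seed);
  Params p = init_params(X[0].n_rows, uvec, n_out, rng);

  // train/validation split for early stopping
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), rng);
  int n_val = (int)std::floor(val_frac * n);
  std::vector<int> val_idx(idx.end() - n_val, idx.end());
  std::vector<int> train_idx(idx.begin(), idx.end() - n_val);
  if (train_idx.empty()) { train_idx = idx; val_idx.clear(); }

  auto eval_loss = [&](const std::vector<int>& which) {
    double s = 0.0;
    for (int i : which)
      s += regression
        ? seq_loss_regression(p, X[i], Y[i], 0.0, false, rng, nullptr)
        : seq_loss_classification(p, X[i], lab[i], 0.0, false, rng, nullptr);
    return s / std::max((size_t)1, which.size());
  };

  std::vector<mat> cache1, cache2;
  long step = 0;
  std::vector<double> tr_hist, val_hist;
  double best_val = R_PosInf;
  Params best = p;
  int best_epoch = 0, wait = 0;
  bool diverged = false;

  double lr_now = lr;
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    if (lr_decay_every > 0)
      lr_now = lr * std::pow(lr_decay_factor,
                             (double)((epoch - 1) / lr_decay_every));
    std::shuffle(train_idx.begin(), train_idx.end(), rng);
    double tr_loss = 0.0;
    int done = 0;
    while (done < (int)train_idx.size()) {
      int bs = std::min(batch_size, (int)train_idx.size() - done);
      Grads g;
      g.zero_like(p);
      double batch_loss = 0.0;
      for (int b = 0; b < bs; ++b) {
        int i = train_idx[done + b];
        batch_loss += regression
          ? seq_loss_regression(p, X[i], Y[i], dropout, true, rng, &g)
          : seq_loss_classification(p, X[i], lab[i], dropout, true, rng, &g);
      }
      tr_loss += batch_loss;
      if (!std::isfinite(batch_loss)) { diverged = true; break; }
      clip_and_update(p, g, 1.0 / bs, optimizer, lr_now, clipnorm,
                      cache1, cache2, step);
      done += bs;
    }
    if (diverged) break;
    tr_loss /= train_idx.size();
    double monitor = val_idx.empty() ? tr_loss : eval_loss(val_idx);
    tr_hist.push_back(tr_loss);
    val_hist.push_back(monitor);
    if (!std::isfinite(monitor)) { diverged = true; break; }
    // burn-in: the monitor is unreliable while the network is still near
    // its initialization, so early stopping only engages after min_epochs
    if (epoch >= min_epochs) {
      if (monitor < best_val - 1e-12) {
        best_val = monitor;
        best = p;
        best_epoch = epoch;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch > 0) p = best;

  return List::create(
    Named("weights") = params_to_list(p),
    Named("history") = DataFrame::create(
      Named("epoch") = seq_len(tr_hist.size()),
      Named("train_loss") = wrap(tr_hist),
      Named("monitor_loss") = wrap(val_hist)),
    Named("diverged") = diverged,
    Named("best_epoch") = best_epoch,
    Named("best_monitor") = best_val,
    Named("n_val") = (int)val_idx.size());
}

// [[Rcpp::export]]
List cpp_lstm_predict(List weights, List xs, std::string task) {
  Params p = params_from_list(weights);
  std::mt19937_64 rng(0);  // unused (no dropout at prediction time)
  int n = xs.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    mat X = arma::trans(as<mat>(xs[i]));
    std::vector<LayerCache> caches;
    mat hd;
    forward_stack(p, X, 0.0, false, rng, caches, hd);
    if (task == "regression") {
      mat Z = p.Wo * hd;
      Z.each_col() += p.bo;
      out[i] = wrap(arma::trans(sigm(Z)));  // T x K
    } else {
      vec z = p.Wo * hd.col(hd.n_cols - 1) + p.bo;
      z -= z.max();
      vec e = arma::exp(z);
      out[i] = wrap(vec(e / arma::accu(e)));
    }
  }
  return out;
}
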