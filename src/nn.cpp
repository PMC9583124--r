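// Minimal deterministic neural-network engine: a fixed two-conv-block CNN
// (conv -> maxpool -> ReLU, twice; then FC+ReLU, FC+softmax) and a generic
// dense feedforward network. Glorot initialization, Adam, categorical
// cross-entropy, early stopping on a monitored loss. Single-threaded and
// driven by its own mt19937 stream so that a given seed reproduces training
// bit-for-bit.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<mat> m, v;
  explicit Adam(double lr_) : lr(lr_) {}
  void init(const std::vector<mat*>& params) {
    for (auto* p : params) {
      m.emplace_back(size(*p), fill::zeros);
      v.emplace_back(size(*p), fill::zeros);
    }
  }
  void step(std::vector<mat*>& params, const std::vector<mat>& grads) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * grads[i];
      v[i] = b2 * v[i] + (1 - b2) * square(grads[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

mat glorot(int rows, int cols, int fan_in, int fan_out, std::mt19937& rng,
           bool uniform) {
  mat w(rows, cols);
  if (uniform) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> d(-lim, lim);
    for (auto& x : w) x = d(rng);
  } else {
    double sd = std::sqrt(2.0 / (fan_in + fan_out));
    std::normal_distribution<double> d(0.0, sd);
    for (auto& x : w) x = d(rng);
  }
  return w;
}

// channels-as-rows layout: feature map = (n_channels x (h*w)), spatial index
// col-major (r + c*h). im2col emits ((k*k*c) x (oh*ow)).
mat im2col(const mat& fm, int h, int w, int k) {
  int c = fm.n_rows, oh = h - k + 1, ow = w - k + 1;
  mat out(k * k * c, oh * ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      int col = i + j * oh;
      for (int ch = 0; ch < c; ++ch)
        for (int dc = 0; dc < k; ++dc)
          for (int dr = 0; dr < k; ++dr)
            out(ch * k * k + dc * k + dr, col) =
                fm(ch, (i + dr) + (j + dc) * h);
    }
  return out;
}

void col2im_add(mat& fm, const mat& cols, int h, int w, int k) {
  int c = fm.n_rows, oh = h - k + 1, ow = w - k + 1;
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      int col = i + j * oh;
      for (int ch = 0; ch < c; ++ch)
        for (int dc = 0; dc < k; ++dc)
          for (int dr = 0; dr < k; ++dr)
            fm(ch, (i + dr) + (j + dc) * h) +=
                cols(ch * k * k + dc * k + dr, col);
    }
}

// 2x2 max pool (stride 2, trailing row/col dropped); records argmax.
void maxpool2(const mat& fm, int h, int w, mat& out, umat& arg) {
  int ph = h / 2, pw = w / 2, c = fm.n_rows;
  out.set_size(c, ph * pw);
  arg.set_size(c, ph * pw);
  for (int j = 0; j < pw; ++j)
    for (int i = 0; i < ph; ++i) {
      int col = i + j * ph;
      int base_r = 2 * i, base_c = 2 * j;
      for (int ch = 0; ch < c; ++ch) {
        double best = -datum::inf;
        uword best_idx = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            uword idx = (base_r + dr) + (base_c + dc) * h;
            double v = fm(ch, idx);
            if (v > best) { best = v; best_idx = idx; }
          }
        out(ch, col) = best;
        arg(ch, col) = best_idx;
      }
    }
}

void unpool_add(mat& dfm, const mat& dpooled, const umat& arg) {
  for (uword ch = 0; ch < dpooled.n_rows; ++ch)
    for (uword col = 0; col < dpooled.n_cols; ++col)
      dfm(ch, arg(ch, col)) += dpooled(ch, col);
}

vec softmax(const vec& z) {
  vec e = exp(z - z.max());
  return e / accu(e);
}

struct CnnShape {
  int side, k, c1, c2, fc, ncls;
  int o1h, p1h, o2h, p2h, flat;
  void compute() {
    o1h = side - k + 1; p1h = o1h / 2;
    o2h = p1h - k + 1;  p2h = o2h / 2;
    flat = c2 * p2h * p2h;
  }
};

struct CnnWeights {
  mat W1, W2, W3, W4;
  mat b1, b2, b3, b4; // column vectors
};

struct CnnCache {
  mat C1, C2;        // im2col matrices
  mat pre1, pre2;    // post-pool pre-ReLU
  mat act1, act2;    // post-ReLU feature maps
  umat arg1, arg2;   // pool argmax
  vec f, a3, p;      // flatten, fc hidden, probabilities
};

vec cnn_forward(const CnnWeights& wt, const CnnShape& s, const mat& img,
                CnnCache* cache) {
  CnnCache local;
  CnnCache& c = cache ? *cache : local;
  mat in = img;
  in.reshape(1, s.side * s.side);
  c.C1 = im2col(in, s.side, s.side, s.k);
  mat conv1 = wt.W1 * c.C1;
  conv1.each_col() += vec(wt.b1.col(0));
  maxpool2(conv1, s.o1h, s.o1h, c.pre1, c.arg1);
  c.act1 = clamp(c.pre1, 0.0, datum::inf);
  c.C2 = im2col(c.act1, s.p1h, s.p1h, s.k);
  mat conv2 = wt.W2 * c.C2;
  conv2.each_col() += vec(wt.b2.col(0));
  maxpool2(conv2, s.o2h, s.o2h, c.pre2, c.arg2);
  c.act2 = clamp(c.pre2, 0.0, datum::inf);
  c.f = vectorise(c.act2.t()); // fixed flatten order (col of act2' = channel)
  vec z3 = wt.W3 * c.f + wt.b3.col(0);
  c.a3 = clamp(z3, 0.0, datum::inf);
  vec z4 = wt.W4 * c.a3 + wt.b4.col(0);
  c.p = softmax(z4);
  return c.p;
}

void cnn_backward(const CnnWeights& wt, const CnnShape& s, const CnnCache& c,
                  int label, CnnWeights& g) {
  vec dz4 = c.p;
  dz4(label) -= 1.0;
  g.W4 += dz4 * c.a3.t();
  g.b4.col(0) += dz4;
  vec da3 = wt.W4.t() * dz4;
  vec dz3 = da3 % conv_to<vec>::from(c.a3 > 0);
  g.W3 += dz3 * c.f.t();
  g.b3.col(0) += dz3;
  vec df = wt.W3.t() * dz3;
  // un-flatten (inverse of vectorise(act2.t()))
  mat dact2(c.act2.n_rows, c.act2.n_cols);
  {
    mat tmp(df.memptr(), c.act2.n_cols, c.act2.n_rows);
    dact2 = tmp.t();
  }
  dact2 %= conv_to<mat>::from(c.pre2 > 0);
  mat dconv2(s.c2, s.o2h * s.o2h, fill::zeros);
  unpool_add(dconv2, dact2, c.arg2);
  g.W2 += dconv2 * c.C2.t();
  g.b2.col(0) += sum(dconv2, 1);
  mat dC2 = wt.W2.t() * dconv2;
  mat dact1(s.c1, s.p1h * s.p1h, fill::zeros);
  col2im_add(dact1, dC2, s.p1h, s.p1h, s.k);
  dact1 %= conv_to<mat>::from(c.pre1 > 0);
  mat dconv1(s.c1, s.o1h * s.o1h, fill::zeros);
  unpool_add(dconv1, dact1, c.arg1);
  g.W1 += dconv1 * c.C1.t();
  g.b1.col(0) += sum(dconv1, 1);
}

double cnn_loss(const CnnWeights& wt, const CnnShape& s, const cube& X,
                const ivec& y) {
  double loss = 0;
  for (uword i = 0; i < X.n_slices; ++i) {
    vec p = cnn_forward(wt, s, X.slice(i), nullptr);
    loss -= std::log(std::max(p(y(i)), 1e-12));
  }
  return loss / X.n_slices;
}

CnnShape shape_from_cfg(const Rcpp::List& cfg, int side) {
  CnnShape s;
  s.side = side;
  s.k = Rcpp::as<int>(cfg["kernel_size"]);
  s.c1 = Rcpp::as<int>(cfg["conv1_filters"]);
  s.c2 = Rcpp::as<int>(cfg["conv2_filters"]);
  s.fc = Rcpp::as<int>(cfg["fc_width"]);
  s.ncls = Rcpp::as<int>(cfg["n_class"]);
  s.compute();
  return s;
}

CnnWeights weights_from_list(const Rcpp::List& w) {
  CnnWeights wt;
  wt.W1 = Rcpp::as<mat>(w["W1"]); wt.b1 = Rcpp::as<mat>(w["b1"]);
  wt.W2 = Rcpp::as<mat>(w["W2"]); wt.b2 = Rcpp::as<mat>(w["b2"]);
  wt.W3 = Rcpp::as<mat>(w["W3"]); wt.b3 = Rcpp::as<mat>(w["b3"]);
  wt.W4 = Rcpp::as<mat>(w["W4"]); wt.b4 = Rcpp::as<mat>(w["b4"]);
  return wt;
}

Rcpp::List weights_to_list(const CnnWeights& wt) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = wt.W1, Rcpp::Named("b1") = wt.b1,
      Rcpp::Named("W2") = wt.W2, Rcpp::Named("b2") = wt.b2,
      Rcpp::Named("W3") = wt.W3, Rcpp::Named("b3") = wt.b3,
      Rcpp::Named("W4") = wt.W4, Rcpp::Named("b4") = wt.b4);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const arma::cube& Xtr, const arma::ivec& ytr,
                         const arma::cube& Xval, const arma::ivec& yval,
                         const Rcpp::List& cfg, int seed) {
  CnnShape s = shape_from_cfg(cfg, Xtr.n_rows);
  double lr = Rcpp::as<double>(cfg["learning_rate"]);
  int batch = Rcpp::as<int>(cfg["batch_size"]);
  int epochs = Rcpp::as<int>(cfg["epochs"]);
  int patience = Rcpp::as<int>(cfg["patience"]);
  double min_delta = Rcpp::as<double>(cfg["min_delta"]);

  std::mt19937 rng(seed);
  CnnWeights wt;
  // hidden biases start slightly positive: with an aggressive first Adam
  // epoch on small data, zero-initialized ReLU layers can die wholesale and
  // freeze the network at the class prior
  wt.W1 = glorot(s.c1, s.k * s.k, s.k * s.k, s.c1, rng, false);
  wt.b1 = mat(s.c1, 1, fill::value(0.05));
  wt.W2 = glorot(s.c2, s.k * s.k * s.c1, s.k * s.k * s.c1, s.c2, rng, false);
  wt.b2 = mat(s.c2, 1, fill::value(0.05));
  wt.W3 = glorot(s.fc, s.flat, s.flat, s.fc, rng, false);
  wt.b3 = mat(s.fc, 1, fill::value(0.05));
  wt.W4 = glorot(s.ncls, s.fc, s.fc, s.ncls, rng, false);
  wt.b4 = mat(s.ncls, 1, fill::zeros);

  std::vector<mat*> params = {&wt.W1, &wt.b1, &wt.W2, &wt.b2,
                              &wt.W3, &wt.b3, &wt.W4, &wt.b4};
  Adam opt(lr);
  opt.init(params);

  int n = Xtr.n_slices;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  bool has_val = Xval.n_slices > 0;
  double best = datum::inf;
  int wait = 0;
  CnnWeights best_wt = wt;
  std::vector<double> history;
  int stopped_epoch = epochs;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += batch) {
      int end = std::min(start + batch, n);
      CnnWeights g;
      g.W1 = mat(size(wt.W1), fill::zeros); g.b1 = mat(size(wt.b1), fill::zeros);
      g.W2 = mat(size(wt.W2), fill::zeros); g.b2 = mat(size(wt.b2), fill::zeros);
      g.W3 = mat(size(wt.W3), fill::zeros); g.b3 = mat(size(wt.b3), fill::zeros);
      g.W4 = mat(size(wt.W4), fill::zeros); g.b4 = mat(size(wt.b4), fill::zeros);
      for (int ii = start; ii < end; ++ii) {
        CnnCache cache;
        cnn_forward(wt, s, Xtr.slice(order[ii]), &cache);
        cnn_backward(wt, s, cache, ytr(order[ii]), g);
      }
      double inv = 1.0 / (end - start);
      std::vector<mat> grads = {g.W1 * inv, g.b1 * inv, g.W2 * inv, g.b2 * inv,
                                g.W3 * inv, g.b3 * inv, g.W4 * inv, g.b4 * inv};
      opt.step(params, grads);
    }
    double monitored = has_val ? cnn_loss(wt, s, Xval, yval)
                               : cnn_loss(wt, s, Xtr, ytr);
    history.push_back(monitored);
    if (monitored < best - min_delta) {
      best = monitored;
      best_wt = wt;
      wait = 0;
    } else if (++wait >= patience) {
      stopped_epoch = ep + 1;
      break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_list(best_wt),
      Rcpp::Named("history") = history,
      Rcpp::Named("best_loss") = best,
      Rcpp::Named("stopped_epoch") = stopped_epoch);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(const Rcpp::List& weights, const arma::cube& X,
                          const Rcpp::List& cfg) {
  CnnShape s = shape_from_cfg(cfg, X.n_rows);
  CnnWeights wt = weights_from_list(weights);
  mat out(X.n_slices, s.ncls);
  for (uword i = 0; i < X.n_slices; ++i)
    out.row(i) = cnn_forward(wt, s, X.slice(i), nullptr).t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_grad(const Rcpp::List& weights, const arma::cube& X,
                        const arma::ivec& y, const Rcpp::List& cfg) {
  // Mean cross-entropy gradient over the batch; used by the test suite to
  // validate the backward pass against finite differences.
  CnnShape s = shape_from_cfg(cfg, X.n_rows);
  CnnWeights wt = weights_from_list(weights);
  CnnWeights g;
  g.W1 = mat(size(wt.W1), fill::zeros); g.b1 = mat(size(wt.b1), fill::zeros);
  g.W2 = mat(size(wt.W2), fill::zeros); g.b2 = mat(size(wt.b2), fill::zeros);
  g.W3 = mat(size(wt.W3), fill::zeros); g.b3 = mat(size(wt.b3), fill::zeros);
  g.W4 = mat(size(wt.W4), fill::zeros); g.b4 = mat(size(wt.b4), fill::zeros);
  for (uword i = 0; i < X.n_slices; ++i) {
    CnnCache cache;
    cnn_forward(wt, s, X.slice(i), &cache);
    cnn_backward(wt, s, cache, y(i), g);
  }
  double inv = 1.0 / X.n_slices;
  g.W1 *= inv; g.b1 *= inv; g.W2 *= inv; g.b2 *= inv;
  g.W3 *= inv; g.b3 *= inv; g.W4 *= inv; g.b4 *= inv;
  return weights_to_list(g);
}

// [[Rcpp::export]]
double cpp_cnn_loss(const Rcpp::List& weights, const arma::cube& X,
                    const arma::ivec& y, const Rcpp::List& cfg) {
  CnnShape s = shape_from_cfg(cfg, X.n_rows);
  CnnWeights wt = weights_from_list(weights);
  return cnn_loss(wt, s, X, y);
}

// ---------------------------------------------------------------------------
// Dense feedforward network (ReLU hidden layers, softmax output). With no
// hidden layers this is multinomial logistic regression.

namespace {

struct Mlp {
  std::vector<mat> W;
  std::vector<vec> b;
};

mat mlp_forward_batch(const Mlp& net, const mat& X,
                      std::vector<mat>* acts) {
  // X: n x p (rows = samples); activations kept as (units x n)
  mat a = X.t();
  if (acts) acts->push_back(a);
  for (size_t l = 0; l < net.W.size(); ++l) {
    mat z = net.W[l] * a;
    z.each_col() += net.b[l];
    if (l + 1 < net.W.size()) {
      a = clamp(z, 0.0, datum::inf);
    } else {
      a = z;
      a.each_row() -= max(a, 0);
      a = exp(a);
      a.each_row() /= sum(a, 0);
    }
    if (acts) acts->push_back(a);
  }
  return a; // n_class x n
}

double mlp_loss(const Mlp& net, const mat& X, const ivec& y) {
  mat P = mlp_forward_batch(net, X, nullptr);
  double loss = 0;
  for (uword i = 0; i < X.n_rows; ++i)
    loss -= std::log(std::max(P(y(i), i), 1e-12));
  return loss / X.n_rows;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_mlp_train(const arma::mat& Xtr, const arma::ivec& ytr,
                         const arma::mat& Xval, const arma::ivec& yval,
                         const arma::ivec& hidden, int n_class,
                         double lr, int batch, int epochs, int patience,
                         double min_delta, bool glorot_uniform, int seed) {
  std::mt19937 rng(seed);
  std::vector<int> widths;
  widths.push_back(Xtr.n_cols);
  for (uword i = 0; i < hidden.n_elem; ++i) widths.push_back(hidden(i));
  widths.push_back(n_class);

  Mlp net;
  for (size_t l = 0; l + 1 < widths.size(); ++l) {
    net.W.push_back(glorot(widths[l + 1], widths[l], widths[l], widths[l + 1],
                           rng, glorot_uniform));
    net.b.push_back(vec(widths[l + 1], fill::zeros));
  }

  std::vector<mat*> params;
  std::vector<mat> bias_as_mat(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) params.push_back(&net.W[l]);
  Adam optW(lr), optB(lr);
  optW.init(params);
  std::vector<vec> mb(net.b.size()), vb(net.b.size());
  for (size_t l = 0; l < net.b.size(); ++l) {
    mb[l] = vec(net.b[l].n_elem, fill::zeros);
    vb[l] = vec(net.b[l].n_elem, fill::zeros);
  }
  long tb = 0;

  int n = Xtr.n_rows;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  bool has_val = Xval.n_rows > 0;
  double best = datum::inf;
  int wait = 0;
  Mlp best_net = net;
  std::vector<double> history;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += batch) {
      int end = std::min(start + batch, n);
      uvec idx(end - start);
      for (int ii = start; ii < end; ++ii) idx(ii - start) = order[ii];
      mat Xb = Xtr.rows(idx);
      std::vector<mat> acts;
      mat P = mlp_forward_batch(net, Xb, &acts);
      mat delta = P; // n_class x nb
      for (uword i = 0; i < idx.n_elem; ++i) delta(ytr(idx(i)), i) -= 1.0;
      delta /= (double)idx.n_elem;
      std::vector<mat> gW(net.W.size());
      std::vector<vec> gb(net.b.size());
      for (int l = (int)net.W.size() - 1; l >= 0; --l) {
        gW[l] = delta * acts[l].t();
        gb[l] = sum(delta, 1);
        if (l > 0) {
          mat da = net.W[l].t() * delta;
          delta = da % conv_to<mat>::from(acts[l] > 0);
        }
      }
      optW.step(params, gW);
      ++tb;
      double c1 = 1.0 - std::pow(0.9, (double)tb);
      double c2 = 1.0 - std::pow(0.999, (double)tb);
      for (size_t l = 0; l < net.b.size(); ++l) {
        mb[l] = 0.9 * mb[l] + 0.1 * gb[l];
        vb[l] = 0.999 * vb[l] + 0.001 * square(gb[l]);
        net.b[l] -= lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + 1e-8);
      }
    }
    double monitored = has_val ? mlp_loss(net, Xval, yval)
                               : mlp_loss(net, Xtr, ytr);
    history.push_back(monitored);
    if (monitored < best - min_delta) {
      best = monitored;
      best_net = net;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }

  Rcpp::List Wl(best_net.W.size()), bl(best_net.b.size());
  for (size_t l = 0; l < best_net.W.size(); ++l) {
    Wl[l] = best_net.W[l];
    bl[l] = best_net.b[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl,
      Rcpp::Named("history") = history, Rcpp::Named("best_loss") = best);
}

// [[Rcpp::export]]
arma::mat cpp_mlp_predict(const Rcpp::List& Wl, const Rcpp::List& bl,
                          const arma::mat& X) {
  Mlp net;
  for (int l = 0; l < Wl.size(); ++l) {
    net.W.push_back(Rcpp::as<mat>(Wl[l]));
    net.b.push_back(Rcpp::as<vec>(bl[l]));
  }
  return mlp_forward_batch(net, X, nullptr).t();
}
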