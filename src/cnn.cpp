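// Small convolutional network for binary 100x100 QR images:
// conv(F,3x3,same) + ReLU -> maxpool(3,stride 3) -> conv(F,3x3,valid) + ReLU
// -> maxpool(3,stride 3) -> flatten -> [optional dense(H) + ReLU] -> dense(K)
// -> softmax, trained with mini-batch Adam on cross-entropy. Single
// precision; all randomness from std::mt19937 so a seed fixes the run.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using arma::fmat;
using arma::fvec;

static const int KSIDE = 3;   // kernel side
static const int PSIDE = 3;   // pool side == stride (non-overlapping, floor)

struct Dims {
  int side, filters, p1, c2, p2, flat;
};

static Dims make_dims(int side, int filters) {
  Dims d;
  d.side = side;
  d.filters = filters;
  d.p1 = (side - PSIDE) / PSIDE + 1;   // pool over 'same' conv output
  d.c2 = d.p1 - (KSIDE - 1);           // valid conv
  d.p2 = (d.c2 - PSIDE) / PSIDE + 1;
  d.flat = filters * d.p2 * d.p2;
  return d;
}

// im2col for a single-channel image, 3x3 kernel, stride 1, zero pad 1
// ("same"): out (9 x side*side), spatial index i + j*side (column-major).
static void im2col_same(const fmat& img, fmat& out) {
  const int S = img.n_rows;
  out.zeros(9, S * S);
  for (int dr = 0; dr < 3; ++dr)
    for (int dc = 0; dc < 3; ++dc) {
      const int row = dr * 3 + dc;
      for (int j = 0; j < S; ++j) {
        const int cj = j + dc - 1;
        if (cj < 0 || cj >= S) continue;
        for (int i = 0; i < S; ++i) {
          const int ci = i + dr - 1;
          if (ci < 0 || ci >= S) continue;
          out(row, i + j * S) = img(ci, cj);
        }
      }
    }
}

// im2col over C channel maps stored as rows of 'maps' (each row a side x
// side image, column-major), 3x3 kernel, stride 1, no padding ("valid"):
// out (C*9 x outS*outS).
static void im2col_valid(const fmat& maps, int side, fmat& out) {
  const int C = maps.n_rows;
  const int outS = side - 2;
  out.set_size(C * 9, outS * outS);
  for (int c = 0; c < C; ++c)
    for (int dr = 0; dr < 3; ++dr)
      for (int dc = 0; dc < 3; ++dc) {
        const int row = c * 9 + dr * 3 + dc;
        for (int j = 0; j < outS; ++j)
          for (int i = 0; i < outS; ++i)
            out(row, i + j * outS) = maps(c, (i + dr) + (j + dc) * side);
      }
}

// scatter-add transpose of im2col_valid
static void col2im_valid(const fmat& cols, int side, fmat& dmaps) {
  const int C = dmaps.n_rows;
  const int outS = side - 2;
  for (int c = 0; c < C; ++c)
    for (int dr = 0; dr < 3; ++dr)
      for (int dc = 0; dc < 3; ++dc) {
        const int row = c * 9 + dr * 3 + dc;
        for (int j = 0; j < outS; ++j)
          for (int i = 0; i < outS; ++i)
            dmaps(c, (i + dr) + (j + dc) * side) += cols(row, i + j * outS);
      }
}

// non-overlapping 3x3 max pool with floor semantics over each row-map;
// records the argmax (input spatial index) for the backward pass.
static void maxpool(const fmat& maps, int side, fmat& out, arma::umat& arg) {
  const int C = maps.n_rows;
  const int outS = (side - PSIDE) / PSIDE + 1;
  out.set_size(C, outS * outS);
  arg.set_size(C, outS * outS);
  for (int c = 0; c < C; ++c)
    for (int pj = 0; pj < outS; ++pj)
      for (int pi = 0; pi < outS; ++pi) {
        float best = -std::numeric_limits<float>::infinity();
        int besti = 0;
        for (int dj = 0; dj < PSIDE; ++dj)
          for (int di = 0; di < PSIDE; ++di) {
            const int idx = (pi * PSIDE + di) + (pj * PSIDE + dj) * side;
            const float v = maps(c, idx);
            if (v > best) { best = v; besti = idx; }
          }
        out(c, pi + pj * outS) = best;
        arg(c, pi + pj * outS) = besti;
      }
}

struct Weights {
  fmat W1, W2, Wh, Wo;
  fvec b1, b2, bh, bo;
  bool has_hidden;
};

static Weights init_weights(const Dims& d, int hidden, int n_classes,
                            int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  auto he = [&rng](fmat& m, int fan_in) {
    std::normal_distribution<float> g(0.0f, std::sqrt(2.0f / fan_in));
    for (arma::uword k = 0; k < m.n_elem; ++k) m(k) = g(rng);
  };
  Weights w;
  w.has_hidden = hidden > 0;
  w.W1.set_size(d.filters, 9);             he(w.W1, 9);
  w.b1.zeros(d.filters);
  w.W2.set_size(d.filters, d.filters * 9); he(w.W2, d.filters * 9);
  w.b2.zeros(d.filters);
  int head_in = d.flat;
  if (w.has_hidden) {
    w.Wh.set_size(hidden, d.flat);         he(w.Wh, d.flat);
    w.bh.zeros(hidden);
    head_in = hidden;
  }
  w.Wo.set_size(n_classes, head_in);       he(w.Wo, head_in);
  w.bo.zeros(n_classes);
  return w;
}

static Rcpp::List weights_to_list(const Weights& w) {
  using Rcpp::wrap;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("W1") = wrap(arma::conv_to<arma::mat>::from(w.W1)),
      Rcpp::Named("b1") = wrap(arma::conv_to<arma::vec>::from(w.b1)),
      Rcpp::Named("W2") = wrap(arma::conv_to<arma::mat>::from(w.W2)),
      Rcpp::Named("b2") = wrap(arma::conv_to<arma::vec>::from(w.b2)),
      Rcpp::Named("Wo") = wrap(arma::conv_to<arma::mat>::from(w.Wo)),
      Rcpp::Named("bo") = wrap(arma::conv_to<arma::vec>::from(w.bo)));
  if (w.has_hidden) {
    out["Wh"] = wrap(arma::conv_to<arma::mat>::from(w.Wh));
    out["bh"] = wrap(arma::conv_to<arma::vec>::from(w.bh));
  }
  return out;
}

static Weights weights_from_list(Rcpp::List lst) {
  Weights w;
  w.W1 = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lst["W1"]));
  w.b1 = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(lst["b1"]));
  w.W2 = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lst["W2"]));
  w.b2 = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(lst["b2"]));
  w.Wo = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lst["Wo"]));
  w.bo = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(lst["bo"]));
  w.has_hidden = lst.containsElementNamed("Wh");
  if (w.has_hidden) {
    w.Wh = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lst["Wh"]));
    w.bh = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(lst["bh"]));
  }
  return w;
}

struct Workspace {
  fmat P1, C1, Pool1, P2, C2, Pool2;
  arma::umat Arg1, Arg2;
  fvec flat, hid, logits, prob;
};

// forward pass for one image; activations kept for the backward pass
static void forward(const fmat& img, const Weights& w, const Dims& d,
                    Workspace& ws) {
  im2col_same(img, ws.P1);
  ws.C1 = w.W1 * ws.P1;
  ws.C1.each_col() += w.b1;
  ws.C1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  maxpool(ws.C1, d.side, ws.Pool1, ws.Arg1);
  im2col_valid(ws.Pool1, d.p1, ws.P2);
  ws.C2 = w.W2 * ws.P2;
  ws.C2.each_col() += w.b2;
  ws.C2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  maxpool(ws.C2, d.c2, ws.Pool2, ws.Arg2);
  ws.flat = arma::vectorise(ws.Pool2);
  const fvec* head = &ws.flat;
  if (w.has_hidden) {
    ws.hid = w.Wh * ws.flat + w.bh;
    ws.hid.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    head = &ws.hid;
  }
  ws.logits = w.Wo * (*head) + w.bo;
  const float mx = ws.logits.max();
  ws.prob = arma::exp(ws.logits - mx);
  ws.prob /= arma::accu(ws.prob);
}

struct Grads {
  fmat W1, W2, Wh, Wo;
  fvec b1, b2, bh, bo;
  void zero_like(const Weights& w) {
    W1.zeros(arma::size(w.W1)); b1.zeros(arma::size(w.b1));
    W2.zeros(arma::size(w.W2)); b2.zeros(arma::size(w.b2));
    Wo.zeros(arma::size(w.Wo)); bo.zeros(arma::size(w.bo));
    if (w.has_hidden) { Wh.zeros(arma::size(w.Wh)); bh.zeros(arma::size(w.bh)); }
  }
};

static void backward(const Weights& w, const Dims& d, Workspace& ws,
                     int label, Grads& g) {
  fvec dlogit = ws.prob;
  dlogit(label) -= 1.0f;

  const fvec& head = w.has_hidden ? ws.hid : ws.flat;
  g.Wo += dlogit * head.t();
  g.bo += dlogit;
  fvec dflat;
  if (w.has_hidden) {
    fvec dhid = w.Wo.t() * dlogit;
    for (arma::uword k = 0; k < dhid.n_elem; ++k)
      if (ws.hid(k) <= 0.0f) dhid(k) = 0.0f;
    g.Wh += dhid * ws.flat.t();
    g.bh += dhid;
    dflat = w.Wh.t() * dhid;
  } else {
    dflat = w.Wo.t() * dlogit;
  }

  // unflatten to (filters x p2*p2), route through pool2 argmax
  fmat dPool2(dflat.memptr(), d.filters, d.p2 * d.p2, false, true);
  fmat dC2(d.filters, d.c2 * d.c2, arma::fill::zeros);
  for (int c = 0; c < d.filters; ++c)
    for (int k = 0; k < d.p2 * d.p2; ++k)
      dC2(c, ws.Arg2(c, k)) += dPool2(c, k);
  // ReLU
  for (arma::uword k = 0; k < dC2.n_elem; ++k)
    if (ws.C2(k) <= 0.0f) dC2(k) = 0.0f;

  g.W2 += dC2 * ws.P2.t();
  g.b2 += arma::sum(dC2, 1);
  fmat dP2 = w.W2.t() * dC2;
  fmat dPool1(d.filters, d.p1 * d.p1, arma::fill::zeros);
  col2im_valid(dP2, d.p1, dPool1);

  fmat dC1(d.filters, d.side * d.side, arma::fill::zeros);
  for (int c = 0; c < d.filters; ++c)
    for (int k = 0; k < d.p1 * d.p1; ++k)
      dC1(c, ws.Arg1(c, k)) += dPool1(c, k);
  for (arma::uword k = 0; k < dC1.n_elem; ++k)
    if (ws.C1(k) <= 0.0f) dC1(k) = 0.0f;

  g.W1 += dC1 * ws.P1.t();
  g.b1 += arma::sum(dC1, 1);
}

struct Adam {
  fmat mW1, vW1, mW2, vW2, mWh, vWh, mWo, vWo;
  fvec mb1, vb1, mb2, vb2, mbh, vbh, mbo, vbo;
  long t = 0;
  float lr, beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  void init(const Weights& w, float lr_) {
    lr = lr_;
    mW1.zeros(arma::size(w.W1)); vW1.zeros(arma::size(w.W1));
    mW2.zeros(arma::size(w.W2)); vW2.zeros(arma::size(w.W2));
    mWo.zeros(arma::size(w.Wo)); vWo.zeros(arma::size(w.Wo));
    mb1.zeros(arma::size(w.b1)); vb1.zeros(arma::size(w.b1));
    mb2.zeros(arma::size(w.b2)); vb2.zeros(arma::size(w.b2));
    mbo.zeros(arma::size(w.bo)); vbo.zeros(arma::size(w.bo));
    if (w.has_hidden) {
      mWh.zeros(arma::size(w.Wh)); vWh.zeros(arma::size(w.Wh));
      mbh.zeros(arma::size(w.bh)); vbh.zeros(arma::size(w.bh));
    }
  }
  template <typename T>
  void step_one(T& p, T& m, T& v, const T& grad) {
    m = beta1 * m + (1.0f - beta1) * grad;
    v = beta2 * v + (1.0f - beta2) * (grad % grad);
    const float c1 = 1.0f - std::pow(beta1, (float)t);
    const float c2 = 1.0f - std::pow(beta2, (float)t);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
  void step(Weights& w, const Grads& g) {
    ++t;
    step_one(w.W1, mW1, vW1, g.W1); step_one(w.b1, mb1, vb1, g.b1);
    step_one(w.W2, mW2, vW2, g.W2); step_one(w.b2, mb2, vb2, g.b2);
    if (w.has_hidden) {
      step_one(w.Wh, mWh, vWh, g.Wh); step_one(w.bh, mbh, vbh, g.bh);
    }
    step_one(w.Wo, mWo, vWo, g.Wo); step_one(w.bo, mbo, vbo, g.bo);
  }
};

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(int input_side, int filters, int hidden,
                        int n_classes, int seed) {
  Dims d = make_dims(input_side, filters);
  return weights_to_list(init_weights(d, hidden, n_classes, seed));
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::cube& x, const arma::ivec& y,
                         Rcpp::List weights, int n_classes, int epochs,
                         int batch_size, double lr, int seed) {
  const int n = x.n_slices;
  const int side = x.n_rows;
  Weights w = weights_from_list(weights);
  const int filters = w.W1.n_rows;
  const int hidden = w.has_hidden ? w.Wh.n_rows : 0;
  Dims d = make_dims(side, filters);
  if ((int)w.Wo.n_cols != (hidden > 0 ? hidden : d.flat))
    Rcpp::stop("weight shapes do not match the input dimensions");

  std::vector<fmat> imgs(n);
  for (int i = 0; i < n; ++i)
    imgs[i] = arma::conv_to<fmat>::from(x.slice(i));

  Adam opt; opt.init(w, (float)lr);
  Workspace ws;
  Grads g;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Rcpp::NumericVector ep_loss(epochs), ep_acc(epochs);
  for (int e = 0; e < epochs; ++e) {
    std::mt19937 rng(static_cast<uint32_t>(seed) + 0x9E3779B9u * (e + 1));
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      g.zero_like(w);
      for (int k = start; k < stop; ++k) {
        const int i = order[k];
        forward(imgs[i], w, d, ws);
        const int lab = y(i);
        loss_sum += -std::log(std::max(ws.prob(lab), 1e-12f));
        if ((int)ws.prob.index_max() == lab) ++correct;
        backward(w, d, ws, lab, g);
      }
      const float inv = 1.0f / (stop - start);
      g.W1 *= inv; g.b1 *= inv; g.W2 *= inv; g.b2 *= inv;
      g.Wo *= inv; g.bo *= inv;
      if (w.has_hidden) { g.Wh *= inv; g.bh *= inv; }
      opt.step(w, g);
      Rcpp::checkUserInterrupt();
    }
    ep_loss[e] = loss_sum / n;
    ep_acc[e] = (double)correct / n;
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_list(w),
      Rcpp::Named("history") = Rcpp::DataFrame::create(
          Rcpp::Named("epoch") = Rcpp::seq(1, epochs),
          Rcpp::Named("loss") = ep_loss,
          Rcpp::Named("accuracy") = ep_acc));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_predict_cpp(Rcpp::List weights, const arma::cube& x) {
  const int n = x.n_slices;
  const int side = x.n_rows;
  Weights w = weights_from_list(weights);
  Dims d = make_dims(side, w.W1.n_rows);
  const int K = w.Wo.n_rows;
  Rcpp::NumericMatrix out(n, K);
  Workspace ws;
  for (int i = 0; i < n; ++i) {
    fmat img = arma::conv_to<fmat>::from(x.slice(i));
    forward(img, w, d, ws);
    for (int k = 0; k < K; ++k) out(i, k) = ws.prob(k);
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
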