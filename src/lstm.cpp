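// Single-layer LSTM regressor trained by truncated BPTT with Adam.
//
// Input windows arrive as a cube with dimensions (N, F, L): slice t is the
// N x F matrix of channel values at lag position t (t = 0 oldest).  The last
// hidden state feeds a linear read-out to a single scalar target.
// All randomness (weight init, epoch shuffling) is drawn from R's RNG so a
// set.seed() call on the R side makes training reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Weights {
  mat W;       // (F+H) x 4H, gate order [input, forget, cell, output]
  rowvec b;    // 4H
  vec wout;    // H
  double bout;
};

Weights unpack(const List& w) {
  Weights out;
  out.W = as<mat>(w["W"]);
  out.b = as<rowvec>(w["b"]);
  out.wout = as<vec>(w["wout"]);
  out.bout = as<double>(w["bout"]);
  return out;
}

List pack(const Weights& w) {
  return List::create(Named("W") = w.W, Named("b") = w.b,
                      Named("wout") = w.wout, Named("bout") = w.bout);
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct Cache {
  std::vector<mat> Z, I, Fg, G, O, C, TC;  // per time step
};

// forward pass over the full cube (optionally caching for backprop)
vec forward(const Weights& w, const cube& X, Cache* cache) {
  const arma::uword N = X.n_rows, F = X.n_cols, L = X.n_slices;
  const arma::uword H = w.wout.n_elem;
  mat h(N, H, arma::fill::zeros), c(N, H, arma::fill::zeros);
  for (arma::uword t = 0; t < L; ++t) {
    mat Z = arma::join_rows(X.slice(t), h);       // N x (F+H)
    mat A = Z * w.W;                              // N x 4H
    A.each_row() += w.b;
    mat I = sigm(A.cols(0, H - 1));
    mat Fg = sigm(A.cols(H, 2 * H - 1));
    mat G = arma::tanh(A.cols(2 * H, 3 * H - 1));
    mat O = sigm(A.cols(3 * H, 4 * H - 1));
    if (cache) cache->C.push_back(c);             // c_{t-1}
    c = Fg % c + I % G;
    mat tc = arma::tanh(c);
    h = O % tc;
    if (cache) {
      cache->Z.push_back(Z);
      cache->I.push_back(I);
      cache->Fg.push_back(Fg);
      cache->G.push_back(G);
      cache->O.push_back(O);
      cache->TC.push_back(tc);
    }
  }
  return h * w.wout + w.bout;
}

// MSE loss and gradients on one batch; returns loss
double backward(const Weights& w, const cube& X, const vec& y, Weights& g) {
  const arma::uword N = X.n_rows, F = X.n_cols, L = X.n_slices;
  const arma::uword H = w.wout.n_elem;
  Cache cc;
  vec yhat = forward(w, X, &cc);
  vec r = yhat - y;
  double loss = arma::dot(r, r) / N;
  vec dyhat = 2.0 * r / (double)N;

  g.W.zeros(F + H, 4 * H);
  g.b.zeros(4 * H);
  // h_L is recoverable from the cache of step L-1
  mat hL = cc.O[L - 1] % cc.TC[L - 1];
  g.wout = hL.t() * dyhat;
  g.bout = arma::accu(dyhat);

  mat dh = dyhat * w.wout.t();                    // N x H
  mat dc(N, H, arma::fill::zeros);
  for (arma::uword t = L; t-- > 0;) {
    const mat& I = cc.I[t];
    const mat& Fg = cc.Fg[t];
    const mat& G = cc.G[t];
    const mat& O = cc.O[t];
    const mat& tc = cc.TC[t];
    const mat& cprev = cc.C[t];
    mat dO = dh % tc;
    dc += dh % O % (1.0 - tc % tc);
    mat dI = dc % G;
    mat dF = dc % cprev;
    mat dG = dc % I;
    mat dA(N, 4 * H);
    dA.cols(0, H - 1) = dI % I % (1.0 - I);
    dA.cols(H, 2 * H - 1) = dF % Fg % (1.0 - Fg);
    dA.cols(2 * H, 3 * H - 1) = dG % (1.0 - G % G);
    dA.cols(3 * H, 4 * H - 1) = dO % O % (1.0 - O);
    g.W += cc.Z[t].t() * dA;
    g.b += arma::sum(dA, 0);
    mat dZ = dA * w.W.t();
    dh = dZ.cols(F, F + H - 1);
    dc = dc % Fg;
  }
  return loss;
}

double mse_loss(const Weights& w, const cube& X, const vec& y) {
  vec yhat = forward(w, X, nullptr);
  vec r = yhat - y;
  return arma::dot(r, r) / X.n_rows;
}

cube subset_cube(const cube& X, const arma::uvec& idx) {
  cube out(idx.n_elem, X.n_cols, X.n_slices);
  for (arma::uword t = 0; t < X.n_slices; ++t)
    out.slice(t) = X.slice(t).rows(idx);
  return out;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".lstm_init_cpp")]]
List lstm_init_cpp(int n_features, int hidden) {
  const int F = n_features, H = hidden;
  const double s = std::sqrt(6.0 / (double)(F + H + 4 * H));
  Weights w;
  w.W.set_size(F + H, 4 * H);
  for (arma::uword j = 0; j < w.W.n_cols; ++j)
    for (arma::uword i = 0; i < w.W.n_rows; ++i)
      w.W(i, j) = R::runif(-s, s);
  w.b.zeros(4 * H);
  w.b.subvec(H, 2 * H - 1).fill(1.0);  // forget-gate bias
  const double s2 = std::sqrt(6.0 / (double)(H + 1));
  w.wout.set_size(H);
  for (int i = 0; i < H; ++i) w.wout(i) = R::runif(-s2, s2);
  w.bout = 0.0;
  return pack(w);
}

//' @noRd
// [[Rcpp::export(name = ".lstm_forward_cpp")]]
NumericVector lstm_forward_cpp(List weights, NumericVector x_cube) {
  IntegerVector dim = x_cube.attr("dim");
  if (dim.size() != 3) stop("window array must have dim (N, F, L)");
  cube X(x_cube.begin(), dim[0], dim[1], dim[2], false);
  Weights w = unpack(weights);
  vec yhat = forward(w, X, nullptr);
  return wrap(yhat);
}

//' @noRd
// [[Rcpp::export(name = ".lstm_grad_cpp")]]
List lstm_grad_cpp(List weights, NumericVector x_cube, NumericVector y) {
  IntegerVector dim = x_cube.attr("dim");
  cube X(x_cube.begin(), dim[0], dim[1], dim[2], false);
  Weights w = unpack(weights), g;
  double loss = backward(w, X, as<vec>(y), g);
  return List::create(Named("loss") = loss, Named("grad") = pack(g));
}

//' @noRd
// [[Rcpp::export(name = ".lstm_fit_cpp")]]
List lstm_fit_cpp(List weights, NumericVector x_train, NumericVector y_train,
                  NumericVector x_val, NumericVector y_val, int epochs,
                  int batch, double lr, int patience) {
  IntegerVector dtr = x_train.attr("dim"), dva = x_val.attr("dim");
  cube Xtr(x_train.begin(), dtr[0], dtr[1], dtr[2], false);
  cube Xva(x_val.begin(), dva[0], dva[1], dva[2], false);
  vec ytr = as<vec>(y_train), yva = as<vec>(y_val);
  Weights w = unpack(weights);

  Weights m, v;  // Adam moments
  m.W.zeros(arma::size(w.W)); m.b.zeros(w.b.n_elem);
  m.wout.zeros(w.wout.n_elem); m.bout = 0.0;
  v = m;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step_count = 0;

  const arma::uword N = Xtr.n_rows;
  Weights best = w;
  double best_val = mse_loss(w, Xva, yva);
  int best_epoch = 0, wait = 0;
  std::vector<double> val_hist, train_hist;

  for (int ep = 1; ep <= epochs; ++ep) {
    IntegerVector perm = sample(static_cast<int>(N), static_cast<int>(N));
    arma::uvec order(N);
    for (arma::uword i = 0; i < N; ++i) order(i) = perm[i] - 1;
    double ep_loss = 0.0;
    arma::uword done = 0;
    while (done < N) {
      arma::uword hi = std::min(done + (arma::uword)batch, N) - 1;
      arma::uvec idx = order.subvec(done, hi);
      cube Xb = subset_cube(Xtr, idx);
      vec yb = ytr(idx);
      Weights g;
      ep_loss += backward(w, Xb, yb, g) * idx.n_elem;
      ++step_count;
      const double bc1 = 1.0 - std::pow(b1, (double)step_count);
      const double bc2 = 1.0 - std::pow(b2, (double)step_count);
      m.W = b1 * m.W + (1 - b1) * g.W;      v.W = b2 * v.W + (1 - b2) * arma::square(g.W);
      m.b = b1 * m.b + (1 - b1) * g.b;      v.b = b2 * v.b + (1 - b2) * arma::square(g.b);
      m.wout = b1 * m.wout + (1 - b1) * g.wout;
      v.wout = b2 * v.wout + (1 - b2) * arma::square(g.wout);
      m.bout = b1 * m.bout + (1 - b1) * g.bout;
      v.bout = b2 * v.bout + (1 - b2) * g.bout * g.bout;
      w.W -= lr * (m.W / bc1) / (arma::sqrt(v.W / bc2) + eps);
      w.b -= lr * (m.b / bc1) / (arma::sqrt(v.b / bc2) + eps);
      w.wout -= lr * (m.wout / bc1) / (arma::sqrt(v.wout / bc2) + eps);
      w.bout -= lr * (m.bout / bc1) / (std::sqrt(v.bout / bc2) + eps);
      done = hi + 1;
    }
    train_hist.push_back(ep_loss / N);
    double vl = mse_loss(w, Xva, yva);
    val_hist.push_back(vl);
    if (vl < best_val - 1e-9) {
      best_val = vl;
      best = w;
      best_epoch = ep;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }
  return List::create(Named("weights") = pack(best),
                      Named("val_loss") = wrap(val_hist),
                      Named("train_loss") = wrap(train_hist),
                      Named("best_val_loss") = best_val,
                      Named("best_epoch") = best_epoch);
}
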