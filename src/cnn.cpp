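// Small convolutional binary classifier used for shearlet-patch
// classification: n_conv convolutional layers (same padding) each followed
// by batch normalization, ReLU and 2x2 max pooling, then a fully connected
// ReLU layer and a single sigmoid output. Training uses minibatch Adam on
// the binary cross-entropy. The implementation favours clarity and exact
// reproducibility (all randomness lives on the R side).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double BN_EPS = 1e-5;

struct ConvLayer {
  arma::mat W;     // (Cout, Cin*k*k)
  arma::vec b;     // Cout
  arma::vec gamma, beta, rmean, rvar;
  int cin, cout, k;
};

struct Net {
  int H0, W0, C0;
  std::vector<ConvLayer> conv;
  arma::mat Wd1; arma::vec bd1;   // (Dw, F)
  arma::mat Wd2; arma::vec bd2;   // (1, Dw)
};

Net parse_net(const List& params) {
  Net net;
  IntegerVector dim = params["input_dim"];
  net.H0 = dim[0]; net.W0 = dim[1]; net.C0 = dim[2];
  List conv = params["conv"];
  for (int l = 0; l < conv.size(); ++l) {
    List cl = conv[l];
    ConvLayer c;
    c.W = as<arma::mat>(cl["W"]);
    c.b = as<arma::vec>(cl["b"]);
    c.gamma = as<arma::vec>(cl["gamma"]);
    c.beta = as<arma::vec>(cl["beta"]);
    c.rmean = as<arma::vec>(cl["rmean"]);
    c.rvar = as<arma::vec>(cl["rvar"]);
    c.cout = c.W.n_rows;
    c.k = as<int>(cl["kernel"]);
    c.cin = c.W.n_cols / (c.k * c.k);
    net.conv.push_back(c);
  }
  List d1 = params["dense1"], d2 = params["dense2"];
  net.Wd1 = as<arma::mat>(d1["W"]); net.bd1 = as<arma::vec>(d1["b"]);
  net.Wd2 = as<arma::mat>(d2["W"]); net.bd2 = as<arma::vec>(d2["b"]);
  return net;
}

// column c*k*k + ki*k + kj of the patch around (i, j), zero padded
arma::mat im2col(const arma::cube& x, int b, int C, int H, int W, int k) {
  int pad = (k - 1) / 2;
  arma::mat col(C * k * k, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice((arma::uword)(c + C * b));
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        int r = c * k * k + ki * k + kj;
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int ii = i + ki - pad;
            if (ii < 0 || ii >= H) continue;
            col(r, i + H * j) = sl(ii, jj);
          }
        }
      }
    }
  }
  return col;
}

void col2im_add(arma::cube& dx, const arma::mat& dcol, int b, int C, int H,
                int W, int k) {
  int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    arma::mat& sl = dx.slice((arma::uword)(c + C * b));
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        int r = c * k * k + ki * k + kj;
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int ii = i + ki - pad;
            if (ii < 0 || ii >= H) continue;
            sl(ii, jj) += dcol(r, i + H * j);
          }
        }
      }
    }
  }
}

struct LayerCache {
  std::vector<arma::mat> cols;   // per sample im2col of the layer input
  arma::mat xhat;                // (Cout, H*W*B) normalized pre-activation
  arma::vec mu, ivar;            // batch stats
  arma::mat relu_mask;           // (Cout, H*W*B)
  arma::ucube pool_arg;          // (Hp, Wp, Cout*B) winning offset 0..3
  int H, W, Hp, Wp;
};

struct ForwardState {
  arma::cube input0;
  std::vector<LayerCache> caches;
  arma::mat feat;                // (F, B) flattened features
  arma::mat z1, h1, z2, prob;    // dense caches
  int Hl, Wl, Cl;                // final conv output geometry
};

// Forward pass. `training` selects batch statistics (and fills caches when
// `keep` is true); otherwise running statistics are used.
ForwardState forward(const Net& net, const arma::cube& x0, int B,
                     bool training, bool keep,
                     std::vector<arma::vec>* batch_mu = nullptr,
                     std::vector<arma::vec>* batch_var = nullptr) {
  ForwardState st;
  arma::cube cur = x0;
  int H = net.H0, W = net.W0, C = net.C0;
  for (size_t l = 0; l < net.conv.size(); ++l) {
    const ConvLayer& cl = net.conv[l];
    LayerCache cache;
    cache.H = H; cache.W = W;
    int HW = H * W;
    arma::mat pre(cl.cout, HW * B);
    for (int b = 0; b < B; ++b) {
      arma::mat col = im2col(cur, b, C, H, W, cl.k);
      pre.cols(b * HW, (b + 1) * HW - 1) = cl.W * col;
      pre.cols(b * HW, (b + 1) * HW - 1).each_col() += cl.b;
      if (keep) cache.cols.push_back(std::move(col));
    }
    arma::vec mu, var;
    if (training) {
      mu = arma::mean(pre, 1);
      arma::mat cen = pre.each_col() - mu;
      var = arma::mean(arma::square(cen), 1);
    } else {
      mu = cl.rmean;
      var = cl.rvar;
    }
    if (batch_mu) { batch_mu->push_back(mu); batch_var->push_back(var); }
    arma::vec ivar = 1.0 / arma::sqrt(var + BN_EPS);
    arma::mat xhat = pre.each_col() - mu;
    xhat.each_col() %= ivar;
    arma::mat act = xhat.each_col() % cl.gamma;
    act.each_col() += cl.beta;
    arma::mat mask = arma::conv_to<arma::mat>::from(act > 0.0);
    act %= mask;
    if (keep) {
      cache.xhat = xhat; cache.mu = mu; cache.ivar = ivar;
      cache.relu_mask = mask;
    }
    // 2x2 max pool (floor geometry)
    int Hp = H / 2, Wp = W / 2;
    cache.Hp = Hp; cache.Wp = Wp;
    arma::cube pooled(Hp, Wp, (arma::uword)(cl.cout * B));
    arma::ucube parg(Hp, Wp, (arma::uword)(cl.cout * B));
    for (int b = 0; b < B; ++b) {
      for (int c = 0; c < cl.cout; ++c) {
        for (int jp = 0; jp < Wp; ++jp) {
          for (int ip = 0; ip < Hp; ++ip) {
            double best = -arma::datum::inf; int barg = 0;
            for (int o = 0; o < 4; ++o) {
              int di = o % 2, dj = o / 2;
              int i = 2 * ip + di, j = 2 * jp + dj;
              double v = act(c, b * HW + i + H * j);
              if (v > best) { best = v; barg = o; }
            }
            pooled(ip, jp, (arma::uword)(c + cl.cout * b)) = best;
            parg(ip, jp, (arma::uword)(c + cl.cout * b)) = barg;
          }
        }
      }
    }
    if (keep) cache.pool_arg = parg;
    if (keep) st.caches.push_back(std::move(cache));
    cur = pooled;
    H = Hp; W = Wp; C = cl.cout;
  }
  st.Hl = H; st.Wl = W; st.Cl = C;
  // flatten: per sample, slices (channels) stacked in order
  int F = H * W * C;
  st.feat.set_size(F, B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      st.feat.col(b).subvec(c * H * W, (c + 1) * H * W - 1) =
        arma::vectorise(cur.slice((arma::uword)(c + C * b)));
    }
  }
  st.z1 = net.Wd1 * st.feat;
  st.z1.each_col() += net.bd1;
  st.h1 = arma::clamp(st.z1, 0.0, arma::datum::inf);
  st.z2 = net.Wd2 * st.h1;
  st.z2.each_col() += net.bd2;
  st.prob = 1.0 / (1.0 + arma::exp(-st.z2));
  if (keep) st.input0 = x0;
  return st;
}

arma::cube as_cube(const NumericVector& x, int H, int W, int CB) {
  arma::cube out(H, W, CB);
  std::copy(x.begin(), x.end(), out.memptr());
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
NumericVector cnn_forward_cpp(List params, NumericVector x, bool training) {
  Net net = parse_net(params);
  IntegerVector d = x.attr("dim");
  if (d.size() != 4 || d[0] != net.H0 || d[1] != net.W0 || d[2] != net.C0)
    stop("input dimensions do not match the network");
  int B = d[3];
  arma::cube x0 = as_cube(x, net.H0, net.W0, net.C0 * B);
  ForwardState st = forward(net, x0, B, training, false);
  return NumericVector(st.prob.begin(), st.prob.end());
}

// [[Rcpp::export(name = ".cnn_train_batch_cpp")]]
List cnn_train_batch_cpp(List params, List adam, NumericVector x,
                         NumericVector y, double lr, int t,
                         double beta1, double beta2, double adam_eps,
                         double bn_momentum) {
  Net net = parse_net(params);
  IntegerVector d = x.attr("dim");
  if (d.size() != 4 || d[0] != net.H0 || d[1] != net.W0 || d[2] != net.C0)
    stop("input dimensions do not match the network");
  int B = d[3];
  if (y.size() != B) stop("label count does not match the batch");
  arma::cube x0 = as_cube(x, net.H0, net.W0, net.C0 * B);
  arma::rowvec yy(B);
  for (int b = 0; b < B; ++b) yy(b) = y[b];

  std::vector<arma::vec> bmu, bvar;
  ForwardState st = forward(net, x0, B, true, true, &bmu, &bvar);

  // binary cross-entropy from logits (numerically stable)
  arma::rowvec z = st.z2.row(0);
  double loss = arma::mean(arma::max(z, arma::rowvec(B, arma::fill::zeros)) -
                           z % yy + arma::log1p(arma::exp(-arma::abs(z))));

  // ---- backward ----
  int nconv = net.conv.size();
  std::vector<arma::mat> gW(nconv), gGamma(nconv);
  std::vector<arma::vec> gB(nconv), gBeta(nconv);

  arma::mat dz2 = (st.prob - arma::mat(yy)) / B;          // (1, B)
  arma::mat gWd2 = dz2 * st.h1.t();
  arma::vec gbd2 = arma::sum(dz2, 1);
  arma::mat dh1 = net.Wd2.t() * dz2;
  arma::mat dz1 = dh1 % arma::conv_to<arma::mat>::from(st.z1 > 0.0);
  arma::mat gWd1 = dz1 * st.feat.t();
  arma::vec gbd1 = arma::sum(dz1, 1);
  arma::mat dfeat = net.Wd1.t() * dz1;                    // (F, B)

  // unflatten into the pooled-output cube of the last conv layer
  int H = st.Hl, W = st.Wl, C = st.Cl;
  arma::cube dcur(H, W, (arma::uword)(C * B), arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      dcur.slice((arma::uword)(c + C * b)) = arma::reshape(
        dfeat.col(b).subvec(c * H * W, (c + 1) * H * W - 1), H, W);
    }
  }

  for (int l = nconv - 1; l >= 0; --l) {
    const ConvLayer& cl = net.conv[l];
    LayerCache& cache = st.caches[l];
    int Hf = cache.H, Wf = cache.W, HW = Hf * Wf;
    // unpool
    arma::mat dact(cl.cout, HW * B, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (int c = 0; c < cl.cout; ++c) {
        for (int jp = 0; jp < cache.Wp; ++jp) {
          for (int ip = 0; ip < cache.Hp; ++ip) {
            int o = cache.pool_arg(ip, jp, (arma::uword)(c + cl.cout * b));
            int i = 2 * ip + o % 2, j = 2 * jp + o / 2;
            dact(c, b * HW + i + Hf * j) +=
              dcur(ip, jp, (arma::uword)(c + cl.cout * b));
          }
        }
      }
    }
    dact %= cache.relu_mask;
    // batchnorm backward
    double N = HW * B;
    gGamma[l] = arma::sum(dact % cache.xhat, 1);
    gBeta[l] = arma::sum(dact, 1);
    arma::mat dxhat = dact.each_col() % cl.gamma;
    arma::vec sum_dxhat = arma::sum(dxhat, 1);
    arma::vec sum_dxhat_xhat = arma::sum(dxhat % cache.xhat, 1);
    arma::mat dpre = dxhat;
    dpre.each_col() -= sum_dxhat / N;
    dpre -= cache.xhat.each_col() % (sum_dxhat_xhat / N);
    dpre.each_col() %= cache.ivar;
    // conv backward
    gW[l].zeros(cl.W.n_rows, cl.W.n_cols);
    gB[l] = arma::sum(dpre, 1);
    int Cin = cl.cin;
    arma::cube dprev;
    if (l > 0) {
      dprev.zeros(Hf, Wf, (arma::uword)(Cin * B));
    }
    for (int b = 0; b < B; ++b) {
      arma::mat dp = dpre.cols(b * HW, (b + 1) * HW - 1);
      gW[l] += dp * cache.cols[b].t();
      if (l > 0) {
        arma::mat dcol = cl.W.t() * dp;
        col2im_add(dprev, dcol, b, Cin, Hf, Wf, cl.k);
      }
    }
    if (l > 0) dcur = std::move(dprev);
  }

  // ---- Adam update ----
  List conv = params["conv"];
  List aconv = adam["conv"];
  double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
  auto step = [&](arma::mat& p, arma::mat& m, arma::mat& v,
                  const arma::mat& g) {
    m = beta1 * m + (1 - beta1) * g;
    v = beta2 * v + (1 - beta2) * arma::square(g);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + adam_eps);
  };
  List out_conv(conv.size());
  List out_aconv(conv.size());
  for (int l = 0; l < conv.size(); ++l) {
    List cl = conv[l];
    List al = aconv[l];
    arma::mat W = as<arma::mat>(cl["W"]), Wm = as<arma::mat>(al["Wm"]),
      Wv = as<arma::mat>(al["Wv"]);
    arma::mat b = as<arma::mat>(cl["b"]), bm = as<arma::mat>(al["bm"]),
      bv = as<arma::mat>(al["bv"]);
    arma::mat g = as<arma::mat>(cl["gamma"]), gm = as<arma::mat>(al["gm"]),
      gv = as<arma::mat>(al["gv"]);
    arma::mat be = as<arma::mat>(cl["beta"]), bem = as<arma::mat>(al["bem"]),
      bev = as<arma::mat>(al["bev"]);
    step(W, Wm, Wv, gW[l]);
    step(b, bm, bv, arma::mat(gB[l]));
    step(g, gm, gv, arma::mat(gGamma[l]));
    step(be, bem, bev, arma::mat(gBeta[l]));
    arma::vec rmean = as<arma::vec>(cl["rmean"]);
    arma::vec rvar = as<arma::vec>(cl["rvar"]);
    rmean = (1 - bn_momentum) * rmean + bn_momentum * bmu[l];
    rvar = (1 - bn_momentum) * rvar + bn_momentum * bvar[l];
    out_conv[l] = List::create(_["W"] = W, _["b"] = b, _["gamma"] = g,
                               _["beta"] = be, _["rmean"] = rmean,
                               _["rvar"] = rvar,
                               _["kernel"] = as<int>(cl["kernel"]));
    out_aconv[l] = List::create(_["Wm"] = Wm, _["Wv"] = Wv, _["bm"] = bm,
                                _["bv"] = bv, _["gm"] = gm, _["gv"] = gv,
                                _["bem"] = bem, _["bev"] = bev);
  }
  List d1 = params["dense1"], d2 = params["dense2"];
  List ad = adam["dense"];
  arma::mat W1 = as<arma::mat>(d1["W"]), W1m = as<arma::mat>(ad["W1m"]),
    W1v = as<arma::mat>(ad["W1v"]);
  arma::mat b1 = as<arma::mat>(d1["b"]), b1m = as<arma::mat>(ad["b1m"]),
    b1v = as<arma::mat>(ad["b1v"]);
  arma::mat W2 = as<arma::mat>(d2["W"]), W2m = as<arma::mat>(ad["W2m"]),
    W2v = as<arma::mat>(ad["W2v"]);
  arma::mat b2 = as<arma::mat>(d2["b"]), b2m = as<arma::mat>(ad["b2m"]),
    b2v = as<arma::mat>(ad["b2v"]);
  step(W1, W1m, W1v, gWd1);
  step(b1, b1m, b1v, arma::mat(gbd1));
  step(W2, W2m, W2v, gWd2);
  step(b2, b2m, b2v, arma::mat(gbd2));

  List out_params = List::create(
    _["input_dim"] = params["input_dim"],
    _["conv"] = out_conv,
    _["dense1"] = List::create(_["W"] = W1, _["b"] = b1),
    _["dense2"] = List::create(_["W"] = W2, _["b"] = b2));
  List out_adam = List::create(
    _["conv"] = out_aconv,
    _["dense"] = List::create(_["W1m"] = W1m, _["W1v"] = W1v,
                              _["b1m"] = b1m, _["b1v"] = b1v,
                              _["W2m"] = W2m, _["W2v"] = W2v,
                              _["b2m"] = b2m, _["b2v"] = b2v));
  return List::create(_["params"] = out_params, _["adam"] = out_adam,
                      _["loss"] = loss);
}

// Loss and parameter gradients for a batch, without updating. Used by the
// finite-difference gradient checks in the test suite.
// [[Rcpp::export(name = ".cnn_loss_grads_cpp")]]
List cnn_loss_grads_cpp(List params, NumericVector x, NumericVector y) {
  Net net = parse_net(params);
  IntegerVector d = x.attr("dim");
  int B = d[3];
  arma::cube x0 = as_cube(x, net.H0, net.W0, net.C0 * B);
  arma::rowvec yy(B);
  for (int b = 0; b < B; ++b) yy(b) = y[b];
  std::vector<arma::vec> bmu, bvar;
  ForwardState st = forward(net, x0, B, true, true, &bmu, &bvar);
  arma::rowvec z = st.z2.row(0);
  double loss = arma::mean(arma::max(z, arma::rowvec(B, arma::fill::zeros)) -
                           z % yy + arma::log1p(arma::exp(-arma::abs(z))));

  int nconv = net.conv.size();
  std::vector<arma::mat> gW(nconv), gGamma(nconv);
  std::vector<arma::vec> gB(nconv), gBeta(nconv);
  arma::mat dz2 = (st.prob - arma::mat(yy)) / B;
  arma::mat gWd2 = dz2 * st.h1.t();
  arma::vec gbd2 = arma::sum(dz2, 1);
  arma::mat dh1 = net.Wd2.t() * dz2;
  arma::mat dz1 = dh1 % arma::conv_to<arma::mat>::from(st.z1 > 0.0);
  arma::mat gWd1 = dz1 * st.feat.t();
  arma::vec gbd1 = arma::sum(dz1, 1);
  arma::mat dfeat = net.Wd1.t() * dz1;
  int H = st.Hl, W = st.Wl, C = st.Cl;
  arma::cube dcur(H, W, (arma::uword)(C * B), arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      dcur.slice((arma::uword)(c + C * b)) = arma::reshape(
        dfeat.col(b).subvec(c * H * W, (c + 1) * H * W - 1), H, W);
  for (int l = nconv - 1; l >= 0; --l) {
    const ConvLayer& cl = net.conv[l];
    LayerCache& cache = st.caches[l];
    int Hf = cache.H, Wf = cache.W, HW = Hf * Wf;
    arma::mat dact(cl.cout, HW * B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < cl.cout; ++c)
        for (int jp = 0; jp < cache.Wp; ++jp)
          for (int ip = 0; ip < cache.Hp; ++ip) {
            int o = cache.pool_arg(ip, jp, (arma::uword)(c + cl.cout * b));
            int i = 2 * ip + o % 2, j = 2 * jp + o / 2;
            dact(c, b * HW + i + Hf * j) +=
              dcur(ip, jp, (arma::uword)(c + cl.cout * b));
          }
    dact %= cache.relu_mask;
    double N = HW * B;
    gGamma[l] = arma::sum(dact % cache.xhat, 1);
    gBeta[l] = arma::sum(dact, 1);
    arma::mat dxhat = dact.each_col() % cl.gamma;
    arma::vec sum_dxhat = arma::sum(dxhat, 1);
    arma::vec sum_dxhat_xhat = arma::sum(dxhat % cache.xhat, 1);
    arma::mat dpre = dxhat;
    dpre.each_col() -= sum_dxhat / N;
    dpre -= cache.xhat.each_col() % (sum_dxhat_xhat / N);
    dpre.each_col() %= cache.ivar;
    gW[l].zeros(cl.W.n_rows, cl.W.n_cols);
    gB[l] = arma::sum(dpre, 1);
    arma::cube dprev;
    if (l > 0) dprev.zeros(Hf, Wf, (arma::uword)(cl.cin * B));
    for (int b = 0; b < B; ++b) {
      arma::mat dp = dpre.cols(b * HW, (b + 1) * HW - 1);
      gW[l] += dp * cache.cols[b].t();
      if (l > 0) {
        arma::mat dcol = cl.W.t() * dp;
        col2im_add(dprev, dcol, b, cl.cin, Hf, Wf, cl.k);
      }
    }
    if (l > 0) dcur = std::move(dprev);
  }
  List out_conv(nconv);
  for (int l = 0; l < nconv; ++l) {
    out_conv[l] = List::create(_["W"] = gW[l], _["b"] = arma::mat(gB[l]),
                               _["gamma"] = arma::mat(gGamma[l]),
                               _["beta"] = arma::mat(gBeta[l]));
  }
  return List::create(
    _["loss"] = loss, _["conv"] = out_conv,
    _["dense1"] = List::create(_["W"] = gWd1, _["b"] = arma::mat(gbd1)),
    _["dense2"] = List::create(_["W"] = gWd2, _["b"] = arma::mat(gbd2)));
}
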