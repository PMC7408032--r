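// 1D convolutional network for spectral classification.
// Valid (unpadded) convolutions via im2col + GEMM, ReLU, max-pooling,
// one dropout-regularized dense hidden layer, softmax output.
// Training: SGD with momentum and L2 penalty on weights, early stopping on
// validation classification error with best-weight restore.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Arch {
  int n_conv;                 // total conv blocks (section depth + 2)
  int kernel;
  std::vector<int> filters;   // per conv block
  int pool;
  int dense_units;
  int n_classes;
  double dropout;
  int input_len;
  std::vector<int> conv_len;  // length after conv l
  std::vector<int> pool_len;  // length after pool l
  int flat;
};

static Arch make_arch(const Rcpp::List& a) {
  Arch ar;
  ar.kernel = Rcpp::as<int>(a["filter_size"]);
  ar.filters = Rcpp::as<std::vector<int>>(a["filters"]);
  ar.n_conv = (int)ar.filters.size();
  ar.pool = Rcpp::as<int>(a["pool_size"]);
  ar.dense_units = Rcpp::as<int>(a["dense_units"]);
  ar.n_classes = Rcpp::as<int>(a["n_classes"]);
  ar.dropout = Rcpp::as<double>(a["dropout_rate"]);
  ar.input_len = Rcpp::as<int>(a["input_length"]);
  int len = ar.input_len;
  for (int l = 0; l < ar.n_conv; ++l) {
    int cl = len - ar.kernel + 1;
    if (cl < 1) Rcpp::stop("conv block %d: length %d below kernel %d",
                           l + 1, len, ar.kernel);
    int pl = cl / ar.pool;
    if (pl < 1) Rcpp::stop("conv block %d: pooled length reaches 0", l + 1);
    ar.conv_len.push_back(cl);
    ar.pool_len.push_back(pl);
    len = pl;
  }
  ar.flat = len * ar.filters[ar.n_conv - 1];
  return ar;
}

struct Weights {
  std::vector<mat> Wc;  // (f_l x k*c_{l-1})
  std::vector<vec> bc;
  mat W1, W2;           // dense hidden, output
  vec b1, b2;
};

static Weights init_weights(const Arch& ar, std::mt19937_64& rng) {
  Weights w;
  std::normal_distribution<double> N(0.0, 1.0);
  int cin = 1;
  for (int l = 0; l < ar.n_conv; ++l) {
    int fan_in = ar.kernel * cin;
    mat W(ar.filters[l], fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = N(rng) * std::sqrt(2.0 / fan_in);
    w.Wc.push_back(W);
    w.bc.push_back(vec(ar.filters[l], fill::zeros));
    cin = ar.filters[l];
  }
  w.W1.set_size(ar.dense_units, ar.flat);
  for (uword i = 0; i < w.W1.n_elem; ++i)
    w.W1(i) = N(rng) * std::sqrt(2.0 / ar.flat);
  w.b1 = vec(ar.dense_units, fill::zeros);
  w.W2.set_size(ar.n_classes, ar.dense_units);
  for (uword i = 0; i < w.W2.n_elem; ++i)
    w.W2(i) = N(rng) * std::sqrt(2.0 / ar.dense_units);
  w.b2 = vec(ar.n_classes, fill::zeros);
  return w;
}

// im2col over a batch: A (len x channels x m) -> P (k*channels x m*Lout)
static mat im2col(const cube& A, int kernel, int Lout) {
  int len = A.n_rows, ch = A.n_cols, m = A.n_slices;
  mat P(kernel * ch, (uword)m * Lout);
  for (int s = 0; s < m; ++s) {
    const mat& As = A.slice(s);
    for (int j = 0; j < Lout; ++j) {
      uword col = (uword)s * Lout + j;
      for (int c = 0; c < ch; ++c)
        for (int t = 0; t < kernel; ++t)
          P((uword)c * kernel + t, col) = As(j + t, c);
    }
  }
  return P;
}

static cube col2im(const mat& dP, int len, int ch, int m, int kernel, int Lout) {
  cube dA(len, ch, m, fill::zeros);
  for (int s = 0; s < m; ++s) {
    mat& dAs = dA.slice(s);
    for (int j = 0; j < Lout; ++j) {
      uword col = (uword)s * Lout + j;
      for (int c = 0; c < ch; ++c)
        for (int t = 0; t < kernel; ++t)
          dAs(j + t, c) += dP((uword)c * kernel + t, col);
    }
  }
  return dA;
}

struct Cache {
  std::vector<mat> P;        // im2col inputs per conv layer
  std::vector<mat> Z;        // pre-activation (f x m*Lout)
  std::vector<cube> Apool;   // pooled activations
  std::vector<umat> argmax;  // pool argmax (f x m*Lpool) flat index into Lout
  mat flat;                  // flat x m
  mat H1, M1;                // dense hidden activation, dropout mask
  mat probs;                 // n_classes x m
};

// forward pass for a batch; X rows are samples (m x L)
static void forward(const Arch& ar, const Weights& w, const mat& Xb,
                    bool training, double dropout, std::mt19937_64& rng,
                    Cache& cc) {
  int m = Xb.n_rows;
  cube A(ar.input_len, 1, m);
  for (int s = 0; s < m; ++s) A.slice(s).col(0) = Xb.row(s).t();
  cc.P.clear(); cc.Z.clear(); cc.Apool.clear(); cc.argmax.clear();
  for (int l = 0; l < ar.n_conv; ++l) {
    int Lout = ar.conv_len[l], Lp = ar.pool_len[l], f = ar.filters[l];
    mat P = im2col(A, ar.kernel, Lout);
    mat Z = w.Wc[l] * P;
    Z.each_col() += w.bc[l];
    mat R = clamp(Z, 0.0, datum::inf);           // ReLU
    cube Ap(Lp, f, m);
    umat am(f, (uword)m * Lp);
    for (int s = 0; s < m; ++s) {
      for (int j = 0; j < Lp; ++j) {
        uword c0 = (uword)s * Lout + (uword)j * ar.pool;
        for (int q = 0; q < f; ++q) {
          double best = R(q, c0); uword bi = c0;
          for (int t = 1; t < ar.pool; ++t) {
            if (R(q, c0 + t) > best) { best = R(q, c0 + t); bi = c0 + t; }
          }
          Ap(j, q, s) = best;
          am(q, (uword)s * Lp + j) = bi;
        }
      }
    }
    cc.P.push_back(std::move(P));
    cc.Z.push_back(std::move(Z));
    cc.Apool.push_back(Ap);
    cc.argmax.push_back(std::move(am));
    A = std::move(Ap);
  }
  cc.flat.set_size(ar.flat, m);
  for (int s = 0; s < m; ++s) cc.flat.col(s) = vectorise(A.slice(s));
  mat H1 = w.W1 * cc.flat;
  H1.each_col() += w.b1;
  H1 = clamp(H1, 0.0, datum::inf);
  if (training && dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    cc.M1.set_size(H1.n_rows, H1.n_cols);
    for (uword i = 0; i < cc.M1.n_elem; ++i)
      cc.M1(i) = (U(rng) >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
    H1 %= cc.M1;
  } else {
    cc.M1.reset();
  }
  cc.H1 = H1;
  mat S = w.W2 * H1;
  S.each_col() += w.b2;
  S.each_row() -= max(S, 0);
  mat E = exp(S);
  rowvec denom = sum(E, 0);
  E.each_row() /= denom;
  cc.probs = std::move(E);
}

struct Grads {
  std::vector<mat> dWc;
  std::vector<vec> dbc;
  mat dW1, dW2;
  vec db1, db2;
};

static Grads backward(const Arch& ar, const Weights& w, const Cache& cc,
                      const uvec& yb) {
  int m = yb.n_elem;
  Grads g;
  mat dS = cc.probs;                       // softmax + CE gradient
  for (int s = 0; s < m; ++s) dS(yb(s), s) -= 1.0;
  dS /= (double)m;
  g.dW2 = dS * cc.H1.t();
  g.db2 = sum(dS, 1);
  mat dH1 = w.W2.t() * dS;
  if (!cc.M1.is_empty()) dH1 %= cc.M1;
  dH1 %= conv_to<mat>::from(cc.H1 > 0);
  g.dW1 = dH1 * cc.flat.t();
  g.db1 = sum(dH1, 1);
  mat dflat = w.W1.t() * dH1;              // flat x m

  // unflatten into pooled-activation gradient of the last conv block
  int L = ar.n_conv;
  cube dAp(ar.pool_len[L - 1], ar.filters[L - 1], m);
  for (int s = 0; s < m; ++s)
    dAp.slice(s) = reshape(dflat.col(s), ar.pool_len[L - 1], ar.filters[L - 1]);

  g.dWc.resize(L);
  g.dbc.resize(L);
  for (int l = L - 1; l >= 0; --l) {
    int Lout = ar.conv_len[l], Lp = ar.pool_len[l], f = ar.filters[l];
    // un-pool through stored argmax into dZ, masking ReLU
    mat dZ(f, (uword)m * Lout, fill::zeros);
    for (int s = 0; s < m; ++s)
      for (int j = 0; j < Lp; ++j)
        for (int q = 0; q < f; ++q)
          dZ(q, cc.argmax[l](q, (uword)s * Lp + j)) += dAp(j, q, s);
    dZ %= conv_to<mat>::from(cc.Z[l] > 0);
    g.dWc[l] = dZ * cc.P[l].t();
    g.dbc[l] = sum(dZ, 1);
    if (l > 0) {
      mat dP = w.Wc[l].t() * dZ;
      cube dA = col2im(dP, ar.pool_len[l - 1], ar.filters[l - 1], m,
                       ar.kernel, Lout);
      dAp = std::move(dA);
    }
  }
  return g;
}

static double eval_loss_err(const Arch& ar, const Weights& w, const mat& X,
                            const uvec& y, double& err,
                            std::mt19937_64& rng) {
  int n = X.n_rows;
  double loss = 0.0;
  int wrong = 0;
  Cache cc;
  int chunk = 64;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    int s1 = std::min(n, s0 + chunk);
    mat Xb = X.rows(s0, s1 - 1);
    forward(ar, w, Xb, false, 0.0, rng, cc);
    for (int s = 0; s < s1 - s0; ++s) {
      double p = std::max(cc.probs(y(s0 + s), s), 1e-12);
      loss -= std::log(p);
      uword pred = index_max(cc.probs.col(s));
      // ties resolved toward the lowest class index
      double mx = cc.probs.col(s).max();
      for (uword q = 0; q < cc.probs.n_rows; ++q)
        if (cc.probs(q, s) == mx) { pred = q; break; }
      if ((int)pred != (int)y(s0 + s)) ++wrong;
    }
  }
  err = (double)wrong / n;
  return loss / n;
}

static Rcpp::List weights_to_list(const Weights& w) {
  Rcpp::List conv(w.Wc.size());
  for (size_t l = 0; l < w.Wc.size(); ++l) {
    conv[l] = Rcpp::List::create(Rcpp::Named("W") = w.Wc[l],
                                 Rcpp::Named("b") = w.bc[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("conv") = conv,
    Rcpp::Named("W1") = w.W1, Rcpp::Named("b1") = w.b1,
    Rcpp::Named("W2") = w.W2, Rcpp::Named("b2") = w.b2);
}

static Weights weights_from_list(const Rcpp::List& wl) {
  Weights w;
  Rcpp::List conv = wl["conv"];
  for (int l = 0; l < conv.size(); ++l) {
    Rcpp::List cl = conv[l];
    w.Wc.push_back(Rcpp::as<mat>(cl["W"]));
    w.bc.push_back(Rcpp::as<vec>(cl["b"]));
  }
  w.W1 = Rcpp::as<mat>(wl["W1"]); w.b1 = Rcpp::as<vec>(wl["b1"]);
  w.W2 = Rcpp::as<mat>(wl["W2"]); w.b2 = Rcpp::as<vec>(wl["b2"]);
  return w;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::mat& Xtr, const arma::ivec& ytr,
                         const arma::mat& Xval, const arma::ivec& yval,
                         const Rcpp::List& arch, const Rcpp::List& par) {
  Arch ar = make_arch(arch);
  double lr = Rcpp::as<double>(par["learning_rate"]);
  double momentum = Rcpp::as<double>(par["momentum"]);
  double l2 = Rcpp::as<double>(par["l2"]);
  int batch = Rcpp::as<int>(par["batch_size"]);
  int max_epochs = Rcpp::as<int>(par["max_epochs"]);
  int patience = Rcpp::as<int>(par["patience"]);
  unsigned long seed = Rcpp::as<unsigned long>(par["seed"]);
  std::mt19937_64 rng(seed);

  Weights w = init_weights(ar, rng);
  Weights vel = w;  // same shapes
  for (auto& M : vel.Wc) M.zeros();
  for (auto& v : vel.bc) v.zeros();
  vel.W1.zeros(); vel.b1.zeros(); vel.W2.zeros(); vel.b2.zeros();

  uvec y = conv_to<uvec>::from(ytr);
  uvec yv = conv_to<uvec>::from(yval);
  int n = Xtr.n_rows;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Weights best = w;
  double best_err = datum::inf, best_loss = datum::inf;
  int best_epoch = 0, wait = 0, epoch = 0;
  std::vector<double> h_tl, h_ta, h_vl, h_va;

  auto sgd_step = [&](mat& W, mat& V, const mat& G) {
    V = momentum * V - lr * (G + l2 * W);
    W += V;
  };
  auto sgd_step_b = [&](vec& b, vec& V, const vec& G) {
    V = momentum * V - lr * G;
    b += V;
  };

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    Cache cc;
    // train loss/accuracy are running minibatch statistics (computed from
    // the forward pass before each update), not a separate full-set pass
    double run_loss = 0.0;
    int run_wrong = 0;
    for (int s0 = 0; s0 < n; s0 += batch) {
      int s1 = std::min(n, s0 + batch);
      int m = s1 - s0;
      mat Xb(m, Xtr.n_cols);
      uvec yb(m);
      for (int i = 0; i < m; ++i) {
        Xb.row(i) = Xtr.row(order[s0 + i]);
        yb(i) = y(order[s0 + i]);
      }
      forward(ar, w, Xb, true, ar.dropout, rng, cc);
      if (!cc.probs.is_finite()) {
        Rcpp::stop("training diverged (non-finite loss) at epoch %d with learning rate %g",
                   epoch, lr);
      }
      for (int i = 0; i < m; ++i) {
        run_loss -= std::log(std::max(cc.probs(yb(i), i), 1e-12));
        uword pred = 0; double mx = cc.probs(0, i);
        for (uword q = 1; q < cc.probs.n_rows; ++q)
          if (cc.probs(q, i) > mx) { mx = cc.probs(q, i); pred = q; }
        if (pred != yb(i)) ++run_wrong;
      }
      Grads g = backward(ar, w, cc, yb);
      for (int l = 0; l < ar.n_conv; ++l) {
        sgd_step(w.Wc[l], vel.Wc[l], g.dWc[l]);
        sgd_step_b(w.bc[l], vel.bc[l], g.dbc[l]);
      }
      sgd_step(w.W1, vel.W1, g.dW1);
      sgd_step_b(w.b1, vel.b1, g.db1);
      sgd_step(w.W2, vel.W2, g.dW2);
      sgd_step_b(w.b2, vel.b2, g.db2);
    }
    double verr;
    double tloss = run_loss / n;
    double terr = (double)run_wrong / n;
    double vloss = eval_loss_err(ar, w, Xval, yv, verr, rng);
    if (!std::isfinite(tloss) || !std::isfinite(vloss)) {
      Rcpp::stop("training diverged (non-finite loss) at epoch %d with learning rate %g",
                 epoch, lr);
    }
    h_tl.push_back(tloss); h_ta.push_back(1 - terr);
    h_vl.push_back(vloss); h_va.push_back(1 - verr);
    bool improved = (verr < best_err) ||
                    (verr == best_err && vloss < best_loss - 1e-12);
    if (improved) {
      best_err = verr; best_loss = vloss; best = w;
      best_epoch = epoch; wait = 0;
    } else {
      ++wait;
      if (wait > patience) break;
    }
  }
  int stopped = std::min(epoch, max_epochs);

  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_to_list(best),
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = Rcpp::seq(1, (int)h_tl.size()),
      Rcpp::Named("train_loss") = h_tl, Rcpp::Named("train_acc") = h_ta,
      Rcpp::Named("val_loss") = h_vl, Rcpp::Named("val_acc") = h_va),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_error") = best_err,
    Rcpp::Named("stopped_epoch") = stopped);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(const Rcpp::List& weights, const Rcpp::List& arch,
                          const arma::mat& X) {
  Arch ar = make_arch(arch);
  if ((int)X.n_cols != ar.input_len)
    Rcpp::stop("input length %d does not match the network's training length %d",
               (int)X.n_cols, ar.input_len);
  Weights w = weights_from_list(weights);
  std::mt19937_64 rng(0);
  Cache cc;
  mat out(X.n_rows, ar.n_classes);
  int chunk = 256;
  for (int s0 = 0; s0 < (int)X.n_rows; s0 += chunk) {
    int s1 = std::min((int)X.n_rows, s0 + chunk);
    forward(ar, w, X.rows(s0, s1 - 1), false, 0.0, rng, cc);
    out.rows(s0, s1 - 1) = cc.probs.t();
  }
  return out;
}
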