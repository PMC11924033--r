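// Dual-task recurrent network: two stacked bidirectional GRU layers over the
// per-cut feature tensor, batch normalization, a fully connected stack with
// dropout, and a single-unit head (sigmoid for direction classification,
// linear for slope regression). Training is full backpropagation through
// time with Adam, minibatches, and early stopping on validation loss.
//
// Everything is seeded through an internal RNG so that a fixed seed plus
// fixed data reproduces the run exactly.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

struct Cfg {
  bool classify;
  bool use_recurrent;
  int T, F, H, f1, f2, dense;
  double lr, dropout;
  int batch, patience, max_epochs, min_epochs;
  // recurrent readout: temporal mean of the top-layer outputs concatenated
  // with the central-timestep output (the CpG-centered cut)
  int enc_dim() const { return use_recurrent ? 4 * H : dense; }
  int mid() const { return (T - 1) / 2; }
};

static Cfg cfg_from(const Rcpp::List& opts) {
  Cfg c;
  c.classify = Rcpp::as<std::string>(opts["task"]) == "CLASSIFY";
  c.use_recurrent = Rcpp::as<bool>(opts["use_recurrent"]);
  c.T = Rcpp::as<int>(opts["T"]);
  c.F = Rcpp::as<int>(opts["F"]);
  c.H = Rcpp::as<int>(opts["hidden"]);
  c.f1 = Rcpp::as<int>(opts["fc1"]);
  c.f2 = Rcpp::as<int>(opts["fc2"]);
  c.dense = Rcpp::as<int>(opts["dense_units"]);
  c.lr = Rcpp::as<double>(opts["learning_rate"]);
  c.dropout = Rcpp::as<double>(opts["dropout"]);
  c.batch = Rcpp::as<int>(opts["batch_size"]);
  c.patience = Rcpp::as<int>(opts["patience"]);
  c.min_epochs = Rcpp::as<int>(opts["min_epochs"]);
  c.max_epochs = Rcpp::as<int>(opts["max_epochs"]);
  return c;
}

// ---------------------------------------------------------------- parameters

struct Params {
  std::vector<std::string> names;
  std::vector<mat> mats;
  std::vector<bool> trainable;

  void add(const std::string& nm, mat m, bool train = true) {
    names.push_back(nm);
    mats.push_back(std::move(m));
    trainable.push_back(train);
  }
  mat& operator[](const std::string& nm) {
    for (size_t i = 0; i < names.size(); ++i)
      if (names[i] == nm) return mats[i];
    Rcpp::stop("unknown parameter: " + nm);
  }
  int index(const std::string& nm) const {
    for (size_t i = 0; i < names.size(); ++i)
      if (names[i] == nm) return (int)i;
    Rcpp::stop("unknown parameter: " + nm);
  }
};

static mat glorot(int nr, int nc, std::mt19937_64& rng) {
  double lim = std::sqrt(6.0 / (nr + nc));
  std::uniform_real_distribution<double> u(-lim, lim);
  mat m(nr, nc);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(rng);
  return m;
}

// Orthogonal recurrent init (per gate block) for stable gradient flow.
static mat orth_block(int H, std::mt19937_64& rng) {
  std::normal_distribution<double> g(0.0, 1.0);
  mat a(H, H);
  for (uword j = 0; j < a.n_cols; ++j)
    for (uword i = 0; i < a.n_rows; ++i) a(i, j) = g(rng);
  mat Q, R;
  qr_econ(Q, R, a);
  return Q;
}

static void add_gru(Params& p, const std::string& tag, int fin, int H,
                    std::mt19937_64& rng) {
  p.add(tag + "_W", glorot(fin, 3 * H, rng));
  mat U = join_rows(orth_block(H, rng), orth_block(H, rng), orth_block(H, rng));
  p.add(tag + "_U", U);
  p.add(tag + "_b", mat(1, 3 * H, fill::zeros));
}

static void add_bn(Params& p, const std::string& tag, int w) {
  p.add(tag + "_gamma", mat(1, w, fill::ones));
  p.add(tag + "_beta", mat(1, w, fill::zeros));
  p.add(tag + "_rmean", mat(1, w, fill::zeros), false);
  p.add(tag + "_rvar", mat(1, w, fill::ones), false);
}

static Params init_params(const Cfg& c, uint64_t seed) {
  std::mt19937_64 rng(seed);
  Params p;
  add_bn(p, "bni", c.T * c.F);  // input normalization per (cut, feature)
  if (c.use_recurrent) {
    add_gru(p, "gru1f", c.F, c.H, rng);
    add_gru(p, "gru1b", c.F, c.H, rng);
    add_gru(p, "gru2f", 2 * c.H, c.H, rng);
    add_gru(p, "gru2b", 2 * c.H, c.H, rng);
  } else {
    p.add("enc_W", glorot(c.T * c.F, c.dense, rng));
    p.add("enc_b", mat(1, c.dense, fill::zeros));
  }
  add_bn(p, "bn0", c.enc_dim());
  p.add("fc1_W", glorot(c.enc_dim(), c.f1, rng));
  p.add("fc1_b", mat(1, c.f1, fill::zeros));
  add_bn(p, "bn1", c.f1);
  p.add("fc2_W", glorot(c.f1, c.f2, rng));
  p.add("fc2_b", mat(1, c.f2, fill::zeros));
  p.add("head_W", glorot(c.f2, 1, rng));
  p.add("head_b", mat(1, 1, fill::zeros));
  return p;
}

static Params params_from_list(const Rcpp::List& lst) {
  Params p;
  Rcpp::CharacterVector nms = lst.names();
  Rcpp::LogicalVector tr = lst.attr("trainable");
  for (int i = 0; i < lst.size(); ++i)
    p.add(Rcpp::as<std::string>(nms[i]), Rcpp::as<mat>(lst[i]), tr[i]);
  return p;
}

static Rcpp::List params_to_list(const Params& p) {
  Rcpp::List out(p.mats.size());
  Rcpp::CharacterVector nms(p.mats.size());
  Rcpp::LogicalVector tr(p.mats.size());
  for (size_t i = 0; i < p.mats.size(); ++i) {
    out[i] = Rcpp::wrap(p.mats[i]);
    nms[i] = p.names[i];
    tr[i] = (bool)p.trainable[i];
  }
  out.names() = nms;
  out.attr("trainable") = tr;
  return out;
}

// ------------------------------------------------------------------- pieces

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GRUCache {
  std::vector<mat> x, hprev, z, r, n, hh, h;
};

// One GRU direction over a T-step sequence of (B x Fin) inputs.
static void gru_forward(const std::vector<mat>& X, const mat& W, const mat& U,
                        const mat& b, int H, bool reverse, GRUCache& cc) {
  int T = X.size();
  int B = X[0].n_rows;
  cc.x.resize(T); cc.hprev.resize(T); cc.z.resize(T); cc.r.resize(T);
  cc.n.resize(T); cc.hh.resize(T); cc.h.resize(T);
  mat h(B, H, fill::zeros);
  for (int k = 0; k < T; ++k) {
    int t = reverse ? T - 1 - k : k;
    mat xw = X[t] * W;
    mat az = xw.cols(0, H - 1) + h * U.cols(0, H - 1);
    az.each_row() += b.cols(0, H - 1);
    mat ar = xw.cols(H, 2 * H - 1) + h * U.cols(H, 2 * H - 1);
    ar.each_row() += b.cols(H, 2 * H - 1);
    mat z = sigmoid(az), r = sigmoid(ar);
    mat hh = h * U.cols(2 * H, 3 * H - 1);
    mat an = xw.cols(2 * H, 3 * H - 1) + r % hh;
    an.each_row() += b.cols(2 * H, 3 * H - 1);
    mat n = tanh(an);
    cc.x[t] = X[t]; cc.hprev[t] = h; cc.z[t] = z; cc.r[t] = r;
    cc.n[t] = n; cc.hh[t] = hh;
    h = (1.0 - z) % n + z % h;
    cc.h[t] = h;
  }
}

// Backward through one direction. dOut[t] is dL/dh_t as emitted at step t;
// dX[t] is accumulated in place.
static void gru_backward(const GRUCache& cc, const mat& W, const mat& U,
                         int H, bool reverse, const std::vector<mat>& dOut,
                         std::vector<mat>& dX, mat& gW, mat& gU, mat& gb) {
  int T = cc.x.size();
  int B = cc.x[0].n_rows;
  mat dh(B, H, fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    int t = reverse ? T - 1 - k : k;
    dh += dOut[t];
    const mat &z = cc.z[t], &r = cc.r[t], &n = cc.n[t], &hh = cc.hh[t],
              &hprev = cc.hprev[t];
    mat dz = dh % (hprev - n);
    mat dn = dh % (1.0 - z);
    mat dan = dn % (1.0 - n % n);
    mat dhh = dan % r;
    mat dr = dan % hh;
    mat dar = dr % r % (1.0 - r);
    mat daz = dz % z % (1.0 - z);
    dX[t] += daz * W.cols(0, H - 1).t() + dar * W.cols(H, 2 * H - 1).t()
           + dan * W.cols(2 * H, 3 * H - 1).t();
    gW.cols(0, H - 1) += cc.x[t].t() * daz;
    gW.cols(H, 2 * H - 1) += cc.x[t].t() * dar;
    gW.cols(2 * H, 3 * H - 1) += cc.x[t].t() * dan;
    gU.cols(0, H - 1) += hprev.t() * daz;
    gU.cols(H, 2 * H - 1) += hprev.t() * dar;
    gU.cols(2 * H, 3 * H - 1) += hprev.t() * dhh;
    gb.cols(0, H - 1) += sum(daz, 0);
    gb.cols(H, 2 * H - 1) += sum(dar, 0);
    gb.cols(2 * H, 3 * H - 1) += sum(dan, 0);
    dh = dh % z + daz * U.cols(0, H - 1).t() + dar * U.cols(H, 2 * H - 1).t()
       + dhh * U.cols(2 * H, 3 * H - 1).t();
  }
}

struct BNCache { mat xhat; rowvec istd; };

static mat bn_forward(const mat& x, mat& gamma, mat& beta, mat& rmean,
                      mat& rvar, bool training, BNCache& cc) {
  rowvec mu, v;
  if (training) {
    mu = mean(x, 0);
    mat xc = x.each_row() - mu;
    v = mean(xc % xc, 0);
    rmean = BN_MOMENTUM * rmean + (1.0 - BN_MOMENTUM) * mu;
    rvar = BN_MOMENTUM * rvar + (1.0 - BN_MOMENTUM) * v;
  } else {
    mu = rmean.row(0);
    v = rvar.row(0);
  }
  cc.istd = 1.0 / sqrt(v + BN_EPS);
  cc.xhat = (x.each_row() - mu).each_row() % cc.istd;
  mat y = cc.xhat.each_row() % gamma.row(0);
  y.each_row() += beta.row(0);
  return y;
}

static mat bn_backward(const mat& dy, const BNCache& cc, const mat& gamma,
                       mat& dgamma, mat& dbeta) {
  double B = (double)dy.n_rows;
  dgamma += sum(dy % cc.xhat, 0);
  dbeta += sum(dy, 0);
  mat dxhat = dy.each_row() % gamma.row(0);
  rowvec s1 = sum(dxhat, 0);
  rowvec s2 = sum(dxhat % cc.xhat, 0);
  mat dx = B * dxhat;
  dx.each_row() -= s1;
  dx -= cc.xhat.each_row() % s2;
  dx.each_row() %= (cc.istd / B);
  return dx;
}

// ------------------------------------------------------------- full network

struct FwdCache {
  GRUCache g1f, g1b, g2f, g2b;
  std::vector<mat> seq0;          // normalized layer-1 inputs (B x F per step)
  std::vector<mat> seq1;          // layer-2 inputs (B x 2H per step)
  mat flat;                       // raw flattened input (B x T*F)
  mat flat_n;                     // normalized flattened input
  mat enc_pre;                    // dense encoder pre-activation
  mat enc, h0, a1, d1mask, h1, a2, d2mask, pen_drop;
  BNCache bni, bn0, bn1;
};

static std::vector<mat> seq_from_array(const double* X, int N, int T, int F,
                                       const uvec& idx) {
  std::vector<mat> out(T);
  int B = idx.n_elem;
  for (int t = 0; t < T; ++t) {
    mat m(B, F);
    for (int f = 0; f < F; ++f) {
      const double* col = X + (size_t)N * t + (size_t)N * T * f;
      for (int b = 0; b < B; ++b) m(b, f) = col[idx[b]];
    }
    out[t] = std::move(m);
  }
  return out;
}

static mat dropout_mask(int nr, int nc, double p, std::mt19937_64& rng) {
  std::uniform_real_distribution<double> u(0.0, 1.0);
  mat m(nr, nc);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (u(rng) >= p) ? 1.0 / (1.0 - p) : 0.0;
  return m;
}

// Forward pass; returns logits (B x 1).
static mat net_forward(Params& p, const Cfg& c, const std::vector<mat>& X,
                       bool training, std::mt19937_64& rng, FwdCache& cc) {
  int B = X[0].n_rows;
  cc.flat.set_size(B, c.T * c.F);
  for (int t = 0; t < c.T; ++t)
    cc.flat.cols(t * c.F, (t + 1) * c.F - 1) = X[t];
  cc.flat_n = bn_forward(cc.flat, p["bni_gamma"], p["bni_beta"],
                         p["bni_rmean"], p["bni_rvar"], training, cc.bni);
  if (c.use_recurrent) {
    cc.seq0.resize(c.T);
    for (int t = 0; t < c.T; ++t)
      cc.seq0[t] = cc.flat_n.cols(t * c.F, (t + 1) * c.F - 1);
    gru_forward(cc.seq0, p["gru1f_W"], p["gru1f_U"], p["gru1f_b"], c.H, false, cc.g1f);
    gru_forward(cc.seq0, p["gru1b_W"], p["gru1b_U"], p["gru1b_b"], c.H, true, cc.g1b);
    cc.seq1.resize(c.T);
    for (int t = 0; t < c.T; ++t)
      cc.seq1[t] = join_rows(cc.g1f.h[t], cc.g1b.h[t]);
    gru_forward(cc.seq1, p["gru2f_W"], p["gru2f_U"], p["gru2f_b"], c.H, false, cc.g2f);
    gru_forward(cc.seq1, p["gru2b_W"], p["gru2b_U"], p["gru2b_b"], c.H, true, cc.g2b);
    // temporal mean pooling (every cut contributes regardless of position)
    // concatenated with the central-timestep output (undiluted view of the
    // CpG-centered cut)
    mat pooled = join_rows(cc.g2f.h[0], cc.g2b.h[0]);
    for (int t = 1; t < c.T; ++t)
      pooled += join_rows(cc.g2f.h[t], cc.g2b.h[t]);
    pooled /= (double)c.T;
    cc.enc = join_rows(pooled, cc.g2f.h[c.mid()], cc.g2b.h[c.mid()]);
  } else {
    cc.enc_pre = cc.flat_n * p["enc_W"];
    cc.enc_pre.each_row() += p["enc_b"].row(0);
    cc.enc = clamp(cc.enc_pre, 0.0, datum::inf);
  }
  cc.h0 = bn_forward(cc.enc, p["bn0_gamma"], p["bn0_beta"], p["bn0_rmean"],
                     p["bn0_rvar"], training, cc.bn0);
  cc.a1 = cc.h0 * p["fc1_W"];
  cc.a1.each_row() += p["fc1_b"].row(0);
  mat r1 = clamp(cc.a1, 0.0, datum::inf);
  if (training && c.dropout > 0) {
    cc.d1mask = dropout_mask(r1.n_rows, r1.n_cols, c.dropout, rng);
    r1 %= cc.d1mask;
  } else cc.d1mask.reset();
  cc.h1 = bn_forward(r1, p["bn1_gamma"], p["bn1_beta"], p["bn1_rmean"],
                     p["bn1_rvar"], training, cc.bn1);
  cc.a2 = cc.h1 * p["fc2_W"];
  cc.a2.each_row() += p["fc2_b"].row(0);
  mat r2 = clamp(cc.a2, 0.0, datum::inf);
  if (training && c.dropout > 0) {
    cc.d2mask = dropout_mask(r2.n_rows, r2.n_cols, c.dropout, rng);
    cc.pen_drop = r2 % cc.d2mask;
  } else {
    cc.d2mask.reset();
    cc.pen_drop = r2;
  }
  mat logit = cc.pen_drop * p["head_W"];
  logit.each_row() += p["head_b"].row(0);
  return logit;
}

// Backward pass from dlogit; accumulates into grads (same layout as params).
static void net_backward(Params& p, const Cfg& c, const FwdCache& cc,
                         const mat& dlogit, std::vector<mat>& g) {
  auto G = [&](const std::string& nm) -> mat& { return g[p.index(nm)]; };
  G("head_W") += cc.pen_drop.t() * dlogit;
  G("head_b") += sum(dlogit, 0);
  mat dpen = dlogit * p["head_W"].t();
  if (cc.d2mask.n_elem) dpen %= cc.d2mask;
  mat da2 = dpen % conv_to<mat>::from(cc.a2 > 0);
  G("fc2_W") += cc.h1.t() * da2;
  G("fc2_b") += sum(da2, 0);
  mat dh1 = da2 * p["fc2_W"].t();
  mat dr1 = bn_backward(dh1, cc.bn1, p["bn1_gamma"], G("bn1_gamma"), G("bn1_beta"));
  if (cc.d1mask.n_elem) dr1 %= cc.d1mask;
  mat da1 = dr1 % conv_to<mat>::from(cc.a1 > 0);
  G("fc1_W") += cc.h0.t() * da1;
  G("fc1_b") += sum(da1, 0);
  mat dh0 = da1 * p["fc1_W"].t();
  mat denc = bn_backward(dh0, cc.bn0, p["bn0_gamma"], G("bn0_gamma"), G("bn0_beta"));
  if (c.use_recurrent) {
    int B = denc.n_rows;
    std::vector<mat> d2f(c.T), d2b(c.T);
    mat df = denc.cols(0, c.H - 1) / (double)c.T;
    mat db = denc.cols(c.H, 2 * c.H - 1) / (double)c.T;
    for (int t = 0; t < c.T; ++t) { d2f[t] = df; d2b[t] = db; }
    d2f[c.mid()] += denc.cols(2 * c.H, 3 * c.H - 1);
    d2b[c.mid()] += denc.cols(3 * c.H, 4 * c.H - 1);
    std::vector<mat> dseq1(c.T, mat(B, 2 * c.H, fill::zeros));
    gru_backward(cc.g2f, p["gru2f_W"], p["gru2f_U"], c.H, false, d2f, dseq1,
                 G("gru2f_W"), G("gru2f_U"), G("gru2f_b"));
    gru_backward(cc.g2b, p["gru2b_W"], p["gru2b_U"], c.H, true, d2b, dseq1,
                 G("gru2b_W"), G("gru2b_U"), G("gru2b_b"));
    std::vector<mat> d1f(c.T), d1b(c.T);
    for (int t = 0; t < c.T; ++t) {
      d1f[t] = dseq1[t].cols(0, c.H - 1);
      d1b[t] = dseq1[t].cols(c.H, 2 * c.H - 1);
    }
    std::vector<mat> dX(c.T, mat(B, c.F, fill::zeros));
    gru_backward(cc.g1f, p["gru1f_W"], p["gru1f_U"], c.H, false, d1f, dX,
                 G("gru1f_W"), G("gru1f_U"), G("gru1f_b"));
    gru_backward(cc.g1b, p["gru1b_W"], p["gru1b_U"], c.H, true, d1b, dX,
                 G("gru1b_W"), G("gru1b_U"), G("gru1b_b"));
    mat dflat(B, c.T * c.F);
    for (int t = 0; t < c.T; ++t)
      dflat.cols(t * c.F, (t + 1) * c.F - 1) = dX[t];
    bn_backward(dflat, cc.bni, p["bni_gamma"], G("bni_gamma"), G("bni_beta"));
  } else {
    mat dpre = denc % conv_to<mat>::from(cc.enc_pre > 0);
    G("enc_W") += cc.flat_n.t() * dpre;
    G("enc_b") += sum(dpre, 0);
    mat dflat = dpre * p["enc_W"].t();
    bn_backward(dflat, cc.bni, p["bni_gamma"], G("bni_gamma"), G("bni_beta"));
  }
}

static double loss_and_grad(const mat& logit, const vec& y, bool classify,
                            mat& dlogit) {
  int B = logit.n_rows;
  double loss = 0;
  dlogit.set_size(B, 1);
  if (classify) {
    for (int i = 0; i < B; ++i) {
      double l = logit(i, 0);
      loss += std::max(l, 0.0) - l * y(i) + std::log1p(std::exp(-std::fabs(l)));
      dlogit(i, 0) = (1.0 / (1.0 + std::exp(-l)) - y(i)) / B;
    }
  } else {
    for (int i = 0; i < B; ++i) {
      double e = logit(i, 0) - y(i);
      loss += e * e;
      dlogit(i, 0) = 2.0 * e / B;
    }
  }
  return loss / B;
}

static double eval_loss(Params& p, const Cfg& c, const double* X, int N,
                        const vec& y, std::mt19937_64& rng) {
  double total = 0;
  int bs = std::max(c.batch, 64);
  for (int s = 0; s < N; s += bs) {
    int e = std::min(N, s + bs);
    uvec idx = regspace<uvec>(s, e - 1);
    std::vector<mat> seq = seq_from_array(X, N, c.T, c.F, idx);
    FwdCache cc;
    mat logit = net_forward(p, c, seq, false, rng, cc);
    mat dl;
    total += loss_and_grad(logit, y.subvec(s, e - 1), c.classify, dl) * (e - s);
  }
  return total / N;
}

// ------------------------------------------------------------------ exports

// [[Rcpp::export]]
Rcpp::List cpp_init_params(Rcpp::List opts, int seed) {
  Cfg c = cfg_from(opts);
  Params p = init_params(c, (uint64_t)seed);
  return params_to_list(p);
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List params, Rcpp::NumericVector X,
                     Rcpp::NumericVector y, Rcpp::NumericVector Xval,
                     Rcpp::NumericVector yval, Rcpp::List opts, int seed) {
  Cfg c = cfg_from(opts);
  Params p = params_from_list(params);
  Rcpp::IntegerVector dx = X.attr("dim");
  int N = dx[0];
  Rcpp::IntegerVector dxv = Xval.attr("dim");
  int Nv = dxv[0];
  if (Nv < 1) Rcpp::stop("empty validation set: early stopping undefined");
  vec yv(y.begin(), N, false);
  vec yvv(yval.begin(), Nv, false);
  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 1);

  // Adam state
  std::vector<mat> m(p.mats.size()), v(p.mats.size()), g(p.mats.size());
  for (size_t i = 0; i < p.mats.size(); ++i) {
    m[i] = mat(size(p.mats[i]), fill::zeros);
    v[i] = mat(size(p.mats[i]), fill::zeros);
  }
  double b1 = 0.9, b2 = 0.999;
  long step = 0;

  std::vector<double> train_hist, val_hist;
  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0, epoch = 0, since_best = 0;

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (epoch = 1; epoch <= c.max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0;
    for (int s = 0; s < N; s += c.batch) {
      int e = std::min(N, s + c.batch);
      uvec idx(e - s);
      vec yb(e - s);
      for (int i = s; i < e; ++i) {
        idx[i - s] = order[i];
        yb[i - s] = yv(order[i]);
      }
      std::vector<mat> seq = seq_from_array(X.begin(), N, c.T, c.F, idx);
      FwdCache cc;
      mat logit = net_forward(p, c, seq, true, rng, cc);
      mat dlogit;
      tr_loss += loss_and_grad(logit, yb, c.classify, dlogit) * (e - s);
      for (size_t i = 0; i < g.size(); ++i)
        g[i] = mat(size(p.mats[i]), fill::zeros);
      net_backward(p, c, cc, dlogit, g);
      // global-norm gradient clipping
      double nrm2 = 0;
      for (size_t i = 0; i < g.size(); ++i)
        if (p.trainable[i]) nrm2 += accu(g[i] % g[i]);
      double scale = 1.0;
      double nrm = std::sqrt(nrm2);
      if (nrm > 5.0) scale = 5.0 / nrm;
      ++step;
      double corr = c.lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                    (1.0 - std::pow(b1, (double)step));
      for (size_t i = 0; i < g.size(); ++i) {
        if (!p.trainable[i]) continue;
        mat gi = g[i] * scale;
        m[i] = b1 * m[i] + (1 - b1) * gi;
        v[i] = b2 * v[i] + (1 - b2) * (gi % gi);
        p.mats[i] -= corr * m[i] / (sqrt(v[i]) + 1e-8);
      }
    }
    train_hist.push_back(tr_loss / N);
    double vl = eval_loss(p, c, Xval.begin(), Nv, yvv, rng);
    val_hist.push_back(vl);
    if (vl < best_val - 1e-12) {
      best_val = vl;
      best = p;
      best_epoch = epoch;
      since_best = 0;
    } else {
      ++since_best;
      // the patience counter only fires after the warmup budget, so a
      // noisy plateau in the first epochs cannot end the run
      if (epoch > c.min_epochs && since_best >= c.patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  int stopped = std::min(epoch, c.max_epochs);
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(best),
      Rcpp::Named("train_loss") = train_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("stopped_epoch") = stopped);
}

// mode: 0 = outputs only, 1 = + penultimate, 2 = + hidden states of the top
// recurrent layer (batch x T x 2H).
// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List params, Rcpp::NumericVector X,
                       Rcpp::List opts, int mode) {
  Cfg c = cfg_from(opts);
  Params p = params_from_list(params);
  Rcpp::IntegerVector dx = X.attr("dim");
  int N = dx[0];
  if (dx[1] != c.T || dx[2] != c.F)
    Rcpp::stop("feature array shape (%d, %d) does not match the model (%d, %d)",
               dx[1], dx[2], c.T, c.F);
  if (mode == 2 && !c.use_recurrent)
    Rcpp::stop("hidden states are undefined for the dense-encoder ablation");
  std::mt19937_64 rng(0);
  vec out(N);
  mat pen;
  if (mode >= 1) pen.set_size(N, c.f2);
  Rcpp::NumericVector hid;
  if (mode == 2) {
    hid = Rcpp::NumericVector((size_t)N * c.T * 2 * c.H);
    hid.attr("dim") = Rcpp::IntegerVector::create(N, c.T, 2 * c.H);
  }
  int bs = 256;
  for (int s = 0; s < N; s += bs) {
    int e = std::min(N, s + bs);
    uvec idx = regspace<uvec>(s, e - 1);
    std::vector<mat> seq = seq_from_array(X.begin(), N, c.T, c.F, idx);
    FwdCache cc;
    mat logit = net_forward(p, c, seq, false, rng, cc);
    for (int i = s; i < e; ++i) {
      double l = logit(i - s, 0);
      out(i) = c.classify ? 1.0 / (1.0 + std::exp(-l)) : l;
    }
    if (mode >= 1) pen.rows(s, e - 1) = cc.pen_drop;
    if (mode == 2) {
      for (int t = 0; t < c.T; ++t) {
        mat h2 = join_rows(cc.g2f.h[t], cc.g2b.h[t]);
        for (int u = 0; u < 2 * c.H; ++u)
          for (int i = s; i < e; ++i)
            hid[(size_t)i + (size_t)N * t + (size_t)N * c.T * u] = h2(i - s, u);
      }
    }
  }
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("output") = out);
  if (mode >= 1) res["penultimate"] = pen;
  if (mode == 2) res["hidden"] = hid;
  return res;
}

// Loss and analytic gradient on one batch (training-mode forward, no
// dropout); used for finite-difference verification of the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List params, Rcpp::NumericVector X,
                         Rcpp::NumericVector y, Rcpp::List opts) {
  Cfg c = cfg_from(opts);
  c.dropout = 0;
  Params p = params_from_list(params);
  Rcpp::IntegerVector dx = X.attr("dim");
  int N = dx[0];
  vec yv(y.begin(), N, false);
  uvec idx = regspace<uvec>(0, N - 1);
  std::vector<mat> seq = seq_from_array(X.begin(), N, c.T, c.F, idx);
  std::mt19937_64 rng(0);
  FwdCache cc;
  mat logit = net_forward(p, c, seq, true, rng, cc);
  mat dlogit;
  double loss = loss_and_grad(logit, yv, c.classify, dlogit);
  std::vector<mat> g(p.mats.size());
  for (size_t i = 0; i < g.size(); ++i)
    g[i] = mat(size(p.mats[i]), fill::zeros);
  net_backward(p, c, cc, dlogit, g);
  Params gp;
  for (size_t i = 0; i < g.size(); ++i)
    gp.add(p.names[i], g[i], p.trainable[i]);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = params_to_list(gp));
}

// [[Rcpp::export]]
int cpp_param_count(Rcpp::List params, bool trainable_only) {
  Params p = params_from_list(params);
  int n = 0;
  for (size_t i = 0; i < p.mats.size(); ++i)
    if (!trainable_only || p.trainable[i]) n += p.mats[i].n_elem;
  return n;
}
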