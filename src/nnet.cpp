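// Compiled engine for the sleep-scoring network: a three-branch 1-D CNN
// feature extractor (narrow + wide EEG branches, wide EMG branch) feeding
// either a per-epoch softmax (pretraining head), an FC-only head (rescoring
// variant) or a two-layer bidirectional LSTM + FC-shortcut head (full
// variant).  Forward, backward and the batch-gradient entry points live
// here; parameter initialization and the Adam loop live in R.
//
// Conventions:
//   * one epoch's signal is one column of an (L x n) matrix;
//   * features are one column per epoch (Fd x n);
//   * labels are 1-based stage codes (1=WAKE, 2=NREM, 3=REM);
//   * biases are (k x 1) matrices so all parameters share one container.

#include <RcppArmadillo.h>
#include <map>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::map<std::string, mat> ParamMap;

struct Geom {
  int k1, s1, p1, k2, p2;
};

struct Cfg {
  int L;            // samples per epoch
  int ch1, ch2;     // channels after first / later convs
  Geom nar, wid;    // narrow-filter and wide-filter branch geometry
  int h;            // LSTM units per direction
  int fc;           // FC width
  int nc;           // classes
  double dropout;   // dropout probability (0 disables)
};

static Geom as_geom(const Rcpp::List& g) {
  Geom out;
  out.k1 = Rcpp::as<int>(g["k1"]);
  out.s1 = Rcpp::as<int>(g["s1"]);
  out.p1 = Rcpp::as<int>(g["p1"]);
  out.k2 = Rcpp::as<int>(g["k2"]);
  out.p2 = Rcpp::as<int>(g["p2"]);
  return out;
}

static Cfg as_cfg(const Rcpp::List& c) {
  Cfg out;
  out.L = Rcpp::as<int>(c["samples_per_epoch"]);
  out.ch1 = Rcpp::as<int>(c["ch1"]);
  out.ch2 = Rcpp::as<int>(c["ch2"]);
  out.nar = as_geom(c["narrow_geom"]);
  out.wid = as_geom(c["wide_geom"]);
  out.h = Rcpp::as<int>(c["lstm_per_dir"]);
  out.fc = Rcpp::as<int>(c["fc_units"]);
  out.nc = Rcpp::as<int>(c["n_classes"]);
  out.dropout = Rcpp::as<double>(c["dropout_rate"]);
  return out;
}

static ParamMap as_params(const Rcpp::List& p) {
  ParamMap out;
  Rcpp::CharacterVector nm = p.names();
  for (int i = 0; i < p.size(); ++i)
    out[std::string(nm[i])] = Rcpp::as<mat>(p[i]);
  return out;
}

static Rcpp::List params_to_list(const ParamMap& p) {
  Rcpp::List out;
  for (ParamMap::const_iterator it = p.begin(); it != p.end(); ++it)
    out[it->first] = it->second;
  return out;
}

static ParamMap zeros_like(const ParamMap& p) {
  ParamMap out;
  for (ParamMap::const_iterator it = p.begin(); it != p.end(); ++it)
    out[it->first] = zeros<mat>(it->second.n_rows, it->second.n_cols);
  return out;
}

// Portable uniform stream for dropout masks (never rely on libstdc++
// distribution internals so a seed reproduces across platforms).
struct Uniform01 {
  std::mt19937_64 gen;
  explicit Uniform01(uint64_t seed) : gen(seed) {}
  double operator()() {
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  mat mask(uword r, uword c, double p) {
    mat m(r, c);
    const double scale = 1.0 / (1.0 - p);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i)
        m(i, j) = ((*this)() < p) ? 0.0 : scale;
    return m;
  }
};

// ---------------------------------------------------------------------------
// im2col / col2im

// Valid convolution with stride: X (C x L) -> col (C*k x Lout).
static mat im2col_valid(const mat& X, int k, int s) {
  const int C = X.n_rows, L = X.n_cols;
  const int Lout = (L - k) / s + 1;
  mat col(C * k, Lout);
  for (int t = 0; t < Lout; ++t)
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < C; ++c)
        col(c * k + j, t) = X(c, t * s + j);
  return col;
}

// Same-padded stride-1 convolution patches.
static mat im2col_same(const mat& X, int k) {
  const int C = X.n_rows, L = X.n_cols;
  const int left = (k - 1) / 2;
  mat col(C * k, L, fill::zeros);
  for (int t = 0; t < L; ++t)
    for (int j = 0; j < k; ++j) {
      const int pos = t + j - left;
      if (pos < 0 || pos >= L) continue;
      for (int c = 0; c < C; ++c)
        col(c * k + j, t) = X(c, pos);
    }
  return col;
}

// Adjoint of im2col_same: dcol (C*k x L) -> dX (C x L).
static mat col2im_same(const mat& dcol, int C, int L, int k) {
  const int left = (k - 1) / 2;
  mat dX(C, L, fill::zeros);
  for (int t = 0; t < L; ++t)
    for (int j = 0; j < k; ++j) {
      const int pos = t + j - left;
      if (pos < 0 || pos >= L) continue;
      for (int c = 0; c < C; ++c)
        dX(c, pos) += dcol(c * k + j, t);
    }
  return dX;
}

// Non-overlapping max pooling; records argmax offsets for the backward pass.
static mat maxpool(const mat& X, int p, umat& idx) {
  const int C = X.n_rows, L = X.n_cols;
  const int Lp = L / p;
  mat Y(C, Lp);
  idx.set_size(C, Lp);
  for (int t = 0; t < Lp; ++t)
    for (int c = 0; c < C; ++c) {
      double best = X(c, t * p);
      int bj = 0;
      for (int j = 1; j < p; ++j)
        if (X(c, t * p + j) > best) { best = X(c, t * p + j); bj = j; }
      Y(c, t) = best;
      idx(c, t) = bj;
    }
  return Y;
}

static mat maxpool_back(const mat& dY, const umat& idx, int p, int L) {
  const int C = dY.n_rows, Lp = dY.n_cols;
  mat dX(C, L, fill::zeros);
  for (int t = 0; t < Lp; ++t)
    for (int c = 0; c < C; ++c)
      dX(c, t * p + idx(c, t)) = dY(c, t);
  return dX;
}

// ---------------------------------------------------------------------------
// CNN branch

struct BranchCache {
  rowvec x;           // raw epoch signal (1 x L)
  mat a1;             // post-ReLU conv1 output
  mat p1v; umat p1i;  // pooled
  mat m1;             // dropout mask (empty when dropout off)
  mat d1;             // pooled after dropout (input to conv2a)
  mat a2a, a2b, a2c;
  mat p2v; umat p2i;
};

static int branch_feat_len(const Geom& g, int L, int ch2) {
  const int L1 = (L - g.k1) / g.s1 + 1;
  const int Lp1 = L1 / g.p1;
  const int Lp2 = Lp1 / g.p2;
  return ch2 * Lp2;
}

static vec branch_forward(const rowvec& x, const std::string& pre,
                          const ParamMap& P, const Geom& g, double dropout,
                          Uniform01* rng, BranchCache* cache) {
  mat X(1, x.n_elem);
  X.row(0) = x;
  mat col1 = im2col_valid(X, g.k1, g.s1);
  mat a1 = P.at(pre + "_W1") * col1;
  a1.each_col() += P.at(pre + "_b1").col(0);
  a1.transform([](double v) { return v > 0 ? v : 0.0; });

  umat p1i;
  mat p1v = maxpool(a1, g.p1, p1i);

  mat d1 = p1v, m1;
  if (rng && dropout > 0) {
    m1 = rng->mask(p1v.n_rows, p1v.n_cols, dropout);
    d1 = p1v % m1;
  }

  mat col2a = im2col_same(d1, g.k2);
  mat a2a = P.at(pre + "_W2a") * col2a;
  a2a.each_col() += P.at(pre + "_b2a").col(0);
  a2a.transform([](double v) { return v > 0 ? v : 0.0; });

  mat col2b = im2col_same(a2a, g.k2);
  mat a2b = P.at(pre + "_W2b") * col2b;
  a2b.each_col() += P.at(pre + "_b2b").col(0);
  a2b.transform([](double v) { return v > 0 ? v : 0.0; });

  mat col2c = im2col_same(a2b, g.k2);
  mat a2c = P.at(pre + "_W2c") * col2c;
  a2c.each_col() += P.at(pre + "_b2c").col(0);
  a2c.transform([](double v) { return v > 0 ? v : 0.0; });

  umat p2i;
  mat p2v = maxpool(a2c, g.p2, p2i);

  if (cache) {
    cache->x = x; cache->a1 = a1; cache->p1v = p1v; cache->p1i = p1i;
    cache->m1 = m1; cache->d1 = d1;
    cache->a2a = a2a; cache->a2b = a2b; cache->a2c = a2c;
    cache->p2v = p2v; cache->p2i = p2i;
  }
  return vectorise(p2v);
}

static void branch_backward(const vec& dflat, const std::string& pre,
                            const ParamMap& P, ParamMap& G, const Geom& g,
                            const BranchCache& c) {
  mat dp2v(const_cast<double*>(dflat.memptr()), c.p2v.n_rows, c.p2v.n_cols,
           true, true);
  mat da2c = maxpool_back(dp2v, c.p2i, g.p2, c.a2c.n_cols);
  mat dz2c = da2c % conv_to<mat>::from(c.a2c > 0);
  mat col2c = im2col_same(c.a2b, g.k2);
  G[pre + "_W2c"] += dz2c * col2c.t();
  G[pre + "_b2c"].col(0) += sum(dz2c, 1);
  mat da2b = col2im_same(P.at(pre + "_W2c").t() * dz2c, c.a2b.n_rows,
                         c.a2b.n_cols, g.k2);

  mat dz2b = da2b % conv_to<mat>::from(c.a2b > 0);
  mat col2b = im2col_same(c.a2a, g.k2);
  G[pre + "_W2b"] += dz2b * col2b.t();
  G[pre + "_b2b"].col(0) += sum(dz2b, 1);
  mat da2a = col2im_same(P.at(pre + "_W2b").t() * dz2b, c.a2a.n_rows,
                         c.a2a.n_cols, g.k2);

  mat dz2a = da2a % conv_to<mat>::from(c.a2a > 0);
  mat col2a = im2col_same(c.d1, g.k2);
  G[pre + "_W2a"] += dz2a * col2a.t();
  G[pre + "_b2a"].col(0) += sum(dz2a, 1);
  mat dd1 = col2im_same(P.at(pre + "_W2a").t() * dz2a, c.d1.n_rows,
                        c.d1.n_cols, g.k2);

  mat dp1v = c.m1.n_elem ? mat(dd1 % c.m1) : dd1;
  mat da1 = maxpool_back(dp1v, c.p1i, g.p1, c.a1.n_cols);
  mat dz1 = da1 % conv_to<mat>::from(c.a1 > 0);
  mat X(1, c.x.n_elem);
  X.row(0) = c.x;
  mat col1 = im2col_valid(X, g.k1, g.s1);
  G[pre + "_W1"] += dz1 * col1.t();
  G[pre + "_b1"].col(0) += sum(dz1, 1);
  // gradient w.r.t. the raw signal is never needed
}

// ---------------------------------------------------------------------------
// Feature extraction over a batch of epochs

struct FeatCache {
  std::vector<BranchCache> nar, wid, emg;
};

static mat extract_features(const mat& eeg, const mat& emg, const ParamMap& P,
                            const Cfg& cfg, Uniform01* rng, FeatCache* fcache) {
  const int n = eeg.n_cols;
  const int fn = branch_feat_len(cfg.nar, cfg.L, cfg.ch2);
  const int fw = branch_feat_len(cfg.wid, cfg.L, cfg.ch2);
  mat F(fn + 2 * fw, n);
  if (fcache) {
    fcache->nar.resize(n); fcache->wid.resize(n); fcache->emg.resize(n);
  }
  for (int i = 0; i < n; ++i) {
    rowvec xe = eeg.col(i).t();
    rowvec xm = emg.col(i).t();
    vec f1 = branch_forward(xe, "nar", P, cfg.nar, cfg.dropout, rng,
                            fcache ? &fcache->nar[i] : 0);
    vec f2 = branch_forward(xe, "wid", P, cfg.wid, cfg.dropout, rng,
                            fcache ? &fcache->wid[i] : 0);
    vec f3 = branch_forward(xm, "emg", P, cfg.wid, cfg.dropout, rng,
                            fcache ? &fcache->emg[i] : 0);
    F.col(i) = join_cols(f1, join_cols(f2, f3));
  }
  return F;
}

static void features_backward(const mat& dF, const mat& eeg, const mat& emg,
                              const ParamMap& P, ParamMap& G, const Cfg& cfg,
                              FeatCache& fcache) {
  const int n = dF.n_cols;
  const int fn = branch_feat_len(cfg.nar, cfg.L, cfg.ch2);
  const int fw = branch_feat_len(cfg.wid, cfg.L, cfg.ch2);
  for (int i = 0; i < n; ++i) {
    vec d = dF.col(i);
    branch_backward(d.subvec(0, fn - 1), "nar", P, G, cfg.nar, fcache.nar[i]);
    branch_backward(d.subvec(fn, fn + fw - 1), "wid", P, G, cfg.wid,
                    fcache.wid[i]);
    branch_backward(d.subvec(fn + fw, fn + 2 * fw - 1), "emg", P, G, cfg.wid,
                    fcache.emg[i]);
  }
}

// ---------------------------------------------------------------------------
// LSTM (single direction)

struct LstmCache {
  mat X;                    // input (D x T)
  mat I, Fg, Gg, O, C, H;   // gates & states (h x T)
};

static mat lstm_forward(const mat& X, const mat& W, const mat& U,
                        const vec& b, LstmCache* cache) {
  const int T = X.n_cols;
  const int h = U.n_cols;
  mat I(h, T), Fg(h, T), Gg(h, T), O(h, T), C(h, T), H(h, T);
  vec hprev(h, fill::zeros), cprev(h, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec a = W * X.col(t) + U * hprev + b;
    vec ai = a.subvec(0, h - 1);
    vec af = a.subvec(h, 2 * h - 1);
    vec ag = a.subvec(2 * h, 3 * h - 1);
    vec ao = a.subvec(3 * h, 4 * h - 1);
    vec i = 1.0 / (1.0 + exp(-ai));
    vec f = 1.0 / (1.0 + exp(-af));
    vec g = tanh(ag);
    vec o = 1.0 / (1.0 + exp(-ao));
    vec c = f % cprev + i % g;
    vec hh = o % tanh(c);
    I.col(t) = i; Fg.col(t) = f; Gg.col(t) = g; O.col(t) = o;
    C.col(t) = c; H.col(t) = hh;
    hprev = hh; cprev = c;
  }
  if (cache) {
    cache->X = X; cache->I = I; cache->Fg = Fg; cache->Gg = Gg;
    cache->O = O; cache->C = C; cache->H = H;
  }
  return H;
}

static mat lstm_backward(const mat& dH, const LstmCache& c, const mat& W,
                         const mat& U, mat& dW, mat& dU, vec& db) {
  const int T = c.X.n_cols;
  const int h = U.n_cols;
  mat dX(c.X.n_rows, T, fill::zeros);
  vec dh_next(h, fill::zeros), dc_next(h, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec i = c.I.col(t), f = c.Fg.col(t), g = c.Gg.col(t), o = c.O.col(t);
    vec tc = tanh(c.C.col(t));
    vec cprev = (t == 0) ? vec(h, fill::zeros) : vec(c.C.col(t - 1));
    vec hprev = (t == 0) ? vec(h, fill::zeros) : vec(c.H.col(t - 1));
    vec dh = dH.col(t) + dh_next;
    vec dc = dh % o % (1.0 - tc % tc) + dc_next;
    vec da_o = dh % tc % o % (1.0 - o);
    vec da_i = dc % g % i % (1.0 - i);
    vec da_f = dc % cprev % f % (1.0 - f);
    vec da_g = dc % i % (1.0 - g % g);
    vec da = join_cols(da_i, join_cols(da_f, join_cols(da_g, da_o)));
    dW += da * c.X.col(t).t();
    dU += da * hprev.t();
    db += da;
    dX.col(t) = W.t() * da;
    dh_next = U.t() * da;
    dc_next = dc % f;
  }
  return dX;
}

struct BiCache {
  LstmCache fwd, bwd;
};

static mat bilstm_forward(const mat& X, const std::string& pre,
                          const ParamMap& P, BiCache* cache) {
  mat Hf = lstm_forward(X, P.at(pre + "f_W"), P.at(pre + "f_U"),
                        P.at(pre + "f_b").col(0), cache ? &cache->fwd : 0);
  mat Xr = fliplr(X);
  mat Hbr = lstm_forward(Xr, P.at(pre + "b_W"), P.at(pre + "b_U"),
                         P.at(pre + "b_b").col(0), cache ? &cache->bwd : 0);
  return join_cols(Hf, fliplr(Hbr));
}

static mat bilstm_backward(const mat& dH, const std::string& pre,
                           const ParamMap& P, ParamMap& G, const BiCache& c) {
  const int h = P.at(pre + "f_U").n_cols;
  mat dHf = dH.rows(0, h - 1);
  mat dHbr = fliplr(mat(dH.rows(h, 2 * h - 1)));
  vec dbf = G[pre + "f_b"].col(0), dbb = G[pre + "b_b"].col(0);
  mat dXf = lstm_backward(dHf, c.fwd, P.at(pre + "f_W"), P.at(pre + "f_U"),
                          G[pre + "f_W"], G[pre + "f_U"], dbf);
  mat dXbr = lstm_backward(dHbr, c.bwd, P.at(pre + "b_W"), P.at(pre + "b_U"),
                           G[pre + "b_W"], G[pre + "b_U"], dbb);
  G[pre + "f_b"].col(0) = dbf;
  G[pre + "b_b"].col(0) = dbb;
  return dXf + fliplr(dXbr);
}

// ---------------------------------------------------------------------------
// Heads

static mat softmax_cols(mat Z) {
  for (uword j = 0; j < Z.n_cols; ++j) {
    vec z = Z.col(j);
    z -= z.max();
    vec e = exp(z);
    Z.col(j) = e / accu(e);
  }
  return Z;
}

static mat onehot(const uvec& y, int nc) {
  mat Y(nc, y.n_elem, fill::zeros);
  for (uword i = 0; i < y.n_elem; ++i) Y(y(i) - 1, i) = 1.0;
  return Y;
}

static double ce_loss(const mat& probs, const uvec& y) {
  double s = 0;
  for (uword i = 0; i < y.n_elem; ++i)
    s -= std::log(std::max(probs(y(i) - 1, i), 1e-12));
  return s / y.n_elem;
}

// Full-variant head over one sequence of features.  Returns probs; fills
// caches needed for the backward pass.
struct HeadCache {
  mat F, H1, H2, Pa, Qa, Ms, S;
  BiCache l1, l2;
};

static mat full_head_forward(const mat& F, const ParamMap& P, const Cfg& cfg,
                             Uniform01* rng, HeadCache* hc) {
  mat H1 = bilstm_forward(F, "lstm1", P, hc ? &hc->l1 : 0);
  mat H2 = bilstm_forward(H1, "lstm2", P, hc ? &hc->l2 : 0);
  mat Pa = P.at("proj_W") * H2;
  Pa.each_col() += P.at("proj_b").col(0);
  Pa.transform([](double v) { return v > 0 ? v : 0.0; });
  mat Qa = P.at("fc_W") * F;
  Qa.each_col() += P.at("fc_b").col(0);
  Qa.transform([](double v) { return v > 0 ? v : 0.0; });
  mat S = Pa + Qa, Ms;
  if (rng && cfg.dropout > 0) {
    Ms = rng->mask(S.n_rows, S.n_cols, cfg.dropout);
    S = S % Ms;
  }
  mat logits = P.at("out_W") * S;
  logits.each_col() += P.at("out_b").col(0);
  if (hc) {
    hc->F = F; hc->H1 = H1; hc->H2 = H2; hc->Pa = Pa; hc->Qa = Qa;
    hc->Ms = Ms; hc->S = S;
  }
  return softmax_cols(logits);
}

// dlogits -> dF (also accumulates head parameter gradients)
static mat full_head_backward(const mat& dlogits, const ParamMap& P,
                              ParamMap& G, const HeadCache& hc) {
  G["out_W"] += dlogits * hc.S.t();
  G["out_b"].col(0) += sum(dlogits, 1);
  mat dS = P.at("out_W").t() * dlogits;
  if (hc.Ms.n_elem) dS = dS % hc.Ms;
  mat dPa = dS % conv_to<mat>::from(hc.Pa > 0);
  mat dQa = dS % conv_to<mat>::from(hc.Qa > 0);
  G["proj_W"] += dPa * hc.H2.t();
  G["proj_b"].col(0) += sum(dPa, 1);
  G["fc_W"] += dQa * hc.F.t();
  G["fc_b"].col(0) += sum(dQa, 1);
  mat dH2 = P.at("proj_W").t() * dPa;
  mat dH1 = bilstm_backward(dH2, "lstm2", P, G, hc.l2);
  mat dF = bilstm_backward(dH1, "lstm1", P, G, hc.l1);
  return dF + P.at("fc_W").t() * dQa;
}

// ---------------------------------------------------------------------------
// Exported entry points

// [[Rcpp::export]]
arma::mat cpp_extract_features(const arma::mat& eeg, const arma::mat& emg,
                               const Rcpp::List& params,
                               const Rcpp::List& config) {
  Cfg cfg = as_cfg(config);
  ParamMap P = as_params(params);
  return extract_features(eeg, emg, P, cfg, 0, 0);
}

// [[Rcpp::export]]
Rcpp::List cpp_grad_pretrain(const arma::mat& eeg, const arma::mat& emg,
                             const arma::uvec& y, const Rcpp::List& params,
                             const Rcpp::List& config, double drop_seed) {
  Cfg cfg = as_cfg(config);
  ParamMap P = as_params(params);
  Uniform01 rng((uint64_t)drop_seed);
  Uniform01* rp = drop_seed > 0 ? &rng : 0;
  FeatCache fc;
  mat F = extract_features(eeg, emg, P, cfg, rp, &fc);
  mat logits = P.at("head_Wp") * F;
  logits.each_col() += P.at("head_bp").col(0);
  mat probs = softmax_cols(logits);
  double loss = ce_loss(probs, y);
  mat dlogits = (probs - onehot(y, cfg.nc)) / (double)y.n_elem;
  ParamMap G = zeros_like(P);
  G["head_Wp"] += dlogits * F.t();
  G["head_bp"].col(0) += sum(dlogits, 1);
  mat dF = P.at("head_Wp").t() * dlogits;
  features_backward(dF, eeg, emg, P, G, cfg, fc);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(G));
}

// [[Rcpp::export]]
Rcpp::List cpp_grad_rescoring(const arma::mat& eeg, const arma::mat& emg,
                              const arma::uvec& y, const Rcpp::List& params,
                              const Rcpp::List& config, double drop_seed) {
  Cfg cfg = as_cfg(config);
  ParamMap P = as_params(params);
  Uniform01 rng((uint64_t)drop_seed);
  Uniform01* rp = drop_seed > 0 ? &rng : 0;
  FeatCache fc;
  mat F = extract_features(eeg, emg, P, cfg, rp, &fc);
  mat Qa = P.at("fc_W") * F;
  Qa.each_col() += P.at("fc_b").col(0);
  Qa.transform([](double v) { return v > 0 ? v : 0.0; });
  mat S = Qa, Ms;
  if (rp && cfg.dropout > 0) {
    Ms = rng.mask(S.n_rows, S.n_cols, cfg.dropout);
    S = S % Ms;
  }
  mat logits = P.at("out_W") * S;
  logits.each_col() += P.at("out_b").col(0);
  mat probs = softmax_cols(logits);
  double loss = ce_loss(probs, y);
  mat dlogits = (probs - onehot(y, cfg.nc)) / (double)y.n_elem;
  ParamMap G = zeros_like(P);
  G["out_W"] += dlogits * S.t();
  G["out_b"].col(0) += sum(dlogits, 1);
  mat dS = P.at("out_W").t() * dlogits;
  if (Ms.n_elem) dS = dS % Ms;
  mat dQa = dS % conv_to<mat>::from(Qa > 0);
  G["fc_W"] += dQa * F.t();
  G["fc_b"].col(0) += sum(dQa, 1);
  mat dF = P.at("fc_W").t() * dQa;
  features_backward(dF, eeg, emg, P, G, cfg, fc);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(G));
}

// Batch of independent equal-length sequences laid out as consecutive
// column blocks: columns [i*seq_len, (i+1)*seq_len) form sequence i.
// [[Rcpp::export]]
Rcpp::List cpp_grad_full(const arma::mat& eeg, const arma::mat& emg,
                         const arma::uvec& y, int seq_len,
                         const Rcpp::List& params, const Rcpp::List& config,
                         double drop_seed) {
  Cfg cfg = as_cfg(config);
  ParamMap P = as_params(params);
  const int n = eeg.n_cols;
  if (n % seq_len != 0)
    Rcpp::stop("batch columns must be a multiple of seq_len");
  const int nseq = n / seq_len;
  Uniform01 rng((uint64_t)drop_seed);
  Uniform01* rp = drop_seed > 0 ? &rng : 0;
  FeatCache fc;
  mat F = extract_features(eeg, emg, P, cfg, rp, &fc);
  ParamMap G = zeros_like(P);
  mat Yh = onehot(y, cfg.nc);
  mat dF(F.n_rows, n, fill::zeros);
  double loss = 0;
  for (int s = 0; s < nseq; ++s) {
    const int a = s * seq_len, b = (s + 1) * seq_len - 1;
    HeadCache hc;
    mat probs = full_head_forward(F.cols(a, b), P, cfg, rp, &hc);
    uvec ys = y.subvec(a, b);
    loss += ce_loss(probs, ys) * seq_len;
    mat dlogits = (probs - Yh.cols(a, b)) / (double)n;
    dF.cols(a, b) = full_head_backward(dlogits, P, G, hc);
  }
  loss /= n;
  features_backward(dF, eeg, emg, P, G, cfg, fc);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(G));
}

// Sliding-window inference: feat is (Fd x n); for each 1-based window start
// in `starts`, run the recurrent head over `context` consecutive epochs and
// return the class probabilities at the center position.
// [[Rcpp::export]]
arma::mat cpp_predict_full(const arma::mat& feat, const arma::uvec& starts,
                           int context, const Rcpp::List& params,
                           const Rcpp::List& config) {
  Cfg cfg = as_cfg(config);
  ParamMap P = as_params(params);
  const int center = context / 2;  // 0-based offset within the window
  mat out(cfg.nc, starts.n_elem);
  for (uword w = 0; w < starts.n_elem; ++w) {
    const uword a = starts(w) - 1;
    mat probs = full_head_forward(feat.cols(a, a + context - 1), P, cfg, 0, 0);
    out.col(w) = probs.col(center);
  }
  return out;
}

// Per-position probabilities of the full head over one feature sequence.
// [[Rcpp::export]]
arma::mat cpp_full_seq_probs(const arma::mat& feat, const Rcpp::List& params,
                             const Rcpp::List& config) {
  Cfg cfg = as_cfg(config);
  ParamMap P = as_params(params);
  return full_head_forward(feat, P, cfg, 0, 0);
}
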