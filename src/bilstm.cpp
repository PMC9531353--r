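// Bidirectional-LSTM promoter classifier: forward pass, backpropagation
// through time, and Adam optimisation. Single precision throughout; the
// parameter state crosses the R boundary as a named list of double
// matrices/vectors and is converted at the edges.
//
// Layer stack (per sequence of T triplet indices):
//   embedding (vocab -> D) -> batchnorm over the D features (statistics
//   pooled over batch x positions) -> bidirectional LSTM (D -> H per
//   direction) -> flatten (T*2H) -> FC1 + leaky ReLU -> FC2 + sigmoid.
//
// Flatten layout: row t*2H + j is forward hidden unit j at position t,
// row t*2H + H + j is backward hidden unit j at position t.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::fcube;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;
static const float BCE_EPS = 1e-7f;

struct Net {
  fmat E;                   // D x vocab, one column per token index
  fvec bn_g, bn_b, bn_rm, bn_rv;
  fmat Wxf, Whf; fvec bf;   // forward LSTM:  4H x D, 4H x H, 4H
  fmat Wxb, Whb; fvec bb;   // backward LSTM
  fmat W1; fvec b1;         // FC1: F1 x (T*2H)
  fmat W2; fvec b2;         // FC2: 1 x F1
  int vocab, D, H, T, F1;
};

static fmat as_fmat(SEXP x) { return arma::conv_to<fmat>::from(as<arma::mat>(x)); }
static fvec as_fvec(SEXP x) { return arma::conv_to<fvec>::from(as<arma::vec>(x)); }

static Net net_from_list(const List& p) {
  Net n;
  n.E = as_fmat(p["embedding"]);
  n.bn_g = as_fvec(p["bn_gamma"]);  n.bn_b = as_fvec(p["bn_beta"]);
  n.bn_rm = as_fvec(p["bn_run_mean"]); n.bn_rv = as_fvec(p["bn_run_var"]);
  n.Wxf = as_fmat(p["lstm_fwd_Wx"]); n.Whf = as_fmat(p["lstm_fwd_Wh"]); n.bf = as_fvec(p["lstm_fwd_b"]);
  n.Wxb = as_fmat(p["lstm_bwd_Wx"]); n.Whb = as_fmat(p["lstm_bwd_Wh"]); n.bb = as_fvec(p["lstm_bwd_b"]);
  n.W1 = as_fmat(p["fc1_W"]); n.b1 = as_fvec(p["fc1_b"]);
  n.W2 = as_fmat(p["fc2_W"]); n.b2 = as_fvec(p["fc2_b"]);
  n.D = n.E.n_rows; n.vocab = n.E.n_cols; n.H = n.Whf.n_cols;
  n.F1 = n.W1.n_rows;
  n.T = n.W1.n_cols / (2 * n.H);
  return n;
}

static List net_to_list(const Net& n) {
  return List::create(
    _["embedding"] = wrap(arma::conv_to<arma::mat>::from(n.E)),
    _["bn_gamma"] = wrap(arma::conv_to<arma::vec>::from(n.bn_g)),
    _["bn_beta"] = wrap(arma::conv_to<arma::vec>::from(n.bn_b)),
    _["bn_run_mean"] = wrap(arma::conv_to<arma::vec>::from(n.bn_rm)),
    _["bn_run_var"] = wrap(arma::conv_to<arma::vec>::from(n.bn_rv)),
    _["lstm_fwd_Wx"] = wrap(arma::conv_to<arma::mat>::from(n.Wxf)),
    _["lstm_fwd_Wh"] = wrap(arma::conv_to<arma::mat>::from(n.Whf)),
    _["lstm_fwd_b"] = wrap(arma::conv_to<arma::vec>::from(n.bf)),
    _["lstm_bwd_Wx"] = wrap(arma::conv_to<arma::mat>::from(n.Wxb)),
    _["lstm_bwd_Wh"] = wrap(arma::conv_to<arma::mat>::from(n.Whb)),
    _["lstm_bwd_b"] = wrap(arma::conv_to<arma::vec>::from(n.bb)),
    _["fc1_W"] = wrap(arma::conv_to<arma::mat>::from(n.W1)),
    _["fc1_b"] = wrap(arma::conv_to<arma::vec>::from(n.b1)),
    _["fc2_W"] = wrap(arma::conv_to<arma::mat>::from(n.W2)),
    _["fc2_b"] = wrap(arma::conv_to<arma::vec>::from(n.b2)));
}

static void fill_uniform(fmat& m, std::mt19937& rng, float a) {
  std::uniform_real_distribution<float> d(-a, a);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = d(rng);
}
static void fill_uniform(fvec& v, std::mt19937& rng, float a) {
  std::uniform_real_distribution<float> d(-a, a);
  for (arma::uword i = 0; i < v.n_elem; ++i) v(i) = d(rng);
}

// [[Rcpp::export]]
List cpp_bilstm_init(int vocab, int embed_dim, int hidden_dim, int seq_len,
                     int fc1_dim, int seed) {
  Net n;
  n.vocab = vocab; n.D = embed_dim; n.H = hidden_dim; n.T = seq_len; n.F1 = fc1_dim;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  n.E.set_size(embed_dim, vocab);
  for (arma::uword i = 0; i < n.E.n_elem; ++i) n.E(i) = gauss(rng);
  n.bn_g.ones(embed_dim); n.bn_b.zeros(embed_dim);
  n.bn_rm.zeros(embed_dim); n.bn_rv.ones(embed_dim);
  const int G = 4 * hidden_dim;
  const float klstm = 1.0f / std::sqrt((float)hidden_dim);
  n.Wxf.set_size(G, embed_dim);  fill_uniform(n.Wxf, rng, klstm);
  n.Whf.set_size(G, hidden_dim); fill_uniform(n.Whf, rng, klstm);
  n.bf.set_size(G);              fill_uniform(n.bf, rng, klstm);
  n.Wxb.set_size(G, embed_dim);  fill_uniform(n.Wxb, rng, klstm);
  n.Whb.set_size(G, hidden_dim); fill_uniform(n.Whb, rng, klstm);
  n.bb.set_size(G);              fill_uniform(n.bb, rng, klstm);
  const int flat = seq_len * 2 * hidden_dim;
  const float k1 = 1.0f / std::sqrt((float)flat);
  n.W1.set_size(fc1_dim, flat);  fill_uniform(n.W1, rng, k1);
  n.b1.set_size(fc1_dim);        fill_uniform(n.b1, rng, k1);
  const float k2 = 1.0f / std::sqrt((float)fc1_dim);
  n.W2.set_size(1, fc1_dim);     fill_uniform(n.W2, rng, k2);
  n.b2.set_size(1);              fill_uniform(n.b2, rng, k2);
  return net_to_list(n);
}

// Gather embedding columns for a batch: cube D x B x T.
static fcube embed_batch(const Net& n, const IntegerMatrix& X,
                         const std::vector<int>& rows) {
  const int B = rows.size(), T = X.ncol();
  fcube out(n.D, B, T);
  for (int t = 0; t < T; ++t) {
    fmat& sl = out.slice(t);
    for (int b = 0; b < B; ++b) {
      int tok = X(rows[b], t);
      sl.col(b) = n.E.col(tok);
    }
  }
  return out;
}

static inline fmat fsigmoid(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }

// LSTM over one direction. dir = +1 forward (t = 0..T-1), -1 backward.
// Stores activated gates (i,f,g,o stacked, 4H x B x T, indexed by real
// position t), cell states and hidden states for backprop.
struct LstmTrace { fcube gates, cs, hs; };

static void lstm_forward(const fmat& Wx, const fmat& Wh, const fvec& b,
                         const fcube& Xn, int dir, LstmTrace& tr) {
  const int D = Xn.n_rows, B = Xn.n_cols, T = Xn.n_slices;
  (void)D;
  const int H = Wh.n_cols;
  tr.gates.set_size(4 * H, B, T);
  tr.cs.set_size(H, B, T);
  tr.hs.set_size(H, B, T);
  fmat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int step = 0; step < T; ++step) {
    const int t = (dir > 0) ? step : (T - 1 - step);
    fmat a = Wx * Xn.slice(t) + Wh * h;
    a.each_col() += b;
    fmat i = fsigmoid(a.rows(0, H - 1));
    fmat f = fsigmoid(a.rows(H, 2 * H - 1));
    fmat g = arma::tanh(a.rows(2 * H, 3 * H - 1));
    fmat o = fsigmoid(a.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    tr.gates.slice(t).rows(0, H - 1) = i;
    tr.gates.slice(t).rows(H, 2 * H - 1) = f;
    tr.gates.slice(t).rows(2 * H, 3 * H - 1) = g;
    tr.gates.slice(t).rows(3 * H, 4 * H - 1) = o;
    tr.cs.slice(t) = c;
    tr.hs.slice(t) = h;
  }
}

struct LstmGrads { fmat dWx, dWh; fvec db; };

// BPTT for one direction. dH: gradient wrt hidden states (H x B x T).
// Accumulates dX (gradient wrt the LSTM input cube) and weight gradients.
static void lstm_backward(const fmat& Wx, const fmat& Wh,
                          const fcube& Xn, const LstmTrace& tr, int dir,
                          const fcube& dH, fcube& dX, LstmGrads& gr) {
  const int B = Xn.n_cols, T = Xn.n_slices;
  const int H = Wh.n_cols;
  gr.dWx.zeros(4 * H, Xn.n_rows);
  gr.dWh.zeros(4 * H, H);
  gr.db.zeros(4 * H);
  fmat dh_next(H, B, arma::fill::zeros), dc_next(H, B, arma::fill::zeros);
  for (int step = T - 1; step >= 0; --step) {
    const int t = (dir > 0) ? step : (T - 1 - step);
    const int t_prev = (dir > 0) ? t - 1 : t + 1;   // earlier in iteration order
    const bool has_prev = (dir > 0) ? (t_prev >= 0) : (t_prev <= T - 1);
    const fmat i = tr.gates.slice(t).rows(0, H - 1);
    const fmat f = tr.gates.slice(t).rows(H, 2 * H - 1);
    const fmat g = tr.gates.slice(t).rows(2 * H, 3 * H - 1);
    const fmat o = tr.gates.slice(t).rows(3 * H, 4 * H - 1);
    const fmat tc = arma::tanh(tr.cs.slice(t));
    fmat dh = dH.slice(t) + dh_next;
    fmat d_o = dh % tc;
    fmat dc = dc_next + dh % o % (1.0f - tc % tc);
    fmat c_prev = has_prev ? tr.cs.slice(t_prev)
                           : fmat(H, B, arma::fill::zeros);
    fmat h_prev = has_prev ? tr.hs.slice(t_prev)
                           : fmat(H, B, arma::fill::zeros);
    fmat di = dc % g;
    fmat df = dc % c_prev;
    fmat dg = dc % i;
    fmat da(4 * H, B);
    da.rows(0, H - 1)         = di % i % (1.0f - i);
    da.rows(H, 2 * H - 1)     = df % f % (1.0f - f);
    da.rows(2 * H, 3 * H - 1) = dg % (1.0f - g % g);
    da.rows(3 * H, 4 * H - 1) = d_o % o % (1.0f - o);
    gr.dWx += da * Xn.slice(t).t();
    gr.dWh += da * h_prev.t();
    gr.db += arma::sum(da, 1);
    dX.slice(t) += Wx.t() * da;
    dh_next = Wh.t() * da;
    dc_next = dc % f;
  }
}

// Inference-mode forward for a set of rows: running batchnorm statistics,
// no traces kept. Returns probabilities.
static fvec forward_infer(const Net& n, const IntegerMatrix& X,
                          const std::vector<int>& rows, float slope) {
  const int B = rows.size(), T = X.ncol(), H = n.H;
  fcube Xn = embed_batch(n, X, rows);
  fvec istd = 1.0f / arma::sqrt(n.bn_rv + BN_EPS);
  for (int t = 0; t < T; ++t) {
    fmat& sl = Xn.slice(t);
    sl.each_col() -= n.bn_rm;
    sl.each_col() %= istd;
    sl.each_col() %= n.bn_g;
    sl.each_col() += n.bn_b;
  }
  LstmTrace trF, trB;
  lstm_forward(n.Wxf, n.Whf, n.bf, Xn, +1, trF);
  lstm_forward(n.Wxb, n.Whb, n.bb, Xn, -1, trB);
  fmat F(T * 2 * H, B);
  for (int t = 0; t < T; ++t) {
    F.rows(t * 2 * H, t * 2 * H + H - 1) = trF.hs.slice(t);
    F.rows(t * 2 * H + H, (t + 1) * 2 * H - 1) = trB.hs.slice(t);
  }
  fmat Z1 = n.W1 * F;
  Z1.each_col() += n.b1;
  fmat A1 = arma::max(Z1, slope * Z1);
  fmat z2 = n.W2 * A1;
  z2 += n.b2(0);
  return arma::vectorise(fsigmoid(z2));
}

static double bce(const fvec& p, const fvec& y) {
  fvec pc = arma::clamp(p, BCE_EPS, 1.0f - BCE_EPS);
  return -arma::mean(arma::conv_to<arma::vec>::from(
      y % arma::log(pc) + (1.0f - y) % arma::log(1.0f - pc)));
}

// [[Rcpp::export]]
NumericVector cpp_bilstm_forward(List params, IntegerMatrix X,
                                 double leaky_slope) {
  Net n = net_from_list(params);
  const int nr = X.nrow();
  NumericVector out(nr);
  const int chunk = 128;
  for (int start = 0; start < nr; start += chunk) {
    int end = std::min(start + chunk, nr);
    std::vector<int> rows;
    for (int i = start; i < end; ++i) rows.push_back(i);
    fvec p = forward_infer(n, X, rows, (float)leaky_slope);
    for (int i = start; i < end; ++i) out[i] = p(i - start);
  }
  return out;
}

struct Adam {
  std::vector<fmat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<const fmat*>& ps) {
    for (auto p : ps) {
      m.push_back(fmat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(fmat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<fmat*>& ps, const std::vector<const fmat*>& gs, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t), c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t k = 0; k < ps.size(); ++k) {
      m[k] = (float)b1 * m[k] + (float)(1.0 - b1) * (*gs[k]);
      v[k] = (float)b2 * v[k] + (float)(1.0 - b2) * arma::square(*gs[k]);
      *ps[k] -= (float)(lr) * (m[k] / (float)c1) /
                (arma::sqrt(v[k] / (float)c2) + (float)eps);
    }
  }
};

// [[Rcpp::export]]
List cpp_bilstm_train(List params, IntegerMatrix Xtr, NumericVector ytr,
                      IntegerMatrix Xval, NumericVector yval,
                      double leaky_slope, int max_epochs, int batch_size,
                      double lr, int shuffle_seed, bool shuffle_each_epoch) {
  Net n = net_from_list(params);
  const int ntr = Xtr.nrow(), T = Xtr.ncol(), H = n.H, D = n.D;
  const float slope = (float)leaky_slope;
  if (T != n.T) stop("input width %d does not match model seq_len %d", T, n.T);

  fvec ytr_f(ntr);
  for (int i = 0; i < ntr; ++i) ytr_f(i) = (float)ytr[i];
  const int nval = Xval.nrow();
  fvec yval_f(nval);
  for (int i = 0; i < nval; ++i) yval_f(i) = (float)yval[i];

  // bias vectors are carried as 1-column matrices so Adam sees one list
  fmat bf_m(n.bf), bb_m(n.bb), b1_m(n.b1), b2_m(n.b2);
  fmat bng_m(n.bn_g), bnb_m(n.bn_b);
  std::vector<fmat*> pars = { &n.E, &bng_m, &bnb_m,
                              &n.Wxf, &n.Whf, &bf_m, &n.Wxb, &n.Whb, &bb_m,
                              &n.W1, &b1_m, &n.W2, &b2_m };
  Adam adam;
  {
    std::vector<const fmat*> cps(pars.begin(), pars.end());
    adam.init(cps);
  }

  std::mt19937 rng(static_cast<unsigned int>(shuffle_seed));
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  std::vector<double> hist_train, hist_val;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0;
  List best_params = params;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    if (shuffle_each_epoch) {
      for (int i = ntr - 1; i > 0; --i) {
        std::uniform_int_distribution<int> d(0, i);
        std::swap(order[i], order[d(rng)]);
      }
    }
    double ep_loss = 0.0;
    for (int start = 0; start < ntr; start += batch_size) {
      const int end = std::min(start + batch_size, ntr);
      const int B = end - start;
      std::vector<int> rows(order.begin() + start, order.begin() + end);

      // ---- forward (training mode) ----
      fcube Xe = embed_batch(n, Xtr, rows);       // raw embeddings
      const float N = (float)(B * T);
      fvec mu(D, arma::fill::zeros), var(D, arma::fill::zeros);
      for (int t = 0; t < T; ++t) mu += arma::sum(Xe.slice(t), 1);
      mu /= N;
      for (int t = 0; t < T; ++t) {
        fmat c = Xe.slice(t);
        c.each_col() -= mu;
        var += arma::sum(arma::square(c), 1);
      }
      var /= N;
      fvec istd = 1.0f / arma::sqrt(var + BN_EPS);
      n.bn_rm = (1.0f - BN_MOMENTUM) * n.bn_rm + BN_MOMENTUM * mu;
      n.bn_rv = (1.0f - BN_MOMENTUM) * n.bn_rv + BN_MOMENTUM * var;
      fcube Xhat(D, B, T), Xn(D, B, T);
      for (int t = 0; t < T; ++t) {
        fmat xh = Xe.slice(t);
        xh.each_col() -= mu;
        xh.each_col() %= istd;
        Xhat.slice(t) = xh;
        xh.each_col() %= bng_m.col(0);
        xh.each_col() += bnb_m.col(0);
        Xn.slice(t) = xh;
      }
      LstmTrace trF, trB;
      lstm_forward(n.Wxf, n.Whf, bf_m.col(0), Xn, +1, trF);
      lstm_forward(n.Wxb, n.Whb, bb_m.col(0), Xn, -1, trB);
      fmat F(T * 2 * H, B);
      for (int t = 0; t < T; ++t) {
        F.rows(t * 2 * H, t * 2 * H + H - 1) = trF.hs.slice(t);
        F.rows(t * 2 * H + H, (t + 1) * 2 * H - 1) = trB.hs.slice(t);
      }
      fmat Z1 = n.W1 * F;
      Z1.each_col() += b1_m.col(0);
      fmat A1 = arma::max(Z1, slope * Z1);
      fmat z2 = n.W2 * A1;
      z2 += b2_m(0, 0);
      fvec p = arma::vectorise(fsigmoid(z2));
      fvec yb(B);
      for (int b = 0; b < B; ++b) yb(b) = ytr_f(rows[b]);
      ep_loss += bce(p, yb) * B;

      // ---- backward ----
      fmat dz2 = ((p - yb) / (float)B).t();            // 1 x B
      fmat dW2 = dz2 * A1.t();
      fmat db2(1, 1); db2(0, 0) = arma::accu(dz2);
      fmat dA1 = n.W2.t() * dz2;
      fmat dZ1 = dA1 % ((arma::conv_to<fmat>::from(Z1 > 0.0f)) * (1.0f - slope) + slope);
      fmat dW1 = dZ1 * F.t();
      fmat db1 = arma::sum(dZ1, 1);
      fmat dF = n.W1.t() * dZ1;

      fcube dHf(H, B, T), dHb(H, B, T);
      for (int t = 0; t < T; ++t) {
        dHf.slice(t) = dF.rows(t * 2 * H, t * 2 * H + H - 1);
        dHb.slice(t) = dF.rows(t * 2 * H + H, (t + 1) * 2 * H - 1);
      }
      fcube dXn(D, B, T, arma::fill::zeros);
      LstmGrads grF, grB;
      lstm_backward(n.Wxf, n.Whf, Xn, trF, +1, dHf, dXn, grF);
      lstm_backward(n.Wxb, n.Whb, Xn, trB, -1, dHb, dXn, grB);

      // batchnorm backward (pooled over B*T samples per feature)
      fvec dgamma(D, arma::fill::zeros), dbeta(D, arma::fill::zeros);
      fvec s1(D, arma::fill::zeros), s2(D, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        const fmat& dy = dXn.slice(t);
        dgamma += arma::sum(dy % Xhat.slice(t), 1);
        dbeta += arma::sum(dy, 1);
      }
      // dxhat = dy * gamma; accumulate its pooled sums
      for (int t = 0; t < T; ++t) {
        fmat dxh = dXn.slice(t);
        dxh.each_col() %= bng_m.col(0);
        s1 += arma::sum(dxh, 1);
        s2 += arma::sum(dxh % Xhat.slice(t), 1);
      }
      fmat dE(D, n.vocab, arma::fill::zeros);
      fvec coef = istd / N;
      for (int t = 0; t < T; ++t) {
        fmat dxh = dXn.slice(t);
        dxh.each_col() %= bng_m.col(0);
        fmat dx = dxh * N;
        dx.each_col() -= s1;
        fmat xs = Xhat.slice(t);
        xs.each_col() %= s2;
        dx -= xs;
        dx.each_col() %= coef;
        for (int b = 0; b < B; ++b) {
          dE.col(Xtr(rows[b], t)) += dx.col(b);
        }
      }

      fmat dbng(dgamma), dbnb(dbeta);
      fmat grFb(grF.db), grBb(grB.db);
      std::vector<const fmat*> grads = { &dE, &dbng, &dbnb,
                                         &grF.dWx, &grF.dWh, &grFb,
                                         &grB.dWx, &grB.dWh, &grBb,
                                         &dW1, &db1, &dW2, &db2 };
      adam.step(pars, grads, lr);
    }
    hist_train.push_back(ep_loss / ntr);

    // sync bias columns back into the Net view used by forward_infer
    n.bf = bf_m.col(0); n.bb = bb_m.col(0);
    n.b1 = b1_m.col(0); n.b2 = b2_m.col(0);
    n.bn_g = bng_m.col(0); n.bn_b = bnb_m.col(0);

    double vl;
    {
      NumericVector pv(nval);
      const int chunk = 128;
      fvec pall(nval);
      for (int start = 0; start < nval; start += chunk) {
        int end = std::min(start + chunk, nval);
        std::vector<int> rows;
        for (int i = start; i < end; ++i) rows.push_back(i);
        fvec pc = forward_infer(n, Xval, rows, slope);
        for (int i = start; i < end; ++i) pall(i) = pc(i - start);
      }
      vl = bce(pall, yval_f);
    }
    hist_val.push_back(vl);
    if (vl < best_val) {
      best_val = vl;
      best_epoch = epoch;
      best_params = net_to_list(n);
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["params"] = best_params,
    _["best_epoch"] = best_epoch,
    _["train_loss"] = wrap(hist_train),
    _["val_loss"] = wrap(hist_val));
}
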