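// Character-level BiLSTM-CRF training engine.
//
// Layout shared with the R side:
//   * character ids are 1-based; id V+1 is the UNK row of the embedding;
//   * tag ids are 1-based in 1..K; virtual CRF states START = K+1,
//     STOP = K+2 (0-based K and K+1 here);
//   * `allowed` is a (K+2) x (K+2) 0/1 mask; forbidden transitions score
//     MASKED (-1e4) and receive no gradient;
//   * parameters: E (V+1 x D), Wf/Wb (4H x (D+H)), bf/bb (4H),
//     Wp (K x 2H), bp (K), T ((K+2) x (K+2)).
// Gate order inside the 4H block: input, forget, cell, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static const double MASKED = -1e4;

static inline double lse(const vec &v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(v - m)));
}

static inline vec sigmoid(const vec &z) { return 1.0 / (1.0 + arma::exp(-z)); }

struct LstmCache {
  mat I, F, G, O, C, Tc, H; // each L x Hdim; Tc = tanh(C)
};

// xs: L x D embedded inputs (already in time order for this direction)
static LstmCache lstm_forward(const mat &X, const mat &W, const vec &b) {
  int L = X.n_rows, D = X.n_cols, H = W.n_rows / 4;
  LstmCache c;
  c.I.set_size(L, H); c.F.set_size(L, H); c.G.set_size(L, H);
  c.O.set_size(L, H); c.C.set_size(L, H); c.Tc.set_size(L, H);
  c.H.set_size(L, H);
  vec h(H, arma::fill::zeros), cc(H, arma::fill::zeros);
  vec xh(D + H);
  for (int t = 0; t < L; ++t) {
    xh.subvec(0, D - 1) = X.row(t).t();
    xh.subvec(D, D + H - 1) = h;
    vec z = W * xh + b;
    vec i = sigmoid(z.subvec(0, H - 1));
    vec f = sigmoid(z.subvec(H, 2 * H - 1));
    vec g = arma::tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = sigmoid(z.subvec(3 * H, 4 * H - 1));
    cc = f % cc + i % g;
    vec tc = arma::tanh(cc);
    h = o % tc;
    c.I.row(t) = i.t(); c.F.row(t) = f.t(); c.G.row(t) = g.t();
    c.O.row(t) = o.t(); c.C.row(t) = cc.t(); c.Tc.row(t) = tc.t();
    c.H.row(t) = h.t();
  }
  return c;
}

// dH: L x H gradient wrt hidden states; returns dX and accumulates dW, db.
static mat lstm_backward(const mat &X, const mat &W, const LstmCache &c,
                         const mat &dH, mat &dW, vec &db) {
  int L = X.n_rows, D = X.n_cols, H = W.n_rows / 4;
  mat dX(L, D, arma::fill::zeros);
  vec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  vec xh(D + H), dz(4 * H);
  for (int t = L - 1; t >= 0; --t) {
    vec dh = dH.row(t).t() + dh_next;
    vec i = c.I.row(t).t(), f = c.F.row(t).t(), g = c.G.row(t).t(),
        o = c.O.row(t).t(), tc = c.Tc.row(t).t();
    vec c_prev = (t > 0) ? vec(c.C.row(t - 1).t()) : vec(H, arma::fill::zeros);
    vec dc = dc_next + dh % o % (1.0 - tc % tc);
    vec do_ = dh % tc;
    vec di = dc % g;
    vec df = dc % c_prev;
    vec dg = dc % i;
    dz.subvec(0, H - 1) = di % i % (1.0 - i);
    dz.subvec(H, 2 * H - 1) = df % f % (1.0 - f);
    dz.subvec(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dz.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    xh.subvec(0, D - 1) = X.row(t).t();
    xh.subvec(D, D + H - 1) = (t > 0) ? vec(c.H.row(t - 1).t())
                                      : vec(H, arma::fill::zeros);
    dW += dz * xh.t();
    db += dz;
    vec dxh = W.t() * dz;
    dX.row(t) = dxh.subvec(0, D - 1).t();
    dh_next = dxh.subvec(D, D + H - 1);
    dc_next = dc % f;
  }
  return dX;
}

static mat effective_trans(const mat &T, const arma::imat &allowed) {
  mat Te = T;
  for (arma::uword i = 0; i < Te.n_rows; ++i)
    for (arma::uword j = 0; j < Te.n_cols; ++j)
      if (!allowed(i, j)) Te(i, j) = MASKED;
  return Te;
}

// CRF negative log-likelihood and gradients wrt emissions and transitions.
// E: L x K emissions, Te: effective (K+2)x(K+2) transitions, y: 0-based tags.
static double crf_grad(const mat &E, const mat &Te, const uvec &y,
                       mat &dE, mat &dT) {
  int L = E.n_rows, K = E.n_cols;
  int START = K, STOP = K + 1;
  mat alpha(L, K), beta(L, K);
  alpha.row(0) = Te.row(START).subvec(0, K - 1) + E.row(0);
  for (int t = 1; t < L; ++t)
    for (int k = 0; k < K; ++k)
      alpha(t, k) = lse(alpha.row(t - 1).t() + Te.col(k).subvec(0, K - 1)) + E(t, k);
  double logZ = lse(alpha.row(L - 1).t() + Te.col(STOP).subvec(0, K - 1));
  beta.row(L - 1) = Te.col(STOP).subvec(0, K - 1).t();
  for (int t = L - 2; t >= 0; --t)
    for (int j = 0; j < K; ++j)
      beta(t, j) = lse(Te.row(j).subvec(0, K - 1).t() +
                       E.row(t + 1).t() + beta.row(t + 1).t());
  // unary marginals -> emission gradient
  dE = arma::exp(alpha + beta - logZ);
  for (int t = 0; t < L; ++t) dE(t, y(t)) -= 1.0;
  // pairwise marginals -> transition gradient
  dT.zeros(K + 2, K + 2);
  mat Tin = Te.submat(0, 0, K - 1, K - 1);
  for (int t = 0; t + 1 < L; ++t) {
    vec a = alpha.row(t).t();
    vec b = E.row(t + 1).t() + beta.row(t + 1).t();
    mat P = arma::exp(arma::repmat(a, 1, K) + Tin +
                      arma::repmat(b.t(), K, 1) - logZ);
    dT.submat(0, 0, K - 1, K - 1) += P;
    dT(y(t), y(t + 1)) -= 1.0;
  }
  for (int k = 0; k < K; ++k) {
    dT(START, k) += std::exp(alpha(0, k) + beta(0, k) - logZ);
    dT(k, STOP) += std::exp(alpha(L - 1, k) + beta(L - 1, k) - logZ);
  }
  dT(START, y(0)) -= 1.0;
  dT(y(L - 1), STOP) -= 1.0;
  // gold path score
  double score = Te(START, y(0)) + Te(y(L - 1), STOP);
  for (int t = 0; t < L; ++t) score += E(t, y(t));
  for (int t = 0; t + 1 < L; ++t) score += Te(y(t), y(t + 1));
  return logZ - score;
}

struct Params {
  mat E, Wf, Wb, Wp, T;
  vec bf, bb, bp;
};

static Params params_from_list(const List &p) {
  Params q;
  q.E = as<mat>(p["E"]); q.Wf = as<mat>(p["Wf"]); q.Wb = as<mat>(p["Wb"]);
  q.Wp = as<mat>(p["Wp"]); q.T = as<mat>(p["T"]);
  q.bf = as<vec>(p["bf"]); q.bb = as<vec>(p["bb"]); q.bp = as<vec>(p["bp"]);
  return q;
}

static List params_to_list(const Params &q) {
  return List::create(_["E"] = q.E, _["Wf"] = q.Wf, _["bf"] = q.bf,
                      _["Wb"] = q.Wb, _["bb"] = q.bb, _["Wp"] = q.Wp,
                      _["bp"] = q.bp, _["T"] = q.T);
}

// Embed a sequence (1-based char ids) -> L x D
static mat embed_seq(const mat &E, const IntegerVector &x) {
  int L = x.size(), D = E.n_cols;
  mat X(L, D);
  for (int t = 0; t < L; ++t) X.row(t) = E.row(x[t] - 1);
  return X;
}

// Forward pass to emissions; optionally keep caches for backprop.
static mat emissions_of(const Params &q, const IntegerVector &x,
                        LstmCache *cf = nullptr, LstmCache *cb = nullptr,
                        mat *Xout = nullptr) {
  mat X = embed_seq(q.E, x);
  int L = X.n_rows, H = q.Wf.n_rows / 4, K = q.Wp.n_rows;
  LstmCache f = lstm_forward(X, q.Wf, q.bf);
  mat Xr = arma::flipud(X);
  LstmCache b = lstm_forward(Xr, q.Wb, q.bb);
  mat Hb = arma::flipud(b.H);
  mat Em(L, K);
  for (int t = 0; t < L; ++t) {
    vec h2(2 * H);
    h2.subvec(0, H - 1) = f.H.row(t).t();
    h2.subvec(H, 2 * H - 1) = Hb.row(t).t();
    Em.row(t) = (q.Wp * h2 + q.bp).t();
  }
  if (cf) *cf = f;
  if (cb) *cb = b;
  if (Xout) *Xout = X;
  return Em;
}

// [[Rcpp::export]]
NumericMatrix bc_emissions(List params, IntegerVector x) {
  Params q = params_from_list(params);
  return wrap(emissions_of(q, x));
}

// [[Rcpp::export]]
List bc_init_params(int vocab_size, int K, int embed_dim, int hidden_dim) {
  int D = embed_dim, H = hidden_dim;
  auto runifm = [](int r, int c, double a) {
    mat m(r, c);
    for (int j = 0; j < c; ++j)
      for (int i = 0; i < r; ++i) m(i, j) = R::runif(-a, a);
    return m;
  };
  Params q;
  q.E = runifm(vocab_size + 1, D, 0.1);
  q.Wf = runifm(4 * H, D + H, 1.0 / std::sqrt((double)(D + H)));
  q.Wb = runifm(4 * H, D + H, 1.0 / std::sqrt((double)(D + H)));
  q.Wp = runifm(K, 2 * H, 1.0 / std::sqrt(2.0 * H));
  q.T = mat(K + 2, K + 2, arma::fill::zeros);
  q.bf = vec(4 * H, arma::fill::zeros);
  q.bb = vec(4 * H, arma::fill::zeros);
  q.bp = vec(K, arma::fill::zeros);
  q.bf.subvec(H, 2 * H - 1).fill(1.0); // forget-gate bias
  q.bb.subvec(H, 2 * H - 1).fill(1.0);
  return params_to_list(q);
}

struct Adam {
  Params m, v;
  long step = 0;
};

static Params zeros_like(const Params &q) {
  Params z;
  z.E = arma::zeros<mat>(q.E.n_rows, q.E.n_cols);
  z.Wf = arma::zeros<mat>(q.Wf.n_rows, q.Wf.n_cols);
  z.Wb = arma::zeros<mat>(q.Wb.n_rows, q.Wb.n_cols);
  z.Wp = arma::zeros<mat>(q.Wp.n_rows, q.Wp.n_cols);
  z.T = arma::zeros<mat>(q.T.n_rows, q.T.n_cols);
  z.bf = arma::zeros<vec>(q.bf.n_elem);
  z.bb = arma::zeros<vec>(q.bb.n_elem);
  z.bp = arma::zeros<vec>(q.bp.n_elem);
  return z;
}

static void adamw_update(mat &theta, mat &m, mat &v, const mat &g,
                         double lr, double wd, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  mat mh = m / (1 - std::pow(b1, (double)t));
  mat vh = v / (1 - std::pow(b2, (double)t));
  theta -= lr * (mh / (arma::sqrt(vh) + eps) + wd * theta);
}

static void adamw_update(vec &theta, vec &m, vec &v, const vec &g,
                         double lr, double wd, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  vec mh = m / (1 - std::pow(b1, (double)t));
  vec vh = v / (1 - std::pow(b2, (double)t));
  theta -= lr * (mh / (arma::sqrt(vh) + eps) + wd * theta);
}

// One training epoch; returns updated params, optimizer state, mean NLL.
// xs/ys: lists of 1-based integer vectors; order: 1-based shuffled indices.
// [[Rcpp::export]]
List bc_epoch(List params, Nullable<List> opt_state, List xs, List ys,
              IntegerMatrix allowed, IntegerVector order,
              double lr, double weight_decay, int batch_size) {
  Params q = params_from_list(params);
  arma::imat amask(allowed.nrow(), allowed.ncol());
  for (int i = 0; i < allowed.nrow(); ++i)
    for (int j = 0; j < allowed.ncol(); ++j) amask(i, j) = allowed(i, j);

  Adam ad;
  ad.m = zeros_like(q);
  ad.v = zeros_like(q);
  if (opt_state.isNotNull()) {
    List os(opt_state);
    ad.m = params_from_list(os["m"]);
    ad.v = params_from_list(os["v"]);
    ad.step = as<long>(os["step"]);
  }

  int n = order.size();
  double total_nll = 0.0;
  int done = 0;
  while (done < n) {
    int bs = std::min(batch_size, n - done);
    Params g = zeros_like(q);
    mat Te = effective_trans(q.T, amask);
    for (int bi = 0; bi < bs; ++bi) {
      int idx = order[done + bi] - 1;
      IntegerVector x = xs[idx];
      IntegerVector yv = ys[idx];
      int L = x.size();
      uvec y(L);
      for (int t = 0; t < L; ++t) y(t) = yv[t] - 1;
      LstmCache cf, cb;
      mat X;
      mat Em = emissions_of(q, x, &cf, &cb, &X);
      mat dE_em, dT;
      total_nll += crf_grad(Em, Te, y, dE_em, dT);
      // transition gradient: only trainable (allowed) entries
      for (arma::uword i = 0; i < dT.n_rows; ++i)
        for (arma::uword j = 0; j < dT.n_cols; ++j)
          if (amask(i, j)) g.T(i, j) += dT(i, j);
      // projection backprop
      int H = q.Wf.n_rows / 4, K = q.Wp.n_rows;
      mat Hb = arma::flipud(cb.H);
      mat dHf(L, H, arma::fill::zeros), dHb(L, H, arma::fill::zeros);
      for (int t = 0; t < L; ++t) {
        vec de = dE_em.row(t).t();
        vec h2(2 * H);
        h2.subvec(0, H - 1) = cf.H.row(t).t();
        h2.subvec(H, 2 * H - 1) = Hb.row(t).t();
        g.Wp += de * h2.t();
        g.bp += de;
        vec dh2 = q.Wp.t() * de;
        dHf.row(t) = dh2.subvec(0, H - 1).t();
        dHb.row(t) = dh2.subvec(H, 2 * H - 1).t();
      }
      mat dXf = lstm_backward(X, q.Wf, cf, dHf, g.Wf, g.bf);
      mat Xr = arma::flipud(X);
      mat dXb_r = lstm_backward(Xr, q.Wb, cb, arma::flipud(dHb), g.Wb, g.bb);
      mat dX = dXf + arma::flipud(dXb_r);
      for (int t = 0; t < L; ++t) g.E.row(x[t] - 1) += dX.row(t);
    }
    double inv = 1.0 / bs;
    ad.step += 1;
    adamw_update(q.E, ad.m.E, ad.v.E, g.E * inv, lr, weight_decay, ad.step);
    adamw_update(q.Wf, ad.m.Wf, ad.v.Wf, g.Wf * inv, lr, weight_decay, ad.step);
    adamw_update(q.Wb, ad.m.Wb, ad.v.Wb, g.Wb * inv, lr, weight_decay, ad.step);
    adamw_update(q.Wp, ad.m.Wp, ad.v.Wp, g.Wp * inv, lr, weight_decay, ad.step);
    adamw_update(q.T, ad.m.T, ad.v.T, g.T * inv, lr, 0.0, ad.step);
    adamw_update(q.bf, ad.m.bf, ad.v.bf, g.bf * inv, lr, 0.0, ad.step);
    adamw_update(q.bb, ad.m.bb, ad.v.bb, g.bb * inv, lr, 0.0, ad.step);
    adamw_update(q.bp, ad.m.bp, ad.v.bp, g.bp * inv, lr, 0.0, ad.step);
    done += bs;
  }
  List opt_out = List::create(_["m"] = params_to_list(ad.m),
                              _["v"] = params_to_list(ad.v),
                              _["step"] = (double)ad.step);
  return List::create(_["params"] = params_to_list(q),
                      _["opt"] = opt_out,
                      _["mean_nll"] = total_nll / n);
}

// Viterbi with lowest-index tie-break; returns 1-based tag path.
static arma::ivec viterbi(const mat &Em, const mat &Te) {
  int L = Em.n_rows, K = Em.n_cols;
  int START = K, STOP = K + 1;
  mat delta(L, K);
  arma::imat back(L, K, arma::fill::zeros);
  for (int k = 0; k < K; ++k) delta(0, k) = Te(START, k) + Em(0, k);
  for (int t = 1; t < L; ++t)
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(t - 1, 0) + Te(0, k);
      for (int j = 1; j < K; ++j) {
        double c = delta(t - 1, j) + Te(j, k);
        if (c > best) { best = c; arg = j; }
      }
      back(t, k) = arg;
      delta(t, k) = best + Em(t, k);
    }
  int arg = 0;
  double best = delta(L - 1, 0) + Te(0, STOP);
  for (int k = 1; k < K; ++k) {
    double c = delta(L - 1, k) + Te(k, STOP);
    if (c > best) { best = c; arg = k; }
  }
  arma::ivec path(L);
  path(L - 1) = arg;
  for (int t = L - 1; t >= 1; --t) path(t - 1) = back(t, path(t));
  return path + 1;
}

// [[Rcpp::export]]
IntegerVector bc_decode(List params, IntegerVector x, IntegerMatrix allowed) {
  Params q = params_from_list(params);
  arma::imat amask(allowed.nrow(), allowed.ncol());
  for (int i = 0; i < allowed.nrow(); ++i)
    for (int j = 0; j < allowed.ncol(); ++j) amask(i, j) = allowed(i, j);
  mat Em = emissions_of(q, x);
  mat Te = effective_trans(q.T, amask);
  return wrap(arma::conv_to<std::vector<int>>::from(viterbi(Em, Te)));
}

// CRF NLL + gradients for externally supplied emissions (adapter training
// path and finite-difference tests). y is 1-based.
// [[Rcpp::export]]
List crf_grad_cpp(NumericMatrix emissions, NumericMatrix transitions,
                  IntegerMatrix allowed, IntegerVector y) {
  mat E = as<mat>(emissions), T = as<mat>(transitions);
  arma::imat amask(allowed.nrow(), allowed.ncol());
  for (int i = 0; i < allowed.nrow(); ++i)
    for (int j = 0; j < allowed.ncol(); ++j) amask(i, j) = allowed(i, j);
  mat Te = effective_trans(T, amask);
  uvec yy(y.size());
  for (int t = 0; t < y.size(); ++t) yy(t) = y[t] - 1;
  mat dE, dT;
  double nll = crf_grad(E, Te, yy, dE, dT);
  for (arma::uword i = 0; i < dT.n_rows; ++i)
    for (arma::uword j = 0; j < dT.n_cols; ++j)
      if (!amask(i, j)) dT(i, j) = 0.0;
  return List::create(_["nll"] = nll, _["d_emissions"] = dE,
                      _["d_transitions"] = dT);
}
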