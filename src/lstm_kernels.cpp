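// Compiled kernels for the LSTM sequence loops: the per-time-step gate
// recursions (forward) and backpropagation through time (backward) are the
// package's hot path, so they run in C++; everything else stays in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// read slice t of an R array laid out N x T x K into an N x K matrix
static inline arma::mat get_t(const double* p, int N, int T, int K, int t) {
  arma::mat out(N, K);
  for (int k = 0; k < K; ++k)
    for (int n = 0; n < N; ++n)
      out(n, k) = p[n + (size_t)N * (t + (size_t)T * k)];
  return out;
}

static inline void set_t(double* p, int N, int T, int K, int t,
                         const arma::mat& m) {
  for (int k = 0; k < K; ++k)
    for (int n = 0; n < N; ++n)
      p[n + (size_t)N * (t + (size_t)T * k)] = m(n, k);
}

static NumericVector alloc_arr(int N, int T, int K) {
  NumericVector v((size_t)N * T * K);
  v.attr("dim") = IntegerVector::create(N, T, K);
  return v;
}

// [[Rcpp::export(name = ".cell_forward_cpp")]]
List cell_forward_cpp(const arma::mat& W, const arma::vec& b,
                      NumericVector X, bool reverse, bool keep_cache) {
  IntegerVector dm = X.attr("dim");
  const int N = dm[0], T = dm[1], ind = dm[2];
  const int h = W.n_cols / 4;
  arma::mat Wx = W.rows(0, ind - 1);
  arma::mat Wh = W.rows(ind, ind + h - 1);
  arma::rowvec bt = b.t();

  NumericVector H = alloc_arr(N, T, h);
  NumericVector F, I, O, G, C, TanC;
  if (keep_cache) {
    F = alloc_arr(N, T, h); I = alloc_arr(N, T, h); O = alloc_arr(N, T, h);
    G = alloc_arr(N, T, h); C = alloc_arr(N, T, h); TanC = alloc_arr(N, T, h);
  }
  arma::mat hp(N, h, arma::fill::zeros), cp(N, h, arma::fill::zeros);
  for (int j = 0; j < T; ++j) {
    int t = reverse ? (T - 1 - j) : j;
    arma::mat xt = get_t(X.begin(), N, T, ind, t);
    arma::mat z = xt * Wx + hp * Wh;
    z.each_row() += bt;
    arma::mat f = sigm(z.cols(0, h - 1));
    arma::mat i = sigm(z.cols(h, 2 * h - 1));
    arma::mat o = sigm(z.cols(2 * h, 3 * h - 1));
    arma::mat g = arma::tanh(z.cols(3 * h, 4 * h - 1));
    arma::mat cc = f % cp + g % i;
    arma::mat tc = arma::tanh(cc);
    arma::mat hh = o % tc;
    if (!hh.is_finite())
      stop("non-finite activation at time step %d", t + 1);
    set_t(H.begin(), N, T, h, t, hh);
    if (keep_cache) {
      set_t(F.begin(), N, T, h, t, f);
      set_t(I.begin(), N, T, h, t, i);
      set_t(O.begin(), N, T, h, t, o);
      set_t(G.begin(), N, T, h, t, g);
      set_t(C.begin(), N, T, h, t, cc);
      set_t(TanC.begin(), N, T, h, t, tc);
    }
    hp = hh; cp = cc;
  }
  if (keep_cache)
    return List::create(_["H"] = H, _["F"] = F, _["I"] = I, _["O"] = O,
                        _["G"] = G, _["C"] = C, _["TanC"] = TanC);
  return List::create(_["H"] = H);
}

// [[Rcpp::export(name = ".cell_backward_cpp")]]
List cell_backward_cpp(const arma::mat& W, NumericVector X, NumericVector H,
                       NumericVector F, NumericVector I, NumericVector O,
                       NumericVector G, NumericVector C, NumericVector TanC,
                       NumericVector dH_ext, bool reverse) {
  IntegerVector dm = X.attr("dim");
  const int N = dm[0], T = dm[1], ind = dm[2];
  const int h = W.n_cols / 4;
  arma::mat Wx = W.rows(0, ind - 1);
  arma::mat Wh = W.rows(ind, ind + h - 1);

  NumericVector dX = alloc_arr(N, T, ind);
  arma::mat dWx(ind, 4 * h, arma::fill::zeros);
  arma::mat dWh(h, 4 * h, arma::fill::zeros);
  arma::rowvec db(4 * h, arma::fill::zeros);
  arma::mat dh(N, h, arma::fill::zeros), dc(N, h, arma::fill::zeros);
  arma::mat zero(N, h, arma::fill::zeros);

  for (int j = T - 1; j >= 0; --j) {
    int t = reverse ? (T - 1 - j) : j;
    arma::mat f = get_t(F.begin(), N, T, h, t);
    arma::mat i = get_t(I.begin(), N, T, h, t);
    arma::mat o = get_t(O.begin(), N, T, h, t);
    arma::mat g = get_t(G.begin(), N, T, h, t);
    arma::mat tc = get_t(TanC.begin(), N, T, h, t);
    arma::mat hp, cp;
    if (j > 0) {
      int tp = reverse ? (T - j) : (j - 1);
      hp = get_t(H.begin(), N, T, h, tp);
      cp = get_t(C.begin(), N, T, h, tp);
    } else {
      hp = zero; cp = zero;
    }
    arma::mat dht = dh + get_t(dH_ext.begin(), N, T, h, t);
    arma::mat do_ = dht % tc;
    arma::mat dct = dc + dht % o % (1.0 - tc % tc);
    arma::mat df = dct % cp;
    arma::mat di = dct % g;
    arma::mat dg = dct % i;
    dc = dct % f;
    arma::mat dz(N, 4 * h);
    dz.cols(0, h - 1) = df % f % (1.0 - f);
    dz.cols(h, 2 * h - 1) = di % i % (1.0 - i);
    dz.cols(2 * h, 3 * h - 1) = do_ % o % (1.0 - o);
    dz.cols(3 * h, 4 * h - 1) = dg % (1.0 - g % g);
    arma::mat xt = get_t(X.begin(), N, T, ind, t);
    dWx += xt.t() * dz;
    dWh += hp.t() * dz;
    db += arma::sum(dz, 0);
    set_t(dX.begin(), N, T, ind, t, dz * Wx.t());
    dh = dz * Wh.t();
  }
  arma::mat dW = arma::join_cols(dWx, dWh);
  return List::create(_["dX"] = dX, _["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
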