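// Hot path of the convolutional classifier: training/evaluation forward pass
// and backpropagation. Mirrors the reference R implementation in model.R
// (channel-major layout: conv-stage tensors are filters x N*positions with
// columns ordered sample-fastest); the two are compared in the test suite.
//
// The conv-stage tensors are large (filters x N*conv_len), so the code works
// in place where possible and caches only what backpropagation needs: the
// batch-normalized activations xhat1, the pool argmax index, and the
// flattened features. The window matrix Xw is cheap to rebuild.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-5;

// wrap an arma vector as a plain R vector (not an n x 1 matrix)
static NumericVector nv(const arma::vec& v) {
  return NumericVector(v.begin(), v.end());
}

static arma::mat build_windows(const arma::mat& X, int K, int stride,
                               int conv_len) {
  const int N = X.n_rows;
  arma::mat Xw(N * conv_len, K);
  for (int s = 0; s < K; ++s)
    for (int t = 0; t < conv_len; ++t)
      Xw.col(s).subvec(t * N, t * N + N - 1) = X.col(t * stride + s);
  return Xw;
}

// rows = channels/features, columns = observations; normalizes Z in place
// into xhat and reports the statistics used
struct BnStats {
  arma::vec mu, invstd, run_mean, run_var;
};

static BnStats bn_normalize(arma::mat& Z, bool training, double momentum,
                            const arma::vec& run_mean,
                            const arma::vec& run_var) {
  BnStats st;
  if (training) {
    st.mu = arma::mean(Z, 1);
    arma::vec va = arma::mean(arma::square(Z), 1) - arma::square(st.mu);
    double m = (double)Z.n_cols;
    arma::vec unbiased = (m > 1.0) ? arma::vec(va * m / (m - 1.0)) : va;
    st.run_mean = (1.0 - momentum) * run_mean + momentum * st.mu;
    st.run_var = (1.0 - momentum) * run_var + momentum * unbiased;
    st.invstd = 1.0 / arma::sqrt(va + BN_EPS);
  } else {
    st.mu = run_mean;
    st.run_mean = run_mean;
    st.run_var = run_var;
    st.invstd = 1.0 / arma::sqrt(run_var + BN_EPS);
  }
  Z.each_col() -= st.mu;
  Z.each_col() %= st.invstd;
  return st;
}

// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(const List& params, const List& buffers,
                 const arma::mat& X, bool training, double momentum,
                 bool relu_act, int conv_stride, int pool_kernel,
                 int pool_stride) {
  const arma::mat conv_w = params["conv_w"];   // F x K
  const arma::vec conv_b = params["conv_b"];
  const arma::vec bn1_gamma = params["bn1_gamma"], bn1_beta = params["bn1_beta"];
  const arma::mat fc1_w = params["fc1_w"];     // flat_dim x H
  const arma::vec fc1_b = params["fc1_b"];
  const arma::vec bn2_gamma = params["bn2_gamma"], bn2_beta = params["bn2_beta"];
  const arma::mat fc2_w = params["fc2_w"];     // H x C
  const arma::vec fc2_b = params["fc2_b"];

  const int N = X.n_rows, D = X.n_cols;
  const int F = conv_w.n_rows, K = conv_w.n_cols;
  const int conv_len = (D - K) / conv_stride + 1;
  const int pool_len = (conv_len - pool_kernel) / pool_stride + 1;
  const int M2 = N * pool_len;

  const arma::vec bn1_mean = buffers["bn1_mean"], bn1_var = buffers["bn1_var"];
  const arma::vec bn2_mean = buffers["bn2_mean"], bn2_var = buffers["bn2_var"];

  arma::mat Xw = build_windows(X, K, conv_stride, conv_len);
  arma::mat Z1 = conv_w * Xw.t();              // F x M1
  Xw.reset();
  Z1.each_col() += conv_b;
  BnStats st1 = bn_normalize(Z1, training, momentum, bn1_mean, bn1_var);
  arma::mat& xhat1 = Z1;                       // normalized in place

  // pool over scale-shifted (and optionally rectified) activations without
  // materializing them: a(f, j) = xhat1(f, j) * gamma_f + beta_f
  arma::mat P(F, M2);
  IntegerMatrix which_s(F, M2);
  const double* g = bn1_gamma.memptr();
  const double* be = bn1_beta.memptr();
  for (int i = 0; i < pool_len; ++i) {
    int base = i * pool_stride;
    for (int n = 0; n < N; ++n) {
      int pc = i * N + n;
      double* Pcol = P.colptr(pc);
      int* Wcol = &which_s(0, pc);
      for (int off = 0; off < pool_kernel; ++off) {
        const double* acol = xhat1.colptr((base + off) * N + n);
        for (int f = 0; f < F; ++f) {
          double v = acol[f] * g[f] + be[f];
          if (relu_act && v < 0.0) v = 0.0;
          if (off == 0 || v > Pcol[f]) { Pcol[f] = v; Wcol[f] = off + 1; }
        }
      }
    }
  }

  arma::mat flat(N, pool_len * F);             // flat(n, i + f*pool_len)
  for (int f = 0; f < F; ++f)
    for (int i = 0; i < pool_len; ++i) {
      double* fcol = flat.colptr(i + f * pool_len);
      const double* pcol = P.colptr(i * N);
      for (int n = 0; n < N; ++n) fcol[n] = pcol[n * F + f];
    }
  P.reset();

  arma::mat Hpre = (flat * fc1_w).t();         // H x N
  Hpre.each_col() += fc1_b;
  BnStats st2 = bn_normalize(Hpre, training, momentum, bn2_mean, bn2_var);
  arma::mat& xhat2 = Hpre;
  arma::mat A2 = xhat2;
  A2.each_col() %= bn2_gamma;
  A2.each_col() += bn2_beta;
  if (relu_act) A2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::mat logits = fc2_w.t() * A2;           // C x N
  logits.each_col() += fc2_b;

  List out = List::create(
    _["logits"] = logits.t(),
    _["buffers"] = List::create(
      _["bn1_mean"] = nv(st1.run_mean), _["bn1_var"] = nv(st1.run_var),
      _["bn2_mean"] = nv(st2.run_mean), _["bn2_var"] = nv(st2.run_var)));
  if (training)
    out["cache"] = List::create(
      _["xhat1"] = xhat1, _["invstd1"] = st1.invstd,
      _["which_s"] = which_s, _["flat"] = flat,
      _["xhat2"] = xhat2, _["invstd2"] = st2.invstd,
      _["A2"] = A2, _["N"] = N);
  return out;
}

// batch-norm backward, channel-major; consumes dy in place and returns dx in
// its memory
static void bn_backward_inplace(arma::mat& dy, const arma::mat& xhat,
                                const arma::vec& invstd,
                                const arma::vec& gamma,
                                arma::vec& dgamma, arma::vec& dbeta) {
  double m = (double)dy.n_cols;
  dgamma = arma::sum(dy % xhat, 1);
  dbeta = arma::sum(dy, 1);
  dy.each_col() %= gamma;                      // dxhat
  arma::vec t1 = arma::sum(dy, 1) / m;
  arma::vec t2 = arma::sum(dy % xhat, 1) / m;
  dy.each_col() -= t1;
  for (arma::uword j = 0; j < dy.n_cols; ++j) {
    double* d = dy.colptr(j);
    const double* xh = xhat.colptr(j);
    for (arma::uword f = 0; f < dy.n_rows; ++f)
      d[f] = (d[f] - xh[f] * t2[f]) * invstd[f];
  }
}

// [[Rcpp::export(name = ".cpp_backward")]]
List cpp_backward(const List& params, const List& cache,
                  const arma::mat& dlogits, const arma::mat& X,
                  bool relu_act, int conv_stride, int pool_kernel,
                  int pool_stride) {
  const arma::mat conv_w = params["conv_w"];
  const arma::mat fc1_w = params["fc1_w"];
  const arma::mat fc2_w = params["fc2_w"];
  const arma::vec bn1_gamma = params["bn1_gamma"], bn1_beta = params["bn1_beta"];
  const arma::vec bn2_gamma = params["bn2_gamma"], bn2_beta = params["bn2_beta"];
  const arma::mat xhat1 = cache["xhat1"];
  const arma::vec invstd1 = cache["invstd1"], invstd2 = cache["invstd2"];
  const IntegerMatrix which_s = cache["which_s"];
  const arma::mat flat = cache["flat"];
  const arma::mat xhat2 = cache["xhat2"];
  const arma::mat A2 = cache["A2"];
  const int N = as<int>(cache["N"]);
  const int F = conv_w.n_rows, K = conv_w.n_cols;
  const int M1 = xhat1.n_cols, M2 = which_s.ncol();
  const int pool_len = M2 / N;

  arma::mat dlt = dlogits.t();                 // C x N
  arma::mat g_fc2_w = A2 * dlogits;            // H x C
  arma::vec g_fc2_b = arma::sum(dlt, 1);
  arma::mat dA2 = fc2_w * dlt;                 // H x N
  if (relu_act) {
    // A2 = relu(bn2 out): the mask is A2 > 0 (ties at 0 get zero gradient)
    for (arma::uword j = 0; j < dA2.n_cols; ++j) {
      double* d = dA2.colptr(j);
      const double* a = A2.colptr(j);
      for (arma::uword f = 0; f < dA2.n_rows; ++f)
        if (a[f] <= 0.0) d[f] = 0.0;
    }
  }
  arma::vec g_bn2_gamma, g_bn2_beta;
  bn_backward_inplace(dA2, xhat2, invstd2, bn2_gamma, g_bn2_gamma, g_bn2_beta);
  arma::mat& dHpre = dA2;                      // H x N
  arma::mat g_fc1_w = flat.t() * dHpre.t();    // flat_dim x H
  arma::vec g_fc1_b = arma::sum(dHpre, 1);
  arma::mat dflat = dHpre.t() * fc1_w.t();     // N x flat_dim

  // scatter pooled gradients back to conv positions (argmax routing),
  // rectifier mask applied on the fly from the cached normalized values
  arma::mat dA1(F, M1, arma::fill::zeros);
  const double* g = bn1_gamma.memptr();
  const double* be = bn1_beta.memptr();
  for (int i = 0; i < pool_len; ++i) {
    int base = i * pool_stride;
    for (int n = 0; n < N; ++n) {
      int pc = i * N + n;
      const int* Wcol = &which_s(0, pc);
      for (int f = 0; f < F; ++f) {
        int ac = (base + Wcol[f] - 1) * N + n;
        double grad = dflat(n, i + f * pool_len);
        if (relu_act) {
          double v = xhat1(f, ac) * g[f] + be[f];
          if (v <= 0.0) grad = 0.0;
        }
        dA1(f, ac) += grad;
      }
    }
  }
  arma::vec g_bn1_gamma, g_bn1_beta;
  bn_backward_inplace(dA1, xhat1, invstd1, bn1_gamma, g_bn1_gamma, g_bn1_beta);
  arma::mat& dZ1 = dA1;                        // F x M1
  arma::mat Xw = build_windows(X, K, conv_stride, (M1 / N));
  arma::mat g_conv_w = dZ1 * Xw;               // F x K
  arma::vec g_conv_b = arma::sum(dZ1, 1);

  return List::create(
    _["fc2_w"] = g_fc2_w, _["fc2_b"] = g_fc2_b,
    _["bn2_gamma"] = g_bn2_gamma, _["bn2_beta"] = g_bn2_beta,
    _["fc1_w"] = g_fc1_w, _["fc1_b"] = g_fc1_b,
    _["bn1_gamma"] = g_bn1_gamma, _["bn1_beta"] = g_bn1_beta,
    _["conv_w"] = g_conv_w, _["conv_b"] = g_conv_b);
}
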