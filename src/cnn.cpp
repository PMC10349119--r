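// Hot kernels of the 1-D convolutional network: per-sample im2col + GEMM
// forward pass, fused backward pass, input gradients, and the init-scale
// calibration. Layout conventions match the R layer: conv weights are
// (channels_in * kernel) x filters with row index c*K + k (channel c,
// kernel offset k, 0-based); the flattened feature map stacks positions
// within each filter channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int K = 3;        // kernel width
static const int NF = 64;      // filters per conv layer
static const int ND = 16;      // dense layer width

// softplus and logistic from one exp(-|z|) pass
static inline void act_pair(const mat& Z, mat& soft, mat& sig) {
  soft.set_size(Z.n_rows, Z.n_cols);
  sig.set_size(Z.n_rows, Z.n_cols);
  for (uword i = 0; i < Z.n_elem; ++i) {
    double z = Z[i];
    double e = std::exp(-std::fabs(z));
    sig[i] = (z >= 0) ? 1.0 / (1.0 + e) : e / (1.0 + e);
    soft[i] = (z >= 0 ? z : 0.0) + std::log1p(e);
  }
}

// A is (C x L); returns (Lout x C*K) with M(t, c*K + k) = A(c, t + k)
static mat im2col1(const mat& A) {
  int C = A.n_rows, L = A.n_cols, Lout = L - K + 1;
  mat M(Lout, C * K);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < Lout; ++t)
        M(t, c * K + k) = A(c, t + k);
  return M;
}

// scatter dM (Lout x C*K) back to dA (C x L)
static mat col2im1(const mat& dM, int C, int L) {
  int Lout = L - K + 1;
  mat dA(C, L, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < Lout; ++t)
        dA(c, t + k) += dM(t, c * K + k);
  return dA;
}

struct Params {
  mat W[3]; vec b[3];
  mat W4; vec b4;
  vec W5; double b5;
  vec g;  // fixed per-layer scale constants
};

static Params unpack(const Rcpp::List& params, const arma::vec& scales) {
  Params P;
  P.W[0] = Rcpp::as<mat>(params["W1"]); P.b[0] = Rcpp::as<vec>(params["b1"]);
  P.W[1] = Rcpp::as<mat>(params["W2"]); P.b[1] = Rcpp::as<vec>(params["b2"]);
  P.W[2] = Rcpp::as<mat>(params["W3"]); P.b[2] = Rcpp::as<vec>(params["b3"]);
  P.W4 = Rcpp::as<mat>(params["W4"]);   P.b4 = Rcpp::as<vec>(params["b4"]);
  P.W5 = Rcpp::as<vec>(params["W5"]);   P.b5 = Rcpp::as<double>(params["b5"]);
  P.g = scales;
  return P;
}

struct Cache {
  mat M[3];      // im2col matrices
  mat sig[3];    // logistic of conv pre-activations
  umat argmax[3];// pooling argmax row (0/1 offset)
  mat drop[3];   // scaled dropout masks (empty when off)
  int Lin[3], Cin[3];
  vec flat, sig4, h;
  double o;
};

// forward one sample; x is a row of the input matrix
static double forward1(const Params& P, const rowvec& x, bool training,
                       double dropout, Cache* cache) {
  mat A = x;  // (1 x p)
  for (int l = 0; l < 3; ++l) {
    int C = A.n_rows, L = A.n_cols;
    mat M = im2col1(A);
    mat Z = (M * P.W[l]) * P.g[l];
    Z.each_row() += P.b[l].t();
    mat soft, sig;
    act_pair(Z, soft, sig);
    int Lout = Z.n_rows, Lp = Lout / 2;
    mat Pool(Lp, NF);
    umat amax(Lp, NF);
    for (int f = 0; f < NF; ++f)
      for (int t = 0; t < Lp; ++t) {
        double a = soft(2 * t, f), b2 = soft(2 * t + 1, f);
        if (a >= b2) { Pool(t, f) = a; amax(t, f) = 0; }
        else         { Pool(t, f) = b2; amax(t, f) = 1; }
      }
    mat dm;
    if (training && dropout > 0) {
      dm.set_size(Lp, NF);
      double inv = 1.0 / (1.0 - dropout);
      for (uword i = 0; i < dm.n_elem; ++i)
        dm[i] = (R::unif_rand() >= dropout) ? inv : 0.0;
      Pool %= dm;
    }
    if (cache) {
      cache->M[l] = std::move(M);
      cache->sig[l] = std::move(sig);
      cache->argmax[l] = std::move(amax);
      cache->drop[l] = std::move(dm);
      cache->Lin[l] = L; cache->Cin[l] = C;
    }
    A = Pool.t();  // next layer input (F x Lp)
  }
  vec flat = vectorise(A.t());  // (Lp x F) column-major: positions fastest
  vec z4 = (P.W4.t() * flat) * P.g[3] + P.b4;
  mat soft4, sig4;
  act_pair(z4, soft4, sig4);
  vec h = soft4;
  double z5 = dot(h, P.W5) * P.g[4] + P.b5;
  double e = std::exp(-std::fabs(z5));
  double o = (z5 >= 0) ? 1.0 / (1.0 + e) : e / (1.0 + e);
  if (cache) {
    cache->flat = std::move(flat);
    cache->sig4 = std::move(sig4);
    cache->h = std::move(h);
    cache->o = o;
  }
  return o;
}

struct Grads {
  mat W[3]; vec b[3];
  mat W4; vec b4;
  vec W5; double b5;
  void init(const Params& P) {
    for (int l = 0; l < 3; ++l) {
      W[l].zeros(P.W[l].n_rows, P.W[l].n_cols);
      b[l].zeros(P.b[l].n_elem);
    }
    W4.zeros(P.W4.n_rows, P.W4.n_cols);
    b4.zeros(P.b4.n_elem);
    W5.zeros(P.W5.n_elem);
    b5 = 0.0;
  }
};

// backward one sample from the seed gradient on the pre-sigmoid output;
// returns the input gradient row when want_dx
static rowvec backward1(const Params& P, const Cache& cc, double dz5,
                        Grads* G, bool want_dx) {
  G->W5 += cc.h * (dz5 * P.g[4]);
  G->b5 += dz5;
  vec dh = P.W5 * (dz5 * P.g[4]);
  vec dz4 = dh % cc.sig4;
  G->W4 += (cc.flat * dz4.t()) * P.g[3];
  G->b4 += dz4;
  vec dflat = (P.W4 * dz4) * P.g[3];
  int Lp3 = dflat.n_elem / NF;
  mat dPool(dflat.memptr(), Lp3, NF);  // copy into (Lp x F)
  for (int l = 2; l >= 0; --l) {
    if (cc.drop[l].n_elem) dPool %= cc.drop[l];
    int Lout = cc.Lin[l] - K + 1;
    mat dZ(Lout, NF, fill::zeros);
    const umat& am = cc.argmax[l];
    for (int f = 0; f < NF; ++f)
      for (uword t = 0; t < dPool.n_rows; ++t)
        dZ(2 * t + am(t, f), f) = dPool(t, f);
    dZ %= cc.sig[l];
    G->W[l] += (cc.M[l].t() * dZ) * P.g[l];
    G->b[l] += sum(dZ, 0).t();
    if (l > 0 || want_dx) {
      mat dM = (dZ * P.W[l].t()) * P.g[l];
      mat dA = col2im1(dM, cc.Cin[l], cc.Lin[l]);  // (C x L)
      if (l > 0) dPool = dA.t();
      else return dA.row(0);
    }
  }
  return rowvec();
}

// [[Rcpp::export]]
arma::vec cpp_cnn_predict(Rcpp::List params, arma::vec scales, arma::mat X) {
  Params P = unpack(params, scales);
  vec out(X.n_rows);
  for (uword i = 0; i < X.n_rows; ++i)
    out(i) = forward1(P, X.row(i), false, 0.0, nullptr);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train_batch(Rcpp::List params, arma::vec scales,
                               arma::mat X, arma::vec y, double dropout) {
  Params P = unpack(params, scales);
  Grads G;
  G.init(P);
  int B = X.n_rows;
  double loss = 0.0;
  Cache cc;
  for (int i = 0; i < B; ++i) {
    double o = forward1(P, X.row(i), true, dropout, &cc);
    double oc = std::min(std::max(o, 1e-12), 1.0 - 1e-12);
    loss += -(y(i) * std::log(oc) + (1.0 - y(i)) * std::log(1.0 - oc));
    double dz5 = (o - y(i)) / B;  // sigmoid + BCE shortcut
    backward1(P, cc, dz5, &G, false);
  }
  loss /= B;
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W1") = G.W[0], Rcpp::Named("b1") = G.b[0],
      Rcpp::Named("W2") = G.W[1], Rcpp::Named("b2") = G.b[1],
      Rcpp::Named("W3") = G.W[2], Rcpp::Named("b3") = G.b[2],
      Rcpp::Named("W4") = G.W4,   Rcpp::Named("b4") = G.b4,
      Rcpp::Named("W5") = G.W5,   Rcpp::Named("b5") = G.b5));
}

// [[Rcpp::export]]
arma::mat cpp_cnn_input_grad(Rcpp::List params, arma::vec scales,
                             arma::mat X) {
  Params P = unpack(params, scales);
  mat out(X.n_rows, X.n_cols);
  Grads G;
  G.init(P);  // accumulated but unused
  Cache cc;
  for (uword i = 0; i < X.n_rows; ++i) {
    double o = forward1(P, X.row(i), false, 0.0, &cc);
    double dz5 = o * (1.0 - o);  // d o / d z5
    out.row(i) = backward1(P, cc, dz5, &G, true);
  }
  return out;
}

// Calibrate the fixed per-layer scales and center the biases on a probe
// batch, dropout active (training regime). Mutates copies; returns the new
// biases and scales.
// [[Rcpp::export]]
Rcpp::List cpp_cnn_calibrate(Rcpp::List params, arma::vec scales,
                             arma::mat X, double dropout) {
  Params P = unpack(params, scales);
  int B = X.n_rows;
  std::vector<mat> A(B);
  for (int i = 0; i < B; ++i) A[i] = mat(X.row(i));
  for (int l = 0; l < 3; ++l) {
    std::vector<mat> raw(B);
    running_stat<double> rs;
    for (int i = 0; i < B; ++i) {
      raw[i] = im2col1(A[i]) * P.W[l];
      for (uword j = 0; j < raw[i].n_elem; ++j) rs(raw[i][j]);
    }
    double s = rs.stddev();
    if (s > 0) P.g[l] = 1.0 / s;
    vec colmean(NF, fill::zeros);
    for (int i = 0; i < B; ++i) colmean += sum(raw[i], 0).t();
    colmean /= (double)(B * raw[0].n_rows);
    P.b[l] -= colmean * P.g[l];
    double inv = 1.0 / (1.0 - dropout);
    for (int i = 0; i < B; ++i) {
      mat Z = raw[i] * P.g[l];
      Z.each_row() += P.b[l].t();
      mat soft, sig;
      act_pair(Z, soft, sig);
      int Lp = Z.n_rows / 2;
      mat Pool(Lp, NF);
      for (int f = 0; f < NF; ++f)
        for (int t = 0; t < Lp; ++t)
          Pool(t, f) = std::max(soft(2 * t, f), soft(2 * t + 1, f));
      if (dropout > 0)
        for (uword j = 0; j < Pool.n_elem; ++j)
          Pool[j] *= (R::unif_rand() >= dropout) ? inv : 0.0;
      A[i] = Pool.t();
    }
  }
  mat raw4(B, ND);
  std::vector<vec> flat(B);
  for (int i = 0; i < B; ++i) {
    flat[i] = vectorise(A[i].t());
    raw4.row(i) = (P.W4.t() * flat[i]).t();
  }
  double s4 = stddev(vectorise(raw4));
  if (s4 > 0) P.g[3] = 1.0 / s4;
  P.b4 -= mean(raw4, 0).t() * P.g[3];
  vec raw5(B);
  for (int i = 0; i < B; ++i) {
    vec z4 = (P.W4.t() * flat[i]) * P.g[3] + P.b4;
    mat soft4, sig4;
    act_pair(z4, soft4, sig4);
    raw5(i) = dot(vec(soft4), P.W5);
  }
  double s5 = stddev(raw5);
  if (s5 > 0) P.g[4] = 1.0 / s5;
  P.b5 -= mean(raw5) * P.g[4];
  return Rcpp::List::create(
    Rcpp::Named("b1") = P.b[0], Rcpp::Named("b2") = P.b[1],
    Rcpp::Named("b3") = P.b[2], Rcpp::Named("b4") = P.b4,
    Rcpp::Named("b5") = P.b5,
    Rcpp::Named("scales") = P.g);
}
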