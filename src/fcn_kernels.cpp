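// Fused 1-D convolution + batch-norm + activation kernels for the FCN.
// Convolutions are valid-mode, stride 1, realised as im2col + GEMM.
// Activation layouts are channel-first: arrays of dim (ch, len, n).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

enum Act { ACT_NONE = 0, ACT_RELU = 1, ACT_SIGMOID = 2, ACT_TANH = 3 };

static arma::cube asCube(NumericVector x) {
  IntegerVector d = x.attr("dim");
  return arma::cube(x.begin(), d[0], d[1], d[2], false, true);
}

// im2col: A (in_ch, L1, n) -> S (k*in_ch, L2*n), row (j*in_ch + c) holds
// channel c at tap offset j.
static arma::mat im2col(const arma::cube& A, int k) {
  const int in_ch = A.n_rows, L1 = A.n_cols, n = A.n_slices;
  const int L2 = L1 - k + 1;
  arma::mat S(k * in_ch, (size_t)L2 * n);
  for (int s = 0; s < n; ++s) {
    const arma::mat& As = A.slice(s);
    for (int j = 0; j < k; ++j) {
      S.submat(j * in_ch, (size_t)s * L2, (j + 1) * in_ch - 1,
               (size_t)s * L2 + L2 - 1) = As.cols(j, j + L2 - 1);
    }
  }
  return S;
}

// col2im accumulate: dS (k*in_ch, L2*n) -> dA (in_ch, L1, n)
static arma::cube col2im(const arma::mat& dS, int k, int in_ch, int L1,
                         int n) {
  const int L2 = L1 - k + 1;
  arma::cube dA(in_ch, L1, n, arma::fill::zeros);
  for (int s = 0; s < n; ++s) {
    arma::mat& dAs = dA.slice(s);
    for (int j = 0; j < k; ++j) {
      dAs.cols(j, j + L2 - 1) +=
        dS.submat(j * in_ch, (size_t)s * L2, (j + 1) * in_ch - 1,
                  (size_t)s * L2 + L2 - 1);
    }
  }
  return dA;
}

static void applyAct(arma::mat& Z, int act) {
  switch (act) {
  case ACT_RELU: Z.for_each([](double& v) { if (v < 0) v = 0; }); break;
  case ACT_SIGMOID: Z.for_each([](double& v) { v = 1.0 / (1.0 + std::exp(-v)); }); break;
  case ACT_TANH: Z.for_each([](double& v) { v = std::tanh(v); }); break;
  default: break;
  }
}

// [[Rcpp::export(name = ".convBlockForward")]]
List convBlockForward(NumericVector A_, NumericMatrix Wmat_,
                      NumericVector b_, int kernel, int act, bool use_bn,
                      NumericVector gamma_, NumericVector beta_,
                      NumericVector rmean_, NumericVector rvar_,
                      bool train, double momentum, double eps) {
  arma::cube A = asCube(A_);
  arma::mat W(Wmat_.begin(), Wmat_.nrow(), Wmat_.ncol(), false, true);
  arma::vec b(b_.begin(), b_.size(), false, true);
  const int in_ch = A.n_rows, L1 = A.n_cols, n = A.n_slices;
  const int L2 = L1 - kernel + 1;
  const int out_ch = W.n_cols;
  const size_t m = (size_t)L2 * n;

  arma::mat S = im2col(A, kernel);
  arma::mat Z = W.t() * S;           // (out_ch, m)
  Z.each_col() += b;

  arma::vec invstd, rmean_new, rvar_new;
  arma::mat xhat;
  if (use_bn) {
    arma::vec gamma(gamma_.begin(), gamma_.size(), false, true);
    arma::vec beta(beta_.begin(), beta_.size(), false, true);
    if (train) {
      arma::vec mu = arma::mean(Z, 1);
      Z.each_col() -= mu;
      arma::vec v = arma::mean(arma::square(Z), 1);
      invstd = 1.0 / arma::sqrt(v + eps);
      Z.each_col() %= invstd;        // Z is now xhat
      xhat = Z;                      // cache for backward
      arma::vec rmean(rmean_.begin(), rmean_.size());
      arma::vec rvar(rvar_.begin(), rvar_.size());
      double ub = m > 1 ? (double)m / (m - 1.0) : 1.0;
      rmean_new = (1 - momentum) * rmean + momentum * mu;
      rvar_new = (1 - momentum) * rvar + momentum * (v * ub);
    } else {
      arma::vec rmean(rmean_.begin(), rmean_.size(), false, true);
      arma::vec rvar(rvar_.begin(), rvar_.size(), false, true);
      invstd = 1.0 / arma::sqrt(rvar + eps);
      Z.each_col() -= rmean;
      Z.each_col() %= invstd;
    }
    Z.each_col() %= gamma;
    Z.each_col() += beta;
  }
  applyAct(Z, act);

  NumericVector Y(Z.begin(), Z.end());
  Y.attr("dim") = IntegerVector::create(out_ch, L2, n);
  List out = List::create(_["Y"] = Y);
  if (use_bn && train) {
    out["xhat"] = xhat;
    out["invstd"] = invstd;
    out["rmean"] = rmean_new;
    out["rvar"] = rvar_new;
  }
  return out;
}

// [[Rcpp::export(name = ".convBlockBackward")]]
List convBlockBackward(NumericVector dY_, NumericVector Y_,
                       NumericVector A_, NumericMatrix Wmat_, int kernel,
                       int act, bool use_bn, NumericVector gamma_,
                       SEXP xhat_, NumericVector invstd_, bool need_dA) {
  arma::cube A = asCube(A_);
  arma::cube Yc = asCube(Y_);
  arma::cube dYc = asCube(dY_);
  arma::mat W(Wmat_.begin(), Wmat_.nrow(), Wmat_.ncol(), false, true);
  const int in_ch = A.n_rows, L1 = A.n_cols, n = A.n_slices;
  const int out_ch = Yc.n_rows;
  const int L2 = L1 - kernel + 1;
  const size_t m = (size_t)L2 * n;

  arma::mat dZ(dYc.memptr(), out_ch, m);      // copy of upstream grad
  const arma::mat Y(Yc.memptr(), out_ch, m, false, true);

  switch (act) {                              // through the activation
  case ACT_RELU: dZ.elem(arma::find(Y <= 0)).zeros(); break;
  case ACT_SIGMOID: dZ %= Y % (1.0 - Y); break;
  case ACT_TANH: dZ %= (1.0 - arma::square(Y)); break;
  default: break;
  }

  List out;
  if (use_bn) {
    arma::vec gamma(gamma_.begin(), gamma_.size(), false, true);
    NumericMatrix xh_(xhat_);
    arma::mat xhat(xh_.begin(), out_ch, m, false, true);
    arma::vec invstd(invstd_.begin(), invstd_.size(), false, true);
    out["dgamma"] = wrap(arma::vec(arma::sum(dZ % xhat, 1)));
    out["dbeta"] = wrap(arma::vec(arma::sum(dZ, 1)));
    dZ.each_col() %= gamma;                   // dxhat
    arma::vec s1 = arma::sum(dZ, 1);
    arma::vec s2 = arma::sum(dZ % xhat, 1);
    dZ *= (double)m;
    dZ.each_col() -= s1;
    dZ -= xhat.each_col() % s2;
    dZ.each_col() %= invstd / (double)m;
  }
  out["db"] = wrap(arma::vec(arma::sum(dZ, 1)));

  arma::mat S = im2col(A, kernel);
  out["dW"] = wrap(arma::mat(S * dZ.t()));    // (k*in_ch, out_ch)
  if (need_dA) {
    arma::mat dS = W * dZ;                    // (k*in_ch, m)
    arma::cube dA = col2im(dS, kernel, in_ch, L1, n);
    NumericVector dAv(dA.begin(), dA.end());
    dAv.attr("dim") = IntegerVector::create(in_ch, L1, n);
    out["dA"] = dAv;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused single-precision training step: full forward + backward for one
// mini-batch in one call. Single precision is the standard arithmetic for
// SGD-trained convolutional networks; the double-precision block kernels
// above remain the reference implementation. Activations are held as
// channel-first matrices (ch, L*n): sample s occupies columns
// [s*L, (s+1)*L).

// Rational minimax tanh approximation on [-7.905, 7.905] (accurate to a
// few float ulps; the form used by the major ML frameworks). Plain
// arithmetic, so the compiler can vectorise the loop.
static inline float fastTanhF(float x) {
  const float clamp = 7.90531110763549805f;
  x = x > clamp ? clamp : (x < -clamp ? -clamp : x);
  const float x2 = x * x;
  float p = -2.76076847742355e-16f;
  p = p * x2 + 2.00018790482477e-13f;
  p = p * x2 + -8.60467152213735e-11f;
  p = p * x2 + 5.12229709037114e-08f;
  p = p * x2 + 1.48572235717979e-05f;
  p = p * x2 + 6.37261928875436e-04f;
  p = p * x2 + 4.89352455891786e-03f;
  p *= x;
  float q = 1.19825839466702e-06f;
  q = q * x2 + 1.18534705686654e-04f;
  q = q * x2 + 2.26843463243900e-03f;
  q = q * x2 + 4.89352518554385e-03f;
  return p / q;
}

static void applyActF(arma::fmat& Z, int act) {
  float* z = Z.memptr();
  const size_t ne = Z.n_elem;
  switch (act) {
  case ACT_RELU:
    for (size_t e = 0; e < ne; ++e) if (z[e] < 0) z[e] = 0;
    break;
  case ACT_SIGMOID:
    for (size_t e = 0; e < ne; ++e)
      z[e] = 0.5f * (1.0f + fastTanhF(0.5f * z[e]));
    break;
  case ACT_TANH:
    for (size_t e = 0; e < ne; ++e) z[e] = fastTanhF(z[e]);
    break;
  default: break;
  }
}

// im2col on a channel-first (in_ch, L1*n) matrix
static arma::fmat im2colF(const arma::fmat& A, int L1, int n, int k) {
  const int in_ch = A.n_rows;
  const int L2 = L1 - k + 1;
  arma::fmat S(k * in_ch, (size_t)L2 * n);
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < k; ++j) {
      S.submat(j * in_ch, (size_t)s * L2, (j + 1) * in_ch - 1,
               (size_t)s * L2 + L2 - 1) =
        A.cols((size_t)s * L1 + j, (size_t)s * L1 + j + L2 - 1);
    }
  }
  return S;
}

// R array (k, in_ch, out_ch) -> (k*in_ch, out_ch) with row = j*in_ch + c
static arma::fmat wToF(NumericVector W_, int k, int in_ch, int out_ch) {
  arma::fmat Wf(k * in_ch, out_ch);
  const double* w = W_.begin();
  for (int o = 0; o < out_ch; ++o)
    for (int c = 0; c < in_ch; ++c)
      for (int j = 0; j < k; ++j)
        Wf(j * in_ch + c, o) = (float)w[j + k * ((size_t)c + in_ch * o)];
  return Wf;
}

static NumericVector wToR(const arma::fmat& G, int k, int in_ch, int out_ch) {
  NumericVector out(k * (size_t)in_ch * out_ch);
  for (int o = 0; o < out_ch; ++o)
    for (int c = 0; c < in_ch; ++c)
      for (int j = 0; j < k; ++j)
        out[j + k * ((size_t)c + in_ch * o)] = G(j * in_ch + c, o);
  out.attr("dim") = IntegerVector::create(k, in_ch, out_ch);
  return out;
}

static arma::fvec paramF(const List& params, const std::string& nm) {
  return arma::conv_to<arma::fvec>::from(
    Rcpp::as<arma::vec>(params[nm]));
}

// [[Rcpp::export(name = ".fcnTrainBatch")]]
List fcnTrainBatch(NumericMatrix X_, NumericMatrix onehot_, List params,
                   List state, List cfg) {
  const IntegerVector kernels = cfg["kernels"];
  const IntegerVector outch = cfg["out_channels"];
  const IntegerVector acts = cfg["acts"];
  const LogicalVector bns = cfg["bns"];
  const int pool = cfg["pool"];
  const int ncls = cfg["n_classes"];
  const double momentum = cfg["momentum"];
  const float eps = (float)Rcpp::as<double>(cfg["eps"]);
  const int nlayers = kernels.size();
  const int n = X_.ncol();

  // input as (1, len*n)
  arma::fmat A(1, (size_t)X_.nrow() * n);
  for (size_t i = 0; i < (size_t)X_.nrow() * n; ++i)
    A(0, i) = (float)X_[i];

  std::vector<arma::fmat> Ss(nlayers), Ys(nlayers), Xh(nlayers), Wf(nlayers);
  std::vector<arma::fvec> Invstd(nlayers);
  std::vector<int> L2s(nlayers), inchs(nlayers);
  List state_out = clone(state);

  int in_ch = 1, L1 = X_.nrow();
  for (int i = 0; i < nlayers; ++i) {
    const int k = kernels[i], oc = outch[i];
    const int L2 = L1 - k + 1;
    const size_t m = (size_t)L2 * n;
    std::string nm = "conv" + std::to_string(i);
    Wf[i] = wToF(params[nm + "_W"], k, in_ch, oc);
    Ss[i] = im2colF(A, L1, n, k);
    arma::fmat Z = Wf[i].t() * Ss[i];
    Z.each_col() += paramF(params, nm + "_b");
    if (bns[i]) {
      arma::fvec mu = arma::mean(Z, 1);
      Z.each_col() -= mu;
      arma::fvec v = arma::mean(arma::square(Z), 1);
      arma::fvec invstd = 1.0f / arma::sqrt(v + eps);
      Z.each_col() %= invstd;
      Xh[i] = Z;
      Invstd[i] = invstd;
      arma::vec rmean = state[nm + "_rmean"];
      arma::vec rvar = state[nm + "_rvar"];
      double ub = m > 1 ? (double)m / (m - 1.0) : 1.0;
      state_out[nm + "_rmean"] = wrap(arma::vec(
        (1 - momentum) * rmean +
        momentum * arma::conv_to<arma::vec>::from(mu)));
      state_out[nm + "_rvar"] = wrap(arma::vec(
        (1 - momentum) * rvar +
        momentum * ub * arma::conv_to<arma::vec>::from(v)));
      Z.each_col() %= paramF(params, nm + "_gamma");
      Z.each_col() += paramF(params, nm + "_beta");
    }
    applyActF(Z, acts[i]);
    Ys[i] = std::move(Z);
    L2s[i] = L2;
    inchs[i] = in_ch;
    A = Ys[i];  // copy; subsequent im2col reads it
    in_ch = oc;
    L1 = L2;
  }

  // average pool + flatten (channel fastest). F (ch*P, n) shares memory
  // layout with an (ch, P*n) matrix whose columns are (q within s).
  const int ch = in_ch, L = L1, P = L / pool;
  const arma::fmat& Atop = Ys[nlayers - 1];
  arma::fmat Fp(ch, (size_t)P * n, arma::fill::zeros);
  {
    arma::uvec cols((size_t)P * n);
    for (int j = 0; j < pool; ++j) {
      size_t t = 0;
      for (int s = 0; s < n; ++s)
        for (int q = 0; q < P; ++q, ++t)
          cols[t] = (size_t)s * L + q * pool + j;
      Fp += Atop.cols(cols);
    }
    Fp /= (float)pool;
  }
  const arma::fmat F(Fp.memptr(), (size_t)ch * P, n, false, true);
  arma::fmat Wc = arma::conv_to<arma::fmat>::from(
    Rcpp::as<arma::mat>(params["cls_W"]));
  arma::fvec bc = paramF(params, "cls_b");
  arma::fmat logits = F.t() * Wc;   // (n, ncls)
  logits.each_row() += bc.t();

  // softmax + cross-entropy
  arma::fmat probs = logits;
  double loss = 0;
  for (int s = 0; s < n; ++s) {
    arma::frowvec r = probs.row(s);
    r -= r.max();
    r = arma::exp(r);
    r /= arma::accu(r);
    probs.row(s) = r;
    for (int c = 0; c < ncls; ++c) {
      if (onehot_(s, c) > 0.5)
        loss -= std::log(std::max((double)r(c), 1e-12));
    }
  }
  loss /= n;
  arma::fmat dlogits = probs;
  for (int s = 0; s < n; ++s)
    for (int c = 0; c < ncls; ++c)
      dlogits(s, c) = (dlogits(s, c) - (float)onehot_(s, c)) / n;

  List grads;
  grads["cls_W"] = wrap(arma::conv_to<arma::mat>::from(
    arma::fmat(F * dlogits)));
  grads["cls_b"] = wrap(arma::conv_to<arma::vec>::from(
    arma::fvec(arma::sum(dlogits, 0).t())));
  arma::fmat dF = Wc * dlogits.t();  // (ch*P, n)

  // un-pool into (ch, L*n)
  arma::fmat dZ(ch, (size_t)L * n, arma::fill::zeros);
  {
    const arma::fmat dFp(dF.memptr(), ch, (size_t)P * n, false, true);
    arma::fmat g = dFp / (float)pool;
    size_t t = 0;
    for (int s = 0; s < n; ++s)
      for (int q = 0; q < P; ++q, ++t) {
        float* dst0 = dZ.colptr((size_t)s * L + q * pool);
        const float* gsrc = g.colptr(t);
        for (int j = 0; j < pool; ++j)
          std::copy(gsrc, gsrc + ch, dst0 + (size_t)j * ch);
      }
  }

  for (int i = nlayers - 1; i >= 0; --i) {
    const int k = kernels[i], oc = outch[i];
    const size_t m = (size_t)L2s[i] * n;
    std::string nm = "conv" + std::to_string(i);
    const arma::fmat& Y = Ys[i];
    switch (acts[i]) {
    case ACT_RELU: {
      const float* y = Y.memptr();
      float* dz = dZ.memptr();
      const size_t ne = Y.n_elem;
      for (size_t e = 0; e < ne; ++e) if (y[e] <= 0) dz[e] = 0;
      break;
    }
    case ACT_SIGMOID: dZ %= Y % (1.0f - Y); break;
    case ACT_TANH: dZ %= (1.0f - arma::square(Y)); break;
    default: break;
    }
    if (bns[i]) {
      const arma::fmat& xhat = Xh[i];
      grads[nm + "_gamma"] = wrap(arma::conv_to<arma::vec>::from(
        arma::fvec(arma::sum(dZ % xhat, 1))));
      grads[nm + "_beta"] = wrap(arma::conv_to<arma::vec>::from(
        arma::fvec(arma::sum(dZ, 1))));
      dZ.each_col() %= paramF(params, nm + "_gamma");
      arma::fvec s1 = arma::sum(dZ, 1);
      arma::fvec s2 = arma::sum(dZ % xhat, 1);
      dZ *= (float)m;
      dZ.each_col() -= s1;
      dZ -= xhat.each_col() % s2;
      dZ.each_col() %= Invstd[i] / (float)m;
    }
    grads[nm + "_b"] = wrap(arma::conv_to<arma::vec>::from(
      arma::fvec(arma::sum(dZ, 1))));
    grads[nm + "_W"] = wToR(arma::fmat(Ss[i] * dZ.t()), k, inchs[i], oc);
    if (i > 0) {
      arma::fmat dS = Wf[i] * dZ;  // (k*in_ch, m)
      const int in_ch_i = inchs[i], L1_i = L2s[i] + k - 1;
      arma::fmat dA(in_ch_i, (size_t)L1_i * n, arma::fill::zeros);
      for (int s = 0; s < n; ++s) {
        for (int j = 0; j < k; ++j) {
          dA.cols((size_t)s * L1_i + j, (size_t)s * L1_i + j + L2s[i] - 1) +=
            dS.submat(j * in_ch_i, (size_t)s * L2s[i], (j + 1) * in_ch_i - 1,
                      (size_t)s * L2s[i] + L2s[i] - 1);
        }
      }
      dZ = std::move(dA);
    }
  }

  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["state"] = state_out,
                      _["probs"] = wrap(arma::conv_to<arma::mat>::from(probs)));
}

// [[Rcpp::export(name = ".fcnPredictBatchF")]]
NumericMatrix fcnPredictBatchF(NumericMatrix X_, List params, List state,
                               List cfg) {
  const IntegerVector kernels = cfg["kernels"];
  const IntegerVector outch = cfg["out_channels"];
  const IntegerVector acts = cfg["acts"];
  const LogicalVector bns = cfg["bns"];
  const int pool = cfg["pool"];
  const int ncls = cfg["n_classes"];
  const float eps = (float)Rcpp::as<double>(cfg["eps"]);
  const int nlayers = kernels.size();
  const int n = X_.ncol();

  arma::fmat A(1, (size_t)X_.nrow() * n);
  for (size_t i = 0; i < (size_t)X_.nrow() * n; ++i)
    A(0, i) = (float)X_[i];

  int in_ch = 1, L1 = X_.nrow();
  for (int i = 0; i < nlayers; ++i) {
    const int k = kernels[i], oc = outch[i];
    const int L2 = L1 - k + 1;
    std::string nm = "conv" + std::to_string(i);
    arma::fmat Wfm = wToF(params[nm + "_W"], k, in_ch, oc);
    arma::fmat S = im2colF(A, L1, n, k);
    arma::fmat Z = Wfm.t() * S;
    Z.each_col() += paramF(params, nm + "_b");
    if (bns[i]) {
      arma::fvec rv = arma::conv_to<arma::fvec>::from(
        Rcpp::as<arma::vec>(state[nm + "_rvar"]));
      arma::fvec invstd = 1.0f / arma::sqrt(rv + eps);
      Z.each_col() -= arma::conv_to<arma::fvec>::from(
        Rcpp::as<arma::vec>(state[nm + "_rmean"]));
      Z.each_col() %= invstd;
      Z.each_col() %= paramF(params, nm + "_gamma");
      Z.each_col() += paramF(params, nm + "_beta");
    }
    applyActF(Z, acts[i]);
    A = std::move(Z);
    in_ch = oc;
    L1 = L2;
  }
  const int ch = in_ch, L = L1, P = L / pool;
  arma::fmat Fp(ch, (size_t)P * n, arma::fill::zeros);
  {
    arma::uvec cols((size_t)P * n);
    for (int j = 0; j < pool; ++j) {
      size_t t = 0;
      for (int s = 0; s < n; ++s)
        for (int q = 0; q < P; ++q, ++t)
          cols[t] = (size_t)s * L + q * pool + j;
      Fp += A.cols(cols);
    }
    Fp /= (float)pool;
  }
  const arma::fmat F(Fp.memptr(), (size_t)ch * P, n, false, true);
  arma::fmat Wc = arma::conv_to<arma::fmat>::from(
    Rcpp::as<arma::mat>(params["cls_W"]));
  arma::fmat logits = F.t() * Wc;
  logits.each_row() += paramF(params, "cls_b").t();
  NumericMatrix out(n, ncls);
  for (int s = 0; s < n; ++s) {
    arma::frowvec r = logits.row(s);
    r -= r.max();
    r = arma::exp(r);
    r /= arma::accu(r);
    for (int c = 0; c < ncls; ++c) out(s, c) = r(c);
  }
  return out;
}
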