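// Minimal convolutional classifier: im2col convolutions, 2x2 max pooling,
// fully-connected head, softmax cross-entropy, SGD with Nesterov momentum.
//
// Layout conventions (shared with the R side):
//  - a batch arrives as a (H, W, C, N) numeric array in [-1, 1];
//  - activations between conv layers are (C x H*W*N) matrices where image n
//    occupies columns [n*H*W, (n+1)*H*W) and the within-image column index is
//    y + H*x (column-major over (y, x));
//  - im2col rows are ordered ky + K*kx + K*K*c, so an R-side
//    array(W[f, ], dim = c(K, K, C)) recovers filter f as [ky, kx, c];
//  - conv weights: (F x K*K*C), fc weights: (out x in); biases are vectors.
//
// Weights and velocities live in R memory as doubles and are updated in
// place; the forward/backward arithmetic runs in single precision (the
// batch compute is gemm-dominated and sgemm is about twice dgemm). No
// randomness lives here: shuffling, cropping, flipping and initialization
// are drawn from R's RNG so whole runs are reproducible from one seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvLayer {
  NumericMatrix Wd;  // R-owned storage (updated in place)
  NumericVector bd;
  arma::fmat W;      // float working copy for this call
  arma::fvec b;
  int K, stride, F;
  bool pool;
  ConvLayer(NumericMatrix w, NumericVector bias, int k, int s, bool p)
      : Wd(w), bd(bias), K(k), stride(s), F(w.nrow()), pool(p) {
    W = arma::conv_to<arma::fmat>::from(
        arma::mat(w.begin(), w.nrow(), w.ncol(), false, true));
    b = arma::conv_to<arma::fvec>::from(
        arma::vec(bias.begin(), bias.size(), false, true));
  }
};

struct FcLayer {
  NumericMatrix Wd;
  NumericVector bd;
  arma::fmat W;
  arma::fvec b;
  FcLayer(NumericMatrix w, NumericVector bias) : Wd(w), bd(bias) {
    W = arma::conv_to<arma::fmat>::from(
        arma::mat(w.begin(), w.nrow(), w.ncol(), false, true));
    b = arma::conv_to<arma::fvec>::from(
        arma::vec(bias.begin(), bias.size(), false, true));
  }
};

std::vector<ConvLayer> parse_conv(List conv) {
  std::vector<ConvLayer> out;
  for (int i = 0; i < conv.size(); ++i) {
    List l = conv[i];
    out.emplace_back(as<NumericMatrix>(l["W"]), as<NumericVector>(l["b"]),
                     as<int>(l["kernel"]), as<int>(l["stride"]),
                     as<bool>(l["pool"]));
  }
  return out;
}

std::vector<FcLayer> parse_fc(List fc) {
  std::vector<FcLayer> out;
  for (int i = 0; i < fc.size(); ++i) {
    List l = fc[i];
    out.emplace_back(as<NumericMatrix>(l["W"]), as<NumericVector>(l["b"]));
  }
  return out;
}

// (H, W, C, N) array -> (C x H*W*N) activation matrix
arma::fmat batch_to_act(const NumericVector& X, int H, int W, int C, int N) {
  arma::fmat A(C, (size_t)H * W * N);
  const double* px = X.begin();
  float* pa = A.memptr();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = px + (size_t)H * W * (c + (size_t)C * n);
      float* dst = pa + (size_t)n * H * W * C + c;
      for (size_t j = 0; j < (size_t)H * W; ++j) dst[j * C] = (float)src[j];
    }
  return A;
}

void im2col(const arma::fmat& A, int C, int H, int W, int K, int stride,
            int N, arma::fmat& out, int& oh, int& ow) {
  oh = (H - K) / stride + 1;
  ow = (W - K) / stride + 1;
  out.set_size((size_t)K * K * C, (size_t)oh * ow * N);
  const float* pa = A.memptr();
  for (int n = 0; n < N; ++n) {
    size_t img_off = (size_t)n * H * W;
    for (int x = 0; x < ow; ++x)
      for (int y = 0; y < oh; ++y) {
        size_t col = (size_t)n * oh * ow + (size_t)x * oh + y;
        float* dst = out.colptr(col);
        for (int c = 0; c < C; ++c) {
          for (int kx = 0; kx < K; ++kx) {
            const float* src =
                pa + ((img_off + (size_t)(x * stride + kx) * H +
                       (size_t)(y * stride)) * C) + c;
            float* d2 = dst + (size_t)c * K * K + (size_t)kx * K;
            for (int ky = 0; ky < K; ++ky) d2[ky] = src[(size_t)ky * C];
          }
        }
      }
  }
}

void col2im(const arma::fmat& dXc, int C, int H, int W, int K, int stride,
            int N, arma::fmat& dA) {
  int oh = (H - K) / stride + 1;
  int ow = (W - K) / stride + 1;
  dA.zeros(C, (size_t)H * W * N);
  float* pa = dA.memptr();
  for (int n = 0; n < N; ++n) {
    size_t img_off = (size_t)n * H * W;
    for (int x = 0; x < ow; ++x)
      for (int y = 0; y < oh; ++y) {
        size_t col = (size_t)n * oh * ow + (size_t)x * oh + y;
        const float* src = dXc.colptr(col);
        for (int c = 0; c < C; ++c)
          for (int kx = 0; kx < K; ++kx) {
            float* dst =
                pa + ((img_off + (size_t)(x * stride + kx) * H +
                       (size_t)(y * stride)) * C) + c;
            const float* s2 = src + (size_t)c * K * K + (size_t)kx * K;
            for (int ky = 0; ky < K; ++ky) dst[(size_t)ky * C] += s2[ky];
          }
      }
  }
}

// 2x2 / stride-2 max pooling over complete blocks; amax holds the source
// column index inside Z for each pooled element (row is unchanged).
void maxpool(const arma::fmat& Z, int F, int oh, int ow, int N, arma::fmat& P,
             arma::Mat<unsigned int>& amax, int& ph, int& pw) {
  ph = oh / 2;
  pw = ow / 2;
  P.set_size(F, (size_t)ph * pw * N);
  amax.set_size(F, (size_t)ph * pw * N);
  for (int n = 0; n < N; ++n)
    for (int x = 0; x < pw; ++x)
      for (int y = 0; y < ph; ++y) {
        size_t pc = (size_t)n * ph * pw + (size_t)x * ph + y;
        size_t c00 = (size_t)n * oh * ow + (size_t)(2 * x) * oh + 2 * y;
        const size_t cand[4] = {c00, c00 + 1, c00 + oh, c00 + oh + 1};
        const float* z0 = Z.colptr(cand[0]);
        const float* z1 = Z.colptr(cand[1]);
        const float* z2 = Z.colptr(cand[2]);
        const float* z3 = Z.colptr(cand[3]);
        float* pp = P.colptr(pc);
        unsigned int* pam = amax.colptr(pc);
        for (int f = 0; f < F; ++f) {
          float best = z0[f];
          size_t bi = cand[0];
          if (z1[f] > best) { best = z1[f]; bi = cand[1]; }
          if (z2[f] > best) { best = z2[f]; bi = cand[2]; }
          if (z3[f] > best) { best = z3[f]; bi = cand[3]; }
          pp[f] = best;
          pam[f] = (unsigned int)bi;
        }
      }
}

inline void relu_copy(const arma::fmat& Z, arma::fmat& R) {
  R.set_size(arma::size(Z));
  const float* z = Z.memptr();
  float* r = R.memptr();
  size_t n = Z.n_elem;
  for (size_t i = 0; i < n; ++i) r[i] = z[i] > 0.0f ? z[i] : 0.0f;
}

inline void relu_mask(const arma::fmat& Z, arma::fmat& D) {
  const float* z = Z.memptr();
  float* d = D.memptr();
  size_t n = Z.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (z[i] <= 0.0f) d[i] = 0.0f;
}

struct ForwardState {
  std::vector<arma::fmat> Xc;
  std::vector<arma::fmat> Z;
  std::vector<arma::Mat<unsigned int>> amax;
  std::vector<int> oh, ow, ph, pw, Cin, Hin, Win;
  arma::fmat Feat;
  std::vector<arma::fmat> fc_z;
  std::vector<arma::fmat> fc_a;
  arma::fmat logits;
};

void forward(const std::vector<ConvLayer>& conv, const std::vector<FcLayer>& fc,
             const NumericVector& X, int H0, int C0, int N, ForwardState& st,
             bool keep) {
  arma::fmat A = batch_to_act(X, H0, H0, C0, N);
  int C = C0, H = H0, W = H0;
  size_t L = conv.size();
  st.Xc.resize(L); st.Z.resize(L); st.amax.resize(L);
  st.oh.resize(L); st.ow.resize(L); st.ph.resize(L); st.pw.resize(L);
  st.Cin.resize(L); st.Hin.resize(L); st.Win.resize(L);
  for (size_t l = 0; l < L; ++l) {
    const ConvLayer& cl = conv[l];
    if (cl.K > H || cl.K > W)
      stop("conv kernel larger than its input feature map");
    st.Cin[l] = C; st.Hin[l] = H; st.Win[l] = W;
    arma::fmat Xc;
    int oh, ow;
    im2col(A, C, H, W, cl.K, cl.stride, N, Xc, oh, ow);
    arma::fmat Z = cl.W * Xc;
    Z.each_col() += cl.b;
    st.oh[l] = oh; st.ow[l] = ow;
    arma::fmat R;
    relu_copy(Z, R);
    if (cl.pool) {
      arma::fmat P; arma::Mat<unsigned int> am; int ph, pw;
      maxpool(R, cl.F, oh, ow, N, P, am, ph, pw);
      if (ph < 1 || pw < 1) stop("feature map too small to pool");
      A = std::move(P);
      st.ph[l] = ph; st.pw[l] = pw;
      if (keep) st.amax[l] = std::move(am);
    } else {
      A = std::move(R);
      st.ph[l] = oh; st.pw[l] = ow;
    }
    if (keep) { st.Xc[l] = std::move(Xc); st.Z[l] = std::move(Z); }
    C = cl.F; H = st.ph[l]; W = st.pw[l];
  }
  size_t pp = (size_t)H * W;
  size_t D = (size_t)C * pp;
  st.Feat.set_size(D, N);
  for (int n = 0; n < N; ++n)
    st.Feat.col(n) =
        arma::vectorise(A.cols((size_t)n * pp, (size_t)(n + 1) * pp - 1));
  arma::fmat a = st.Feat;
  st.fc_z.resize(fc.size());
  st.fc_a.resize(fc.size());
  for (size_t l = 0; l < fc.size(); ++l) {
    if (keep) st.fc_a[l] = a;
    arma::fmat z = fc[l].W * a;
    z.each_col() += fc[l].b;
    if (l + 1 < fc.size()) relu_copy(z, a);
    else a = z;
    if (keep) st.fc_z[l] = std::move(z);
  }
  st.logits = std::move(a);
}

// w (double, R memory) <- Nesterov update from float gradient g
void nesterov_update(double* w, double* v, const float* g, size_t n,
                     double lr, double mu) {
  for (size_t i = 0; i < n; ++i) {
    double gi = (double)g[i];
    v[i] = mu * v[i] + gi;
    w[i] -= lr * (gi + mu * v[i]);
  }
}

}  // namespace

// One SGD + Nesterov minibatch step. Mutates the weight and velocity
// matrices of `model` / `velocity` in place; returns the batch's mean
// cross-entropy (computed before the update).
// [[Rcpp::export]]
double cpp_train_batch(List model, List velocity, NumericVector X,
                       IntegerVector y, double lr, double momentum) {
  IntegerVector dim = X.attr("dim");
  int H0 = dim[0], C0 = dim[2], N = dim[3];
  if (dim[1] != H0) stop("non-square input batch");
  std::vector<ConvLayer> conv = parse_conv(model["conv"]);
  std::vector<FcLayer> fc = parse_fc(model["fc"]);
  std::vector<ConvLayer> vconv = parse_conv(velocity["conv"]);
  std::vector<FcLayer> vfc = parse_fc(velocity["fc"]);

  ForwardState st;
  forward(conv, fc, X, H0, C0, N, st, true);

  arma::fmat p = st.logits;
  p.each_row() -= arma::max(p, 0);
  p = arma::exp(p);
  arma::frowvec colsum = arma::sum(p, 0);
  p.each_row() /= colsum;
  double loss = 0.0;
  for (int n = 0; n < N; ++n)
    loss -= std::log(std::max((double)p(y[n], n), 1e-30));
  loss /= N;

  arma::fmat dz = p;
  for (int n = 0; n < N; ++n) dz(y[n], n) -= 1.0f;
  dz /= (float)N;
  std::vector<arma::fmat> fc_dW(fc.size());
  std::vector<arma::fvec> fc_db(fc.size());
  for (int l = (int)fc.size() - 1; l >= 0; --l) {
    fc_dW[l] = dz * st.fc_a[l].t();
    fc_db[l] = arma::sum(dz, 1);
    if (l > 0) {
      arma::fmat da = fc[l].W.t() * dz;
      dz = std::move(da);
      relu_mask(st.fc_z[l - 1], dz);
    } else {
      dz = fc[0].W.t() * dz;  // gradient w.r.t. Feat
    }
  }

  int L = (int)conv.size();
  int Cl = conv[L - 1].F;
  size_t pp = (size_t)st.ph[L - 1] * st.pw[L - 1];
  arma::fmat dA(Cl, pp * N);
  for (int n = 0; n < N; ++n)
    dA.cols((size_t)n * pp, (size_t)(n + 1) * pp - 1) =
        arma::reshape(dz.col(n), Cl, pp);

  std::vector<arma::fmat> conv_dW(L);
  std::vector<arma::fvec> conv_db(L);
  for (int l = L - 1; l >= 0; --l) {
    const ConvLayer& cl = conv[l];
    arma::fmat dR;
    if (cl.pool) {
      dR.zeros(cl.F, (size_t)st.oh[l] * st.ow[l] * N);
      const arma::Mat<unsigned int>& am = st.amax[l];
      for (size_t j = 0; j < am.n_cols; ++j) {
        const unsigned int* aj = am.colptr(j);
        const float* dj = dA.colptr(j);
        for (int f = 0; f < cl.F; ++f) dR(f, aj[f]) += dj[f];
      }
    } else {
      dR = std::move(dA);
    }
    relu_mask(st.Z[l], dR);
    conv_dW[l] = dR * st.Xc[l].t();
    conv_db[l] = arma::sum(dR, 1);
    if (l > 0) {
      arma::fmat dXc = cl.W.t() * dR;
      col2im(dXc, st.Cin[l], st.Hin[l], st.Win[l], cl.K, cl.stride, N, dA);
    }
  }

  for (int l = 0; l < L; ++l) {
    nesterov_update(conv[l].Wd.begin(), vconv[l].Wd.begin(),
                    conv_dW[l].memptr(), conv_dW[l].n_elem, lr, momentum);
    nesterov_update(conv[l].bd.begin(), vconv[l].bd.begin(),
                    conv_db[l].memptr(), conv_db[l].n_elem, lr, momentum);
  }
  for (size_t l = 0; l < fc.size(); ++l) {
    nesterov_update(fc[l].Wd.begin(), vfc[l].Wd.begin(),
                    fc_dW[l].memptr(), fc_dW[l].n_elem, lr, momentum);
    nesterov_update(fc[l].bd.begin(), vfc[l].bd.begin(),
                    fc_db[l].memptr(), fc_db[l].n_elem, lr, momentum);
  }
  return loss;
}

// Forward pass only; returns the (n_classes x N) logit matrix.
// [[Rcpp::export]]
NumericMatrix cpp_logits(List model, NumericVector X) {
  IntegerVector dim = X.attr("dim");
  int H0 = dim[0], C0 = dim[2], N = dim[3];
  if (dim[1] != H0) stop("non-square input batch");
  std::vector<ConvLayer> conv = parse_conv(model["conv"]);
  std::vector<FcLayer> fc = parse_fc(model["fc"]);
  ForwardState st;
  forward(conv, fc, X, H0, C0, N, st, false);
  arma::mat out = arma::conv_to<arma::mat>::from(st.logits);
  return wrap(out);
}
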