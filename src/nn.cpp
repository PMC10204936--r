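// Compiled CNN engine.
//
// One engine serves both classifier architectures:
//   * the spatial-temporal 3D CNN consumes [C, T, H, W] images (Block or
//     Source-by-Detector stacks) with kernels spanning time and space;
//   * the temporal 1D CNN is the degenerate case [1, T, R, 1] with a
//     [kt, 1, 1] kernel, i.e. the same temporal filters applied to every
//     measurement row independently, with no cross-row mixing before the
//     fully connected stage.
//
// Convolutions are evaluated as im2col + GEMM in single precision; training
// minimises softmax cross-entropy with Adam.  All randomness (weight
// initialisation, epoch shuffling, dropout) is driven by one std::mt19937
// seed, so a given seed reproduces parameters bit-for-bit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct ImDims { int C, T, H, W; int S() const { return T * H * W; } };

struct ConvSpec { int F, kt, kh, kw; };

// Input image block I is [C, S*B]; returns U [K x P*B] with
// K = C*kt*kh*kw, P = T'*H'*W' (valid convolution).
static void im2col(const fmat& I, const ImDims& d, const ConvSpec& k, int B,
                   fmat& U) {
  const int Tp = d.T - k.kt + 1, Hp = d.H - k.kh + 1, Wp = d.W - k.kw + 1;
  const int P = Tp * Hp * Wp, K = d.C * k.kt * k.kh * k.kw;
  U.set_size(K, P * B);
  for (int b = 0; b < B; ++b) {
    const int scol0 = d.S() * b;
    for (int wp = 0; wp < Wp; ++wp)
      for (int hp = 0; hp < Hp; ++hp)
        for (int tp = 0; tp < Tp; ++tp) {
          const int p = tp + Tp * (hp + Hp * wp);
          float* ucol = U.colptr(p + P * b);
          for (int dw = 0; dw < k.kw; ++dw)
            for (int dh = 0; dh < k.kh; ++dh)
              for (int dt = 0; dt < k.kt; ++dt) {
                const int s = (tp + dt) + d.T * ((hp + dh) + d.H * (wp + dw));
                const float* icol = I.colptr(scol0 + s);
                const int r0 = d.C * (dt + k.kt * (dh + k.kh * dw));
                for (int c = 0; c < d.C; ++c) ucol[r0 + c] = icol[c];
              }
        }
  }
}

// Scatter-add transpose of im2col: dU [K x P*B] -> dI [C, S*B].
static void col2im(const fmat& dU, const ImDims& d, const ConvSpec& k, int B,
                   fmat& dI) {
  const int Tp = d.T - k.kt + 1, Hp = d.H - k.kh + 1, Wp = d.W - k.kw + 1;
  const int P = Tp * Hp * Wp;
  dI.zeros(d.C, d.S() * B);
  for (int b = 0; b < B; ++b) {
    const int scol0 = d.S() * b;
    for (int wp = 0; wp < Wp; ++wp)
      for (int hp = 0; hp < Hp; ++hp)
        for (int tp = 0; tp < Tp; ++tp) {
          const int p = tp + Tp * (hp + Hp * wp);
          const float* ucol = dU.colptr(p + P * b);
          for (int dw = 0; dw < k.kw; ++dw)
            for (int dh = 0; dh < k.kh; ++dh)
              for (int dt = 0; dt < k.kt; ++dt) {
                const int s = (tp + dt) + d.T * ((hp + dh) + d.H * (wp + dw));
                float* icol = dI.colptr(scol0 + s);
                const int r0 = d.C * (dt + k.kt * (dh + k.kh * dw));
                for (int c = 0; c < d.C; ++c) icol[c] += ucol[r0 + c];
              }
        }
  }
}

struct Net {
  std::vector<ConvSpec> conv;
  std::vector<fmat> Wc; std::vector<fvec> bc;
  std::vector<fmat> Wf; std::vector<fvec> bf;  // hidden FC + output layer
  std::vector<ImDims> dims;                    // input dims of each conv layer
  ImDims d0;
  int n_classes = 3, flat_dim = 0;
};

static ImDims out_dims(const ImDims& d, const ConvSpec& k) {
  ImDims o;
  o.C = k.F; o.T = d.T - k.kt + 1; o.H = d.H - k.kh + 1; o.W = d.W - k.kw + 1;
  return o;
}

static Net build_net(const ImDims& d0, const std::vector<ConvSpec>& conv,
                     const std::vector<int>& fc, int n_classes,
                     std::mt19937& rng) {
  Net net; net.conv = conv; net.d0 = d0; net.n_classes = n_classes;
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  ImDims d = d0;
  for (const auto& k : conv) {
    if (k.kt > d.T || k.kh > d.H || k.kw > d.W)
      stop("convolution kernel larger than its input (%dx%dx%d vs %dx%dx%d)",
           k.kt, k.kh, k.kw, d.T, d.H, d.W);
    net.dims.push_back(d);
    const int K = d.C * k.kt * k.kh * k.kw;
    fmat W(k.F, K);
    const float sd = std::sqrt(2.0f / K);  // He initialisation for ReLU
    for (auto& w : W) w = sd * gauss(rng);
    net.Wc.push_back(W);
    net.bc.push_back(fvec(k.F, arma::fill::zeros));
    d = out_dims(d, k);
  }
  net.flat_dim = d.C * d.S();
  int in = net.flat_dim;
  for (int h : fc) {
    fmat W(h, in);
    const float sd = std::sqrt(2.0f / in);
    for (auto& w : W) w = sd * gauss(rng);
    net.Wf.push_back(W); net.bf.push_back(fvec(h, arma::fill::zeros));
    in = h;
  }
  fmat Wo(n_classes, in);
  const float sd = std::sqrt(1.0f / in);
  for (auto& w : Wo) w = sd * gauss(rng);
  net.Wf.push_back(Wo); net.bf.push_back(fvec(n_classes, arma::fill::zeros));
  return net;
}

// Forward through the conv stack for a batch image I0 [C0, S0*B].
// `Us`/`As` are caller-owned workspaces (im2col matrices and post-ReLU
// activations), reused across batches to avoid reallocating the large
// column matrices; pass nullptr when gradients are not needed.
static fmat conv_forward(const Net& net, const fmat& I0, int B,
                         std::vector<fmat>* Us, std::vector<fmat>* As) {
  const size_t nl = net.conv.size();
  if (Us) Us->resize(nl);
  if (As) As->resize(nl);
  fmat I = I0;
  fmat Uloc;
  for (size_t l = 0; l < nl; ++l) {
    fmat& U = Us ? (*Us)[l] : Uloc;
    im2col(I, net.dims[l], net.conv[l], B, U);
    fmat Y = net.Wc[l] * U;
    Y.each_col() += net.bc[l];
    Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (As) (*As)[l] = Y;
    I = std::move(Y);  // [F, P*B] is the next layer's [C, S*B]
  }
  return I;
}

// In-place ReLU gradient: zero entries of `grad` where the post-ReLU
// activation `act` is zero (inactive unit).
static void relu_backward(fmat& grad, const fmat& act) {
  float* g = grad.memptr();
  const float* a = act.memptr();
  const size_t n = grad.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (a[i] <= 0.0f) g[i] = 0.0f;
}

static double softmax_ce(fmat& O, const std::vector<int>& yb) {
  const int B = O.n_cols;
  double loss = 0.0;
  for (int j = 0; j < B; ++j) {
    fvec col = O.col(j);
    const float mx = col.max();
    col = arma::exp(col - mx);
    const float Z = arma::accu(col);
    col /= Z;
    loss -= std::log(std::max(static_cast<float>(col(yb[j])), 1e-12f));
    O.col(j) = col;
  }
  return loss / B;
}

struct Adam {
  std::vector<fmat> mW, vW; std::vector<fvec> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8; long t = 0;
  void init(const std::vector<fmat*>& Ws, const std::vector<fvec*>& bs) {
    for (auto* W : Ws) { mW.emplace_back(arma::size(*W), arma::fill::zeros);
                         vW.emplace_back(arma::size(*W), arma::fill::zeros); }
    for (auto* b : bs) { mb.emplace_back(arma::size(*b), arma::fill::zeros);
                         vb.emplace_back(arma::size(*b), arma::fill::zeros); }
  }
  void step(std::vector<fmat*>& Ws, std::vector<fvec*>& bs,
            const std::vector<fmat>& dWs, const std::vector<fvec>& dbs,
            double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < Ws.size(); ++i) {
      mW[i] = b1 * mW[i] + (1 - b1) * dWs[i];
      vW[i] = b2 * vW[i] + (1 - b2) * arma::square(dWs[i]);
      *Ws[i] -= lr * (mW[i] / c1) / (arma::sqrt(vW[i] / c2) + eps);
      mb[i] = b1 * mb[i] + (1 - b1) * dbs[i];
      vb[i] = b2 * vb[i] + (1 - b2) * arma::square(dbs[i]);
      *bs[i] -= lr * (mb[i] / c1) / (arma::sqrt(vb[i] / c2) + eps);
    }
  }
};

static std::vector<ConvSpec> conv_from_cfg(const List& cfg) {
  IntegerVector F = cfg["filters"], kt = cfg["kt"], kh = cfg["kh"],
                kw = cfg["kw"];
  std::vector<ConvSpec> conv;
  for (int i = 0; i < F.size(); ++i)
    conv.push_back({F[i], kt[i], kh[i], kw[i]});
  return conv;
}

// Copy example columns `take` (0-based) of the dataset into a batch block.
static void gather(const float* xf, int ex_len, const std::vector<int>& take,
                   int C, fmat& I0) {
  const int B = static_cast<int>(take.size());
  I0.set_size(C, (ex_len / C) * B);
  for (int b = 0; b < B; ++b)
    std::copy(xf + static_cast<size_t>(take[b]) * ex_len,
              xf + static_cast<size_t>(take[b] + 1) * ex_len,
              I0.memptr() + static_cast<size_t>(b) * ex_len);
}

// [[Rcpp::export]]
List cpp_train_cnn(const NumericVector& x, const IntegerVector& dim,
                   const IntegerVector& y, int n_classes, const List& cfg,
                   int seed) {
  const ImDims d0{dim[0], dim[1], dim[2], dim[3]};
  const int N = dim[4];
  if (N == 0) stop("empty training set");
  if (y.size() != N) stop("label / example count mismatch");
  const std::vector<ConvSpec> conv = conv_from_cfg(cfg);
  const IntegerVector fcv = cfg["fc_sizes"];
  const std::vector<int> fc(fcv.begin(), fcv.end());
  const double dropout = cfg["dropout"], lr = cfg["learning_rate"];
  const int epochs = cfg["n_epochs"];
  int batch = cfg["batch_size"];
  if (batch > N) batch = N;

  // one float copy of the dataset
  const int ex_len = d0.C * d0.S();
  std::vector<float> xf(x.begin(), x.end());

  std::mt19937 rng(static_cast<uint32_t>(seed));
  Net net = build_net(d0, conv, fc, n_classes, rng);

  std::vector<fmat*> Ws; std::vector<fvec*> bs;
  for (size_t l = 0; l < net.Wc.size(); ++l) { Ws.push_back(&net.Wc[l]); bs.push_back(&net.bc[l]); }
  for (size_t l = 0; l < net.Wf.size(); ++l) { Ws.push_back(&net.Wf[l]); bs.push_back(&net.bf[l]); }
  Adam opt; opt.init(Ws, bs);

  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const float keep = 1.0f - static_cast<float>(dropout);

  NumericVector loss_hist(epochs);
  fmat I0;
  std::vector<fmat> Us, As;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0; int n_seen = 0;
    for (int start = 0; start < N; start += batch) {
      const int B = std::min(batch, N - start);
      std::vector<int> take(perm.begin() + start, perm.begin() + start + B);
      std::vector<int> yb(B);
      for (int b = 0; b < B; ++b) yb[b] = y[take[b]];
      gather(xf.data(), ex_len, take, d0.C, I0);

      // forward: conv stack (Us/As declared outside the batch loop)
      fmat Ylast = conv_forward(net, I0, B, &Us, &As);
      fmat Z = arma::reshape(Ylast, net.flat_dim, B);

      // forward: FC stack with inverted dropout on hidden activations
      const size_t nh = net.Wf.size() - 1;
      std::vector<fmat> Af(nh), Mf(nh);
      fmat A = Z;
      for (size_t l = 0; l < nh; ++l) {
        fmat H = net.Wf[l] * A;
        H.each_col() += net.bf[l];
        H.transform([](float v) { return v > 0.0f ? v : 0.0f; });
        fmat M(arma::size(H));
        if (keep < 1.0f) {
          for (auto& mv : M) mv = (unif(rng) < keep) ? 1.0f / keep : 0.0f;
          H %= M;
        } else M.ones();
        Af[l] = H; Mf[l] = std::move(M);
        A = Af[l];
      }
      fmat O = net.Wf[nh] * A;
      O.each_col() += net.bf[nh];
      const double loss = softmax_ce(O, yb);  // O now holds probabilities
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ep_loss += loss * B; n_seen += B;

      // backward
      fmat dO = O;
      for (int b = 0; b < B; ++b) dO(yb[b], b) -= 1.0f;
      dO /= static_cast<float>(B);

      std::vector<fmat> dWs(Ws.size()); std::vector<fvec> dbs(bs.size());
      const size_t off = net.Wc.size();
      fmat dA = dO;
      for (int l = static_cast<int>(nh); l >= 0; --l) {
        const fmat& Ain = (l == 0) ? Z : Af[l - 1];
        dWs[off + l] = dA * Ain.t();
        dbs[off + l] = arma::sum(dA, 1);
        fmat dAin = net.Wf[l].t() * dA;
        if (l > 0) {
          dAin %= Mf[l - 1];
          relu_backward(dAin, Af[l - 1]);
        }
        dA = std::move(dAin);
      }
      // dA is dZ [flat_dim x B] -> conv stack
      const int nc = static_cast<int>(net.Wc.size());
      fmat dY = arma::reshape(dA, net.conv[nc - 1].F,
                              dA.n_elem / net.conv[nc - 1].F);
      for (int l = nc - 1; l >= 0; --l) {
        relu_backward(dY, As[l]);
        dWs[l] = dY * Us[l].t();
        dbs[l] = arma::sum(dY, 1);
        if (l > 0) {
          fmat dU = net.Wc[l].t() * dY;
          fmat dI;
          col2im(dU, net.dims[l], net.conv[l], B, dI);
          dY = std::move(dI);
        }
      }
      opt.step(Ws, bs, dWs, dbs, lr);
    }
    loss_hist[ep] = ep_loss / n_seen;
  }

  // export parameters as double matrices
  List conv_w(net.Wc.size()), conv_b(net.Wc.size());
  for (size_t l = 0; l < net.Wc.size(); ++l) {
    conv_w[l] = wrap(arma::conv_to<arma::mat>::from(net.Wc[l]));
    conv_b[l] = wrap(arma::conv_to<arma::vec>::from(net.bc[l]));
  }
  List fc_w(net.Wf.size()), fc_b(net.Wf.size());
  for (size_t l = 0; l < net.Wf.size(); ++l) {
    fc_w[l] = wrap(arma::conv_to<arma::mat>::from(net.Wf[l]));
    fc_b[l] = wrap(arma::conv_to<arma::vec>::from(net.bf[l]));
  }
  long n_par = 0;
  for (auto* W : Ws) n_par += W->n_elem;
  for (auto* b : bs) n_par += b->n_elem;
  return List::create(_["conv_w"] = conv_w, _["conv_b"] = conv_b,
                      _["fc_w"] = fc_w, _["fc_b"] = fc_b,
                      _["loss"] = loss_hist, _["n_params"] = n_par);
}

static Net net_from_params(const List& params, const ImDims& d0,
                           const List& cfg, int n_classes) {
  Net net; net.d0 = d0; net.n_classes = n_classes;
  net.conv = conv_from_cfg(cfg);
  List cw = params["conv_w"], cb = params["conv_b"];
  ImDims d = d0;
  for (size_t l = 0; l < net.conv.size(); ++l) {
    net.dims.push_back(d);
    net.Wc.push_back(arma::conv_to<fmat>::from(as<arma::mat>(cw[l])));
    net.bc.push_back(arma::conv_to<fvec>::from(as<arma::vec>(cb[l])));
    d = out_dims(d, net.conv[l]);
  }
  net.flat_dim = d.C * d.S();
  List fw = params["fc_w"], fb = params["fc_b"];
  for (int l = 0; l < fw.size(); ++l) {
    net.Wf.push_back(arma::conv_to<fmat>::from(as<arma::mat>(fw[l])));
    net.bf.push_back(arma::conv_to<fvec>::from(as<arma::vec>(fb[l])));
  }
  return net;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_cnn(const List& params, const NumericVector& x,
                              const IntegerVector& dim, const List& cfg,
                              int n_classes, int batch) {
  const ImDims d0{dim[0], dim[1], dim[2], dim[3]};
  const int N = dim[4];
  Net net = net_from_params(params, d0, cfg, n_classes);
  const int ex_len = d0.C * d0.S();
  std::vector<float> xf(x.begin(), x.end());
  NumericMatrix out(N, n_classes);
  fmat I0;
  for (int start = 0; start < N; start += batch) {
    const int B = std::min(batch, N - start);
    std::vector<int> take(B);
    for (int b = 0; b < B; ++b) take[b] = start + b;
    gather(xf.data(), ex_len, take, d0.C, I0);
    fmat Y = conv_forward(net, I0, B, nullptr, nullptr);
    fmat Z = arma::reshape(Y, net.flat_dim, B);
    fmat A = Z;
    const size_t nh = net.Wf.size() - 1;
    for (size_t l = 0; l < nh; ++l) {
      fmat Hh = net.Wf[l] * A;
      Hh.each_col() += net.bf[l];
      Hh.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      A = std::move(Hh);
    }
    fmat O = net.Wf[nh] * A;
    O.each_col() += net.bf[nh];
    std::vector<int> dummy(B, 0);
    softmax_ce(O, dummy);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < n_classes; ++k) out(start + b, k) = O(k, b);
  }
  return out;
}

// Conv-stack feature maps for the first layer stack (used to examine the
// positional invariance of the convolutional stage).
// [[Rcpp::export]]
NumericVector cpp_conv_features(const List& params, const NumericVector& x,
                                const IntegerVector& dim, const List& cfg,
                                int n_classes) {
  const ImDims d0{dim[0], dim[1], dim[2], dim[3]};
  const int N = dim[4];
  Net net = net_from_params(params, d0, cfg, n_classes);
  const int ex_len = d0.C * d0.S();
  std::vector<float> xf(x.begin(), x.end());
  std::vector<int> take(N);
  for (int i = 0; i < N; ++i) take[i] = i;
  fmat I0;
  gather(xf.data(), ex_len, take, d0.C, I0);
  fmat Y = conv_forward(net, I0, N, nullptr, nullptr);
  ImDims d = d0;
  for (const auto& k : net.conv) d = out_dims(d, k);
  NumericVector out(Y.n_elem);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(d.C, d.T, d.H, d.W, N);
  return out;
}
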