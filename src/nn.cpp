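// Minimal CPU convolutional-network engine used by the death classifier.
//
// Activations are carried as channel-major matrices A (C x H*W*N) with
// column index j = h + H*(w + W*n); convolutions are im2col + GEMM so the
// heavy lifting lands in BLAS.  The engine supports plain convolutions
// (optionally fused with ReLU), basic residual blocks (with optional 1x1
// strided projection shortcut), 3x3 max pooling, global average pooling and
// a final linear readout.  Backward passes support three modes:
//   - softmax cross-entropy loss gradients (training),
//   - per-sample class-score gradients (Grad-CAM / guided backprop),
//   - guided ReLU backprop (negative upstream gradients zeroed at ReLUs).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

struct ADims { int H, W, C, N; };

// col rows are ordered channel-fastest: row = c + C*(kr + k*kc), so each
// (kr, kc) tap copies a contiguous C-vector from A.
static mat im2col(const mat& A, const ADims& d, int k, int stride, int pad,
                  int& H2, int& W2) {
  H2 = (d.H + 2 * pad - k) / stride + 1;
  W2 = (d.W + 2 * pad - k) / stride + 1;
  mat col(d.C * k * k, (uword)H2 * W2 * d.N, arma::fill::zeros);
  const int C = d.C;
  const double* Ap = A.memptr();
  double* Cp = col.memptr();
  const uword colH = col.n_rows;
  for (int n = 0; n < d.N; ++n)
    for (int w2 = 0; w2 < W2; ++w2) {
      int w0 = w2 * stride - pad;
      for (int h2 = 0; h2 < H2; ++h2) {
        uword j = (uword)h2 + (uword)H2 * ((uword)w2 + (uword)W2 * n);
        int h0 = h2 * stride - pad;
        double* dst0 = Cp + j * colH;
        for (int kc = 0; kc < k; ++kc) {
          int w = w0 + kc;
          if (w < 0 || w >= d.W) continue;
          const double* acol =
            Ap + (uword)C * ((uword)d.H * ((uword)w + (uword)d.W * n));
          for (int kr = 0; kr < k; ++kr) {
            int h = h0 + kr;
            if (h < 0 || h >= d.H) continue;
            std::memcpy(dst0 + C * (kr + k * kc), acol + (uword)C * h,
                        C * sizeof(double));
          }
        }
      }
    }
  return col;
}

static mat col2im(const mat& dcol, const ADims& d, int k, int stride, int pad,
                  int H2, int W2) {
  mat dA(d.C, (uword)d.H * d.W * d.N, arma::fill::zeros);
  const int C = d.C;
  double* Ap = dA.memptr();
  const double* Cp = dcol.memptr();
  const uword colH = dcol.n_rows;
  for (int n = 0; n < d.N; ++n)
    for (int w2 = 0; w2 < W2; ++w2) {
      int w0 = w2 * stride - pad;
      for (int h2 = 0; h2 < H2; ++h2) {
        uword j = (uword)h2 + (uword)H2 * ((uword)w2 + (uword)W2 * n);
        int h0 = h2 * stride - pad;
        const double* src0 = Cp + j * colH;
        for (int kc = 0; kc < k; ++kc) {
          int w = w0 + kc;
          if (w < 0 || w >= d.W) continue;
          double* acol =
            Ap + (uword)C * ((uword)d.H * ((uword)w + (uword)d.W * n));
          for (int kr = 0; kr < k; ++kr) {
            int h = h0 + kr;
            if (h < 0 || h >= d.H) continue;
            const double* src = src0 + C * (kr + k * kc);
            double* dst = acol + (uword)C * h;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  return dA;
}

enum LayerType { L_CONV, L_MAXPOOL, L_RESBLOCK, L_GAP, L_FC };

struct LayerSpec {
  LayerType type;
  int k = 3, stride = 1, pad = 1;
  bool relu = false;
  // weight list indices (0-based; -1 = absent)
  int w = -1, b = -1, w1 = -1, b1 = -1, w2 = -1, b2 = -1, wp = -1, bp = -1;
};

struct LayerCache {
  ADims din, dout;
  mat in;                 // input activation
  mat out;                // output activation
  mat col, col1, col2, colp;  // im2col caches
  mat r1;                 // resblock: post-ReLU of first conv
  arma::umat argmax;      // maxpool winners (linear column index into input)
};

static std::vector<LayerSpec> parse_layers(const List& layers) {
  std::vector<LayerSpec> out;
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    std::string ty = as<std::string>(l["type"]);
    LayerSpec s;
    auto idx = [&](const char* nm) {
      return l.containsElementNamed(nm) ? as<int>(l[nm]) - 1 : -1;
    };
    if (ty == "conv") {
      s.type = L_CONV;
      s.k = as<int>(l["k"]); s.stride = as<int>(l["stride"]);
      s.pad = as<int>(l["pad"]); s.relu = as<bool>(l["relu"]);
      s.w = idx("w"); s.b = idx("b");
    } else if (ty == "maxpool") {
      s.type = L_MAXPOOL;
      s.k = as<int>(l["k"]); s.stride = as<int>(l["stride"]);
      s.pad = as<int>(l["pad"]);
    } else if (ty == "resblock") {
      s.type = L_RESBLOCK;
      s.stride = as<int>(l["stride"]);
      s.w1 = idx("w1"); s.b1 = idx("b1");
      s.w2 = idx("w2"); s.b2 = idx("b2");
      s.wp = idx("wp"); s.bp = idx("bp");
    } else if (ty == "gap") {
      s.type = L_GAP;
    } else if (ty == "fc") {
      s.type = L_FC; s.w = idx("w"); s.b = idx("b");
    } else {
      stop("unknown layer type: " + ty);
    }
    out.push_back(s);
  }
  return out;
}

static std::vector<mat> parse_weights(const List& weights) {
  std::vector<mat> out;
  for (int i = 0; i < weights.size(); ++i)
    out.push_back(as<mat>(weights[i]));
  return out;
}

// conv forward; weight Wm is (Cout x Cin*k*k), bias (Cout x 1)
static mat conv_fwd(const mat& A, const ADims& din, const mat& Wm,
                    const mat& bv, int k, int stride, int pad,
                    ADims& dout, mat& col) {
  int H2, W2;
  col = im2col(A, din, k, stride, pad, H2, W2);
  mat Y = Wm * col;
  Y.each_col() += vec(bv);
  dout = {H2, W2, (int)Wm.n_rows, din.N};
  return Y;
}

static mat maxpool_fwd(const mat& A, const ADims& din, int k, int stride,
                       int pad, ADims& dout, arma::umat& argmax) {
  int H2 = (din.H + 2 * pad - k) / stride + 1;
  int W2 = (din.W + 2 * pad - k) / stride + 1;
  dout = {H2, W2, din.C, din.N};
  mat Y(din.C, (uword)H2 * W2 * din.N);
  argmax.set_size(din.C, (uword)H2 * W2 * din.N);
  for (int n = 0; n < din.N; ++n)
    for (int w2 = 0; w2 < W2; ++w2)
      for (int h2 = 0; h2 < H2; ++h2) {
        uword j = (uword)h2 + (uword)H2 * ((uword)w2 + (uword)W2 * n);
        int h0 = h2 * stride - pad, w0 = w2 * stride - pad;
        for (int c = 0; c < din.C; ++c) {
          double best = -arma::datum::inf;
          uword bj = 0;
          for (int kc = 0; kc < k; ++kc) {
            int w = w0 + kc;
            if (w < 0 || w >= din.W) continue;
            for (int kr = 0; kr < k; ++kr) {
              int h = h0 + kr;
              if (h < 0 || h >= din.H) continue;
              uword jj = (uword)h + (uword)din.H * ((uword)w + (uword)din.W * n);
              double v = A(c, jj);
              if (v > best) { best = v; bj = jj; }
            }
          }
          Y(c, j) = best;
          argmax(c, j) = bj;
        }
      }
  return Y;
}

// relu backward mask; guided additionally zeroes negative upstream gradients
static void relu_bwd(mat& g, const mat& post, bool guided) {
  double* gp = g.memptr();
  const double* pp = post.memptr();
  const uword n = g.n_elem;
  if (guided) {
    for (uword i = 0; i < n; ++i)
      if (pp[i] <= 0 || gp[i] < 0) gp[i] = 0;
  } else {
    for (uword i = 0; i < n; ++i)
      if (pp[i] <= 0) gp[i] = 0;
  }
}

struct ForwardResult {
  std::vector<LayerCache> caches;
  mat logits;
};

static ForwardResult net_fwd(const std::vector<LayerSpec>& ls,
                             const std::vector<mat>& wt,
                             const mat& X, ADims d0) {
  ForwardResult fr;
  fr.caches.resize(ls.size());
  mat A = X;
  ADims d = d0;
  for (size_t li = 0; li < ls.size(); ++li) {
    const LayerSpec& s = ls[li];
    LayerCache& c = fr.caches[li];
    c.din = d;
    c.in = A;
    switch (s.type) {
    case L_CONV: {
      A = conv_fwd(A, d, wt[s.w], wt[s.b], s.k, s.stride, s.pad, c.dout, c.col);
      if (s.relu) A.clamp(0.0, arma::datum::inf);
      d = c.dout;
      break;
    }
    case L_MAXPOOL: {
      A = maxpool_fwd(A, d, s.k, s.stride, s.pad, c.dout, c.argmax);
      d = c.dout;
      break;
    }
    case L_RESBLOCK: {
      ADims d1, d2, dp;
      c.r1 = conv_fwd(A, d, wt[s.w1], wt[s.b1], 3, s.stride, 1, d1, c.col1);
      c.r1.clamp(0.0, arma::datum::inf);
      mat h2 = conv_fwd(c.r1, d1, wt[s.w2], wt[s.b2], 3, 1, 1, d2, c.col2);
      mat sc;
      if (s.wp >= 0) {
        sc = conv_fwd(A, d, wt[s.wp], wt[s.bp], 1, s.stride, 0, dp, c.colp);
      } else {
        sc = A;
      }
      A = h2 + sc;
      A.clamp(0.0, arma::datum::inf);
      c.dout = d2;
      d = d2;
      break;
    }
    case L_GAP: {
      uword hw = (uword)d.H * d.W;
      mat G(d.C, d.N);
      for (int n = 0; n < d.N; ++n)
        G.col(n) = arma::mean(A.cols((uword)n * hw, (uword)(n + 1) * hw - 1), 1);
      A = G;
      c.dout = {1, 1, d.C, d.N};
      d = c.dout;
      break;
    }
    case L_FC: {
      A = wt[s.w] * A;
      A.each_col() += vec(wt[s.b]);
      c.dout = {1, 1, (int)A.n_rows, d.N};
      d = c.dout;
      break;
    }
    }
    c.out = A;
  }
  fr.logits = A;
  return fr;
}

// [[Rcpp::export(name = ".nn_forward")]]
arma::mat nn_forward_cpp(List layers, List weights, arma::mat X,
                         int H, int W, int C, int N) {
  std::vector<LayerSpec> ls = parse_layers(layers);
  std::vector<mat> wt = parse_weights(weights);
  ADims d0 = {H, W, C, N};
  ForwardResult fr = net_fwd(ls, wt, X, d0);
  return fr.logits;
}

// Full forward + backward.
// mode = "loss": dlogits from mean softmax cross-entropy with labels y (0/1);
// mode = "class": dlogits = one-hot of `target` per sample (score gradient).
// Returns weight gradients, loss, logits, optionally input gradient and the
// activation/gradient pair at `cam_layer` (1-based; 0 = off).
// [[Rcpp::export(name = ".nn_backward")]]
List nn_backward_cpp(List layers, List weights, arma::mat X,
                     int H, int W, int C, int N,
                     IntegerVector y, std::string mode,
                     bool guided, int cam_layer, bool want_input_grad) {
  std::vector<LayerSpec> ls = parse_layers(layers);
  std::vector<mat> wt = parse_weights(weights);
  ADims d0 = {H, W, C, N};
  ForwardResult fr = net_fwd(ls, wt, X, d0);

  int L = (int)ls.size();
  std::vector<mat> grads(wt.size());
  for (size_t i = 0; i < wt.size(); ++i)
    grads[i] = mat(wt[i].n_rows, wt[i].n_cols, arma::fill::zeros);

  // softmax
  mat logits = fr.logits;
  mat P = logits;
  for (int n = 0; n < N; ++n) {
    vec z = logits.col(n);
    z -= z.max();
    vec e = arma::exp(z);
    P.col(n) = e / arma::accu(e);
  }

  double loss = NA_REAL;
  mat g;  // gradient wrt current layer output, flowing backward
  if (mode == "loss") {
    loss = 0.0;
    g = P;
    for (int n = 0; n < N; ++n) {
      int yi = y[n];
      loss -= std::log(std::max(P(yi, n), 1e-300));
      g(yi, n) -= 1.0;
    }
    loss /= N;
    g /= N;
  } else {
    // class-evidence gradient: contrast of the target logit against the
    // others (for two classes the softmax depends only on this difference)
    const double off = -1.0 / (logits.n_rows - 1);
    g = mat(logits.n_rows, N, arma::fill::value(off));
    for (int n = 0; n < N; ++n) g(y[n], n) = 1.0;
  }

  mat cam_act, cam_grad;
  ADims cam_dims = {0, 0, 0, 0};

  for (int i = L - 1; i >= 0; --i) {
    const LayerSpec& s = ls[i];
    LayerCache& c = fr.caches[i];
    if (i + 1 == cam_layer) {  // g is d(out of layer i) right now
      cam_act = c.out;
      cam_grad = g;
      cam_dims = c.dout;
    }
    switch (s.type) {
    case L_FC: {
      grads[s.w] += g * c.in.t();
      grads[s.b] += arma::sum(g, 1);
      g = wt[s.w].t() * g;
      break;
    }
    case L_GAP: {
      uword hw = (uword)c.din.H * c.din.W;
      mat dA(c.din.C, (uword)hw * c.din.N);
      for (int n = 0; n < c.din.N; ++n)
        dA.cols((uword)n * hw, (uword)(n + 1) * hw - 1) =
          arma::repmat(g.col(n) / (double)hw, 1, hw);
      g = dA;
      break;
    }
    case L_CONV: {
      if (s.relu) relu_bwd(g, c.out, guided);
      grads[s.w] += g * c.col.t();
      grads[s.b] += arma::sum(g, 1);
      mat dcol = wt[s.w].t() * g;
      g = col2im(dcol, c.din, s.k, s.stride, s.pad, c.dout.H, c.dout.W);
      break;
    }
    case L_MAXPOOL: {
      mat dA(c.din.C, (uword)c.din.H * c.din.W * c.din.N, arma::fill::zeros);
      for (uword j = 0; j < g.n_cols; ++j)
        for (uword cc = 0; cc < g.n_rows; ++cc)
          dA(cc, c.argmax(cc, j)) += g(cc, j);
      g = dA;
      break;
    }
    case L_RESBLOCK: {
      relu_bwd(g, c.out, guided);  // through the output ReLU
      // conv1 output dims (3x3, pad 1, stride s)
      int H1 = (c.din.H + 2 - 3) / s.stride + 1;
      int W1 = (c.din.W + 2 - 3) / s.stride + 1;
      ADims dr1 = {H1, W1, (int)c.r1.n_rows, c.din.N};
      grads[s.w2] += g * c.col2.t();
      grads[s.b2] += arma::sum(g, 1);
      mat dcol2 = wt[s.w2].t() * g;
      mat dr = col2im(dcol2, dr1, 3, 1, 1, c.dout.H, c.dout.W);
      relu_bwd(dr, c.r1, guided);
      grads[s.w1] += dr * c.col1.t();
      grads[s.b1] += arma::sum(dr, 1);
      mat dcol1 = wt[s.w1].t() * dr;
      mat dx = col2im(dcol1, c.din, 3, s.stride, 1, H1, W1);
      // shortcut branch
      if (s.wp >= 0) {
        grads[s.wp] += g * c.colp.t();
        grads[s.bp] += arma::sum(g, 1);
        mat dcolp = wt[s.wp].t() * g;
        dx += col2im(dcolp, c.din, 1, s.stride, 0, c.dout.H, c.dout.W);
      } else {
        dx += g;
      }
      g = dx;
      break;
    }
    }
  }

  List out = List::create(
    _["logits"] = logits, _["probs"] = P, _["loss"] = loss,
    _["grads"] = [&]() { List gl(grads.size());
      for (size_t i = 0; i < grads.size(); ++i) gl[i] = grads[i];
      return gl; }());
  if (want_input_grad) out["input_grad"] = g;
  if (cam_layer > 0) {
    out["cam_act"] = cam_act;
    out["cam_grad"] = cam_grad;
    out["cam_dims"] = IntegerVector::create(cam_dims.H, cam_dims.W,
                                            cam_dims.C, cam_dims.N);
  }
  return out;
}
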