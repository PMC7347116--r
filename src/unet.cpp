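// Compact CPU U-Net: 3x3 same-padding convolutions + ReLU, 2x2 max pooling,
// nearest-neighbor upsampling followed by a 3x3 convolution, skip
// concatenation, and a 1x1 sigmoid head. Forward, full backpropagation and
// Adam updates are implemented here in single precision; convolutions go
// through im2col + BLAS gemm.
//
// Layer order for depth D (all 3x3 except the final 1x1), L = 5D + 3:
//   enc_0_a, enc_0_b, ..., enc_{D-1}_a, enc_{D-1}_b,
//   bottleneck_a, bottleneck_b,
//   up_{D-1}, dec_{D-1}_a, dec_{D-1}_b, ..., up_0, dec_0_a, dec_0_b,
//   head (1x1)
// Weight matrices are (C_out x C_in*9) (head: 1 x C_in); biases length C_out.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerMatrix;
using Rcpp::stop;

namespace {

struct Layer {
  fmat W;
  fvec b;
  fmat mW, vW;  // Adam state
  fvec mb, vb;
  fmat dW;      // accumulated gradient
  fvec db;
};

std::vector<Layer> load_params(const List& params) {
  std::vector<Layer> layers(params.size());
  for (int i = 0; i < params.size(); ++i) {
    List li = params[i];
    NumericMatrix W = li["W"];
    NumericVector b = li["b"];
    layers[i].W = conv_to<fmat>::from(
        mat(W.begin(), W.nrow(), W.ncol(), false));
    layers[i].b = conv_to<fvec>::from(vec(b.begin(), b.size(), false));
    layers[i].mW.zeros(W.nrow(), W.ncol());
    layers[i].vW.zeros(W.nrow(), W.ncol());
    layers[i].mb.zeros(b.size());
    layers[i].vb.zeros(b.size());
    layers[i].dW.zeros(W.nrow(), W.ncol());
    layers[i].db.zeros(b.size());
  }
  return layers;
}

List export_params(const std::vector<Layer>& layers) {
  List out(layers.size());
  for (size_t i = 0; i < layers.size(); ++i) {
    NumericMatrix W(layers[i].W.n_rows, layers[i].W.n_cols);
    std::copy(layers[i].W.begin(), layers[i].W.end(), W.begin());
    NumericVector b(layers[i].b.n_elem);
    std::copy(layers[i].b.begin(), layers[i].b.end(), b.begin());
    out[i] = List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b);
  }
  return out;
}

// im2col for 3x3 kernels with zero padding 1: (H x W x C) -> (C*9) x (H*W).
// Column j corresponds to output pixel (r, c) with j = r + c*H.
fmat im2col3(const fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat cols(C * 9, H * W, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        const int row = ch * 9 + (dr + 1) * 3 + (dc + 1);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc;
          if (sc < 0 || sc >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
          const float* src = x.slice_colptr(ch, sc);
          for (int r = r0; r <= r1; ++r)
            cols(row, r + c * H) = src[r + dr];
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col3. dcolsT is (H*W) x (C*9) (transposed layout so the
// backward gemm writes it directly).
fcube col2im3(const fmat& dcolsT, int H, int W, int C) {
  fcube dx(H, W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        const int col = ch * 9 + (dr + 1) * 3 + (dc + 1);
        const float* src = dcolsT.colptr(col);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc;
          if (sc < 0 || sc >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
          float* dst = dx.slice_colptr(ch, sc);
          for (int r = r0; r <= r1; ++r)
            dst[r + dr] += src[r + c * H];
        }
      }
    }
  }
  return dx;
}

struct ConvCache {
  fmat cols;   // im2col of the input, (C_in*9) x (H*W)
  fmat outT;   // post-activation output, (H*W) x C_out (cube memory layout)
  int H = 0, W = 0;
};

// 3x3 conv + optional ReLU. outT columns are exactly the cube slices.
fcube conv3_fwd(const fcube& x, const Layer& L, ConvCache& cc, bool relu) {
  const int H = x.n_rows, Wd = x.n_cols;
  cc.H = H; cc.W = Wd;
  cc.cols = im2col3(x);
  fmat outT = cc.cols.t() * L.W.t();  // (H*W) x C_out
  outT.each_row() += L.b.t();
  if (relu) outT.clamp(0.0f, std::numeric_limits<float>::max());
  cc.outT = outT;
  return fcube(outT.memptr(), H, Wd, L.W.n_rows);
}

// Backward through conv3 (+ReLU). dy is the gradient wrt the layer output;
// accumulates into L.dW/L.db; returns gradient wrt the layer input.
fcube conv3_bwd(const fcube& dy, Layer& L, const ConvCache& cc, bool relu,
                bool need_dx) {
  const int H = cc.H, Wd = cc.W, Cin9 = L.W.n_cols;
  fmat dYt(const_cast<float*>(dy.memptr()), H * Wd, dy.n_slices, false);
  fmat dYr;
  const fmat* dptr = &dYt;
  if (relu) {
    dYr = dYt % conv_to<fmat>::from(cc.outT > 0.0f);
    dptr = &dYr;
  }
  L.dW += (cc.cols * (*dptr)).t();          // C_out x C_in*9
  L.db += sum(*dptr, 0).t();
  if (!need_dx) return fcube();
  fmat dcolsT = (*dptr) * L.W;              // (H*W) x C_in*9
  return col2im3(dcolsT, H, Wd, Cin9 / 9);
}

fcube maxpool2_fwd(const fcube& x, ucube& idx) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fcube out(H / 2, W / 2, C);
  idx.set_size(H / 2, W / 2, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W / 2; ++c)
      for (int r = 0; r < H / 2; ++r) {
        float best = x(2 * r, 2 * c, ch);
        unsigned bi = 0;
        const int dr[4] = {0, 1, 0, 1}, dc[4] = {0, 0, 1, 1};
        for (unsigned k = 1; k < 4; ++k) {
          float v = x(2 * r + dr[k], 2 * c + dc[k], ch);
          if (v > best) { best = v; bi = k; }
        }
        out(r, c, ch) = best;
        idx(r, c, ch) = bi;
      }
  return out;
}

fcube maxpool2_bwd(const fcube& dy, const ucube& idx, int H, int W) {
  const int C = dy.n_slices;
  fcube dx(H, W, C, fill::zeros);
  const int dr[4] = {0, 1, 0, 1}, dc[4] = {0, 0, 1, 1};
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W / 2; ++c)
      for (int r = 0; r < H / 2; ++r) {
        unsigned k = idx(r, c, ch);
        dx(2 * r + dr[k], 2 * c + dc[k], ch) += dy(r, c, ch);
      }
  return dx;
}

fcube upsample2_fwd(const fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fcube out(2 * H, 2 * W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const float v = x(r, c, ch);
        out(2 * r, 2 * c, ch) = v;
        out(2 * r + 1, 2 * c, ch) = v;
        out(2 * r, 2 * c + 1, ch) = v;
        out(2 * r + 1, 2 * c + 1, ch) = v;
      }
  return out;
}

fcube upsample2_bwd(const fcube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  fcube dx(H, W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        dx(r, c, ch) = dy(2 * r, 2 * c, ch) + dy(2 * r + 1, 2 * c, ch) +
                       dy(2 * r, 2 * c + 1, ch) + dy(2 * r + 1, 2 * c + 1, ch);
  return dx;
}

struct NetCache {
  std::vector<ConvCache> conv;        // one per conv layer (head included)
  std::vector<ucube> pool_idx;        // per encoder level
  std::vector<int> pool_H, pool_W;    // input dims of each pool
  std::vector<fcube> skips;           // encoder skip outputs
  fmat headX;                         // (H*W) x C input to 1x1 head
  fvec p;                             // sigmoid output, length H*W
  int H = 0, W = 0;
};

// Full forward pass; returns sigmoid probabilities as a cube-of-one-slice.
fvec forward(const std::vector<Layer>& L, const fmat& img, int depth,
             NetCache& nc) {
  const int D = depth;
  nc.conv.assign(L.size(), ConvCache());
  nc.pool_idx.assign(D, ucube());
  nc.pool_H.assign(D, 0);
  nc.pool_W.assign(D, 0);
  nc.skips.assign(D, fcube());
  nc.H = img.n_rows; nc.W = img.n_cols;

  fcube cur(img.n_rows, img.n_cols, 1);
  cur.slice(0) = img;
  for (int i = 0; i < D; ++i) {
    cur = conv3_fwd(cur, L[2 * i], nc.conv[2 * i], true);
    cur = conv3_fwd(cur, L[2 * i + 1], nc.conv[2 * i + 1], true);
    nc.skips[i] = cur;
    nc.pool_H[i] = cur.n_rows; nc.pool_W[i] = cur.n_cols;
    cur = maxpool2_fwd(cur, nc.pool_idx[i]);
  }
  cur = conv3_fwd(cur, L[2 * D], nc.conv[2 * D], true);
  cur = conv3_fwd(cur, L[2 * D + 1], nc.conv[2 * D + 1], true);
  for (int i = D - 1; i >= 0; --i) {
    const int base = 2 * D + 2 + 3 * (D - 1 - i);
    fcube up = upsample2_fwd(cur);
    up = conv3_fwd(up, L[base], nc.conv[base], true);
    fcube cat = join_slices(nc.skips[i], up);
    cur = conv3_fwd(cat, L[base + 1], nc.conv[base + 1], true);
    cur = conv3_fwd(cur, L[base + 2], nc.conv[base + 2], true);
  }
  const int head = 5 * D + 2;
  nc.headX = fmat(cur.memptr(), cur.n_rows * cur.n_cols, cur.n_slices);
  fvec z = nc.headX * L[head].W.t();
  z += L[head].b(0);
  nc.p = 1.0f / (1.0f + exp(-z));
  return nc.p;
}

// Backward from BCE-with-sigmoid gradient dz (length H*W), accumulating
// parameter gradients.
void backward(std::vector<Layer>& L, const fvec& dz, int depth, NetCache& nc) {
  const int D = depth;
  const int head = 5 * D + 2;
  L[head].dW += (nc.headX.t() * dz).t();
  L[head].db(0) += accu(dz);
  fmat dXm = dz * L[head].W;  // (H*W) x C
  int h = nc.H, w = nc.W;
  fcube dcur(dXm.memptr(), h, w, dXm.n_cols);

  std::vector<fcube> dskip(D);
  for (int i = 0; i <= D - 1; ++i) {
    const int base = 2 * D + 2 + 3 * (D - 1 - i);
    dcur = conv3_bwd(dcur, L[base + 2], nc.conv[base + 2], true, true);
    fcube dcat = conv3_bwd(dcur, L[base + 1], nc.conv[base + 1], true, true);
    const int cs = nc.skips[i].n_slices;
    dskip[i] = dcat.slices(0, cs - 1);
    fcube dup = dcat.slices(cs, dcat.n_slices - 1);
    dup = conv3_bwd(dup, L[base], nc.conv[base], true, true);
    dcur = upsample2_bwd(dup);
  }
  dcur = conv3_bwd(dcur, L[2 * D + 1], nc.conv[2 * D + 1], true, true);
  dcur = conv3_bwd(dcur, L[2 * D], nc.conv[2 * D], true, true);
  for (int i = D - 1; i >= 0; --i) {
    dcur = maxpool2_bwd(dcur, nc.pool_idx[i], nc.pool_H[i], nc.pool_W[i]);
    dcur += dskip[i];
    dcur = conv3_bwd(dcur, L[2 * i + 1], nc.conv[2 * i + 1], true, true);
    dcur = conv3_bwd(dcur, L[2 * i], nc.conv[2 * i], true, i > 0);
  }
}

double bce_loss(const fvec& p, const fmat& y) {
  const float eps = 1e-7f;
  fvec yv(const_cast<float*>(y.memptr()), y.n_elem, false);
  fvec pc = clamp(p, eps, 1.0f - eps);
  return -mean(conv_to<vec>::from(yv % log(pc) + (1.0f - yv) % log(1.0f - pc)));
}

void adam_step(std::vector<Layer>& L, double lr, double beta1, double beta2,
               double eps, long t, int batch) {
  const float b1 = beta1, b2 = beta2;
  const float corr1 = 1.0f - std::pow(b1, (float)t);
  const float corr2 = 1.0f - std::pow(b2, (float)t);
  const float alpha = lr * std::sqrt(corr2) / corr1;
  for (auto& layer : L) {
    fmat g = layer.dW / (float)batch;
    fvec gb = layer.db / (float)batch;
    layer.mW = b1 * layer.mW + (1 - b1) * g;
    layer.vW = b2 * layer.vW + (1 - b2) * square(g);
    layer.mb = b1 * layer.mb + (1 - b1) * gb;
    layer.vb = b2 * layer.vb + (1 - b2) * square(gb);
    layer.W -= alpha * layer.mW / (sqrt(layer.vW) + (float)eps);
    layer.b -= alpha * layer.mb / (sqrt(layer.vb) + (float)eps);
    layer.dW.zeros();
    layer.db.zeros();
  }
}

fmat as_fmat(const NumericMatrix& x) {
  mat m(const_cast<double*>(x.begin()), x.nrow(), x.ncol(), false);
  return conv_to<fmat>::from(m);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_unet_predict(const List& params, const NumericMatrix& x,
                               int depth) {
  std::vector<Layer> L = load_params(params);
  NetCache nc;
  fvec p = forward(L, as_fmat(x), depth, nc);
  NumericMatrix out(x.nrow(), x.ncol());
  std::copy(p.begin(), p.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
double cpp_unet_loss(const List& params, const NumericMatrix& x,
                     const NumericMatrix& y, int depth) {
  std::vector<Layer> L = load_params(params);
  NetCache nc;
  fvec p = forward(L, as_fmat(x), depth, nc);
  return bce_loss(p, as_fmat(y));
}

// Analytic parameter gradients for one sample (testing hook).
// [[Rcpp::export]]
List cpp_unet_gradients(const List& params, const NumericMatrix& x,
                        const NumericMatrix& y, int depth) {
  std::vector<Layer> L = load_params(params);
  NetCache nc;
  fvec p = forward(L, as_fmat(x), depth, nc);
  fmat yf = as_fmat(y);
  fvec yv(yf.memptr(), yf.n_elem, false);
  fvec dz = (p - yv) / (float)p.n_elem;
  backward(L, dz, depth, nc);
  List out(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    NumericMatrix dW(L[i].dW.n_rows, L[i].dW.n_cols);
    std::copy(L[i].dW.begin(), L[i].dW.end(), dW.begin());
    NumericVector db(L[i].db.n_elem);
    std::copy(L[i].db.begin(), L[i].db.end(), db.begin());
    out[i] = List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
  }
  return out;
}

// Multi-epoch training. X, Y: lists of H x W matrices (inputs in [0,1],
// targets binary). ord: epochs x n matrix of 1-based sample orders (one
// shuffled row per epoch). Returns per-epoch parameter snapshots and mean
// losses. Epoch N starts from the parameters (and optimizer state) left by
// epoch N-1.
// [[Rcpp::export]]
List cpp_unet_train(const List& params, const List& X, const List& Y,
                    const IntegerMatrix& ord, int depth, double lr,
                    double beta1, double beta2, double eps, int batch_size) {
  const int epochs = ord.nrow(), n = ord.ncol();
  if (n != X.size() || n != Y.size()) stop("order/sample size mismatch");
  std::vector<Layer> L = load_params(params);
  std::vector<fmat> Xs(n), Ys(n);
  for (int i = 0; i < n; ++i) {
    Xs[i] = as_fmat(X[i]);
    Ys[i] = as_fmat(Y[i]);
  }
  List checkpoints(epochs);
  NumericVector losses(epochs);
  long t = 0;
  NetCache nc;
  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0.0;
    int in_batch = 0;
    for (int k = 0; k < n; ++k) {
      const int i = ord(e, k) - 1;
      if (i < 0 || i >= n) stop("order index out of range");
      fvec p = forward(L, Xs[i], depth, nc);
      loss_sum += bce_loss(p, Ys[i]);
      fvec yv(Ys[i].memptr(), Ys[i].n_elem, false);
      fvec dz = (p - yv) / (float)p.n_elem;
      backward(L, dz, depth, nc);
      if (++in_batch == batch_size || k == n - 1) {
        adam_step(L, lr, beta1, beta2, eps, ++t, in_batch);
        in_batch = 0;
      }
      if ((k & 15) == 0) Rcpp::checkUserInterrupt();
    }
    losses[e] = loss_sum / n;
    checkpoints[e] = export_params(L);
  }
  return List::create(Rcpp::Named("checkpoints") = checkpoints,
                      Rcpp::Named("losses") = losses);
}
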