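// Compute kernels for the 3-D segmentation network and label-map geometry.
// Convolutions use im2col + BLAS GEMM; layouts are column-major [D,H,W,C].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Mirror (reflect-101) index for 'same' convolutions: out-of-range
// neighbors reflect about the boundary, so patch borders see plausible
// context instead of an artificial dark rim.
static inline int reflect_idx(int v, int n) {
  if (v < 0) return -v;
  if (v >= n) return 2 * n - 2 - v;
  return v;
}

// im2col for a 3x3x3 'same' convolution with mirror padding.
// Column index = o * Cin + c, where o = i + 3*j + 9*k (offsets in {0,1,2},
// i fastest) and c is the input channel.
static arma::mat im2col3(const double* x, int D, int H, int W, int C) {
  const int N = D * H * W;
  arma::mat M(N, 27 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * N;
    for (int k = 0; k < 3; ++k) {
      int dz = k - 1;
      for (int j = 0; j < 3; ++j) {
        int dy = j - 1;
        for (int i = 0; i < 3; ++i) {
          int dx = i - 1;
          int o = i + 3 * j + 9 * k;
          double* col = M.colptr(o * C + c);
          for (int w = 0; w < W; ++w) {
            int sw = reflect_idx(w + dz, W);
            for (int h = 0; h < H; ++h) {
              int sh = reflect_idx(h + dy, H);
              const double* src = xc + (size_t)(sw * H + sh) * D;
              double* dst = col + (size_t)(w * H + h) * D;
              // interior run is a contiguous shifted copy
              int d0 = std::max(0, -dx), d1 = std::min(D, D - dx);
              for (int d = 0; d < d0; ++d) dst[d] = src[reflect_idx(d + dx, D)];
              std::copy(src + d0 + dx, src + d1 + dx, dst + d0);
              for (int d = d1; d < D; ++d) dst[d] = src[reflect_idx(d + dx, D)];
            }
          }
        }
      }
    }
  }
  return M;
}

static void col2im3(const arma::mat& gM, double* gx, int D, int H, int W, int C) {
  const int N = D * H * W;
  std::fill(gx, gx + (size_t)N * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * N;
    for (int k = 0; k < 3; ++k) {
      int dz = k - 1;
      for (int j = 0; j < 3; ++j) {
        int dy = j - 1;
        for (int i = 0; i < 3; ++i) {
          int dx = i - 1;
          int o = i + 3 * j + 9 * k;
          const double* col = gM.colptr(o * C + c);
          for (int w = 0; w < W; ++w) {
            int sw = reflect_idx(w + dz, W);
            for (int h = 0; h < H; ++h) {
              int sh = reflect_idx(h + dy, H);
              const double* src = col + (size_t)(w * H + h) * D;
              double* dst = xc + (size_t)(sw * H + sh) * D;
              int d0 = std::max(0, -dx), d1 = std::min(D, D - dx);
              for (int d = 0; d < d0; ++d) dst[reflect_idx(d + dx, D)] += src[d];
              for (int d = d0; d < d1; ++d) dst[d + dx] += src[d];
              for (int d = d1; d < D; ++d) dst[reflect_idx(d + dx, D)] += src[d];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, const arma::mat& W_,
                             const arma::vec& b) {
  IntegerVector dm = x.attr("dim");
  int D = dm[0], H = dm[1], W = dm[2], C = dm[3];
  if ((int)W_.n_rows != 27 * C) stop("weight/input channel mismatch");
  arma::mat M = im2col3(x.begin(), D, H, W, C);
  arma::mat Y = M * W_;
  Y.each_row() += b.t();
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(D, H, W, (int)W_.n_cols);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, const arma::mat& W_, NumericVector gy) {
  IntegerVector dm = x.attr("dim");
  int D = dm[0], H = dm[1], W = dm[2], C = dm[3];
  int N = D * H * W;
  int Cout = (int)W_.n_cols;
  arma::mat M = im2col3(x.begin(), D, H, W, C);
  arma::mat gY(gy.begin(), N, Cout, false);
  arma::mat gW = M.t() * gY;
  arma::vec gb = arma::sum(gY, 0).t();
  arma::mat gM = gY * W_.t();
  NumericVector gx(x.size());
  col2im3(gM, gx.begin(), D, H, W, C);
  gx.attr("dim") = dm;
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2x2 max pooling (stride 2). Returns pooled values and 1-based argmax
// linear indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  int D = dm[0], H = dm[1], W = dm[2], C = dm[3];
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Do * Ho * Wo * C);
  IntegerVector arg(y.size());
  const double* px = x.begin();
  size_t q = 0;
  for (int c = 0; c < C; ++c) {
    size_t oc = (size_t)c * D * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t idx = oc + (size_t)(2 * w + dz) * H * D +
                             (size_t)(2 * h + dy) * D + (2 * d + dx);
                if (px[idx] > best) { best = px[idx]; bidx = idx; }
              }
          y[q] = best;
          arg[q] = (int)(bidx + 1);
          ++q;
        }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(IntegerVector arg, NumericVector gy,
                                IntegerVector din) {
  size_t n = (size_t)din[0] * din[1] * din[2] * din[3];
  NumericVector gx(n);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[arg[i] - 1] += gy[i];
  gx.attr("dim") = din;
  return gx;
}

// Connected components of a binary mask, 6- or 26-connectivity, BFS.
// Components are labeled 1,2,... in order of their smallest linear index,
// which makes the "keep the component containing the smallest index"
// tie-break deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dm,
                                   int connectivity) {
  int D = dm[0], H = dm[1], W = dm[2];
  size_t n = (size_t)D * H * W;
  IntegerVector comp(n);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dx, dy, dz});
      }
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || comp[s]) continue;
    ++cur;
    comp[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int d = (int)(v % D), rest = (int)(v / D);
      int h = rest % H, w = rest / H;
      for (auto& o : nb) {
        int dd = d + o[0], hh = h + o[1], ww = w + o[2];
        if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
          continue;
        size_t u = (size_t)(ww * H + hh) * D + dd;
        if (mask[u] && !comp[u]) { comp[u] = cur; stack.push_back(u); }
      }
    }
  }
  comp.attr("dim") = dm;
  return comp;
}

// Resample a 3-D volume onto a new grid. Voxel centers are mapped through
// physical space: in_coord = (out_index + 0.5) * scale - 0.5 per axis,
// where scale = out_spacing / in_spacing. method: 0 nearest, 1 trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector dout,
                             NumericVector scale, int method) {
  IntegerVector dm = x.attr("dim");
  int D = dm[0], H = dm[1], W = dm[2];
  int Do = dout[0], Ho = dout[1], Wo = dout[2];
  NumericVector y((size_t)Do * Ho * Wo);
  const double* px = x.begin();
  auto clampi = [](int v, int lo, int hi) { return std::min(std::max(v, lo), hi); };
  size_t q = 0;
  for (int w = 0; w < Wo; ++w) {
    double sw = (w + 0.5) * scale[2] - 0.5;
    for (int h = 0; h < Ho; ++h) {
      double sh = (h + 0.5) * scale[1] - 0.5;
      for (int d = 0; d < Do; ++d) {
        double sd = (d + 0.5) * scale[0] - 0.5;
        if (method == 0) {
          int id = clampi((int)std::lround(sd), 0, D - 1);
          int ih = clampi((int)std::lround(sh), 0, H - 1);
          int iw = clampi((int)std::lround(sw), 0, W - 1);
          y[q++] = px[(size_t)(iw * H + ih) * D + id];
        } else {
          int d0 = (int)std::floor(sd), h0 = (int)std::floor(sh),
              w0 = (int)std::floor(sw);
          double fd = sd - d0, fh = sh - h0, fw = sw - w0;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int id = clampi(d0 + dx, 0, D - 1);
                int ih = clampi(h0 + dy, 0, H - 1);
                int iw = clampi(w0 + dz, 0, W - 1);
                double wt = (dx ? fd : 1 - fd) * (dy ? fh : 1 - fh) *
                            (dz ? fw : 1 - fw);
                acc += wt * px[(size_t)(iw * H + ih) * D + id];
              }
          y[q++] = acc;
        }
      }
    }
  }
  y.attr("dim") = dout;
  return y;
}
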