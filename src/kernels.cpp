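// Low-level numeric kernels for the segmentation network.
// Layout conventions (match R): images/feature maps are [h, w, c] arrays
// (row = y, col = x, slice = channel); convolution weights are flattened to a
// [k*k*c_in, c_out] matrix with row index dy + k*dx + k*k*c (0-based), i.e.
// the column-major flattening of an R array of dim [k, k, c_in].
// All convolutions are stride 1, zero-padded "same", odd k.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace arma;

static void im2col_same(const cube& x, const int k, mat& out) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int pad = (k - 1) / 2;
  out.set_size(h * w, k * k * c);
  for (int ch = 0; ch < c; ++ch) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = dy + k * dx + k * k * ch;
        mat cv(out.colptr(col), h, w, false, true);
        cv.zeros();
        const int oy = dy - pad, ox = dx - pad;
        const int y0 = std::max(0, -oy), y1 = std::min(h, h - oy);
        const int x0 = std::max(0, -ox), x1 = std::min(w, w - ox);
        if (y1 > y0 && x1 > x0)
          cv.submat(y0, x0, y1 - 1, x1 - 1) =
            x.slice(ch).submat(y0 + oy, x0 + ox, y1 - 1 + oy, x1 - 1 + ox);
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k) {
  mat cols;
  im2col_same(x, k, cols);
  mat Y = cols * W;
  Y.each_row() += b.t();
  cube out(Y.memptr(), x.n_rows, x.n_cols, W.n_cols);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gy, int k) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = W.n_cols;
  const int pad = (k - 1) / 2;
  const mat gym(const_cast<double*>(gy.memptr()), h * w, cout, false, true);
  mat cols;
  im2col_same(x, k, cols);
  mat gW = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  mat gcols = gym * W.t(); // h*w x k*k*cin
  cube gx(h, w, cin, fill::zeros);
  for (int ch = 0; ch < cin; ++ch) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = dy + k * dx + k * k * ch;
        const mat cv(gcols.colptr(col), h, w, false, true);
        const int oy = dy - pad, ox = dx - pad;
        const int y0 = std::max(0, -oy), y1 = std::min(h, h - oy);
        const int x0 = std::max(0, -ox), x1 = std::min(w, w - ox);
        if (y1 > y0 && x1 > x0)
          gx.slice(ch).submat(y0 + oy, x0 + ox, y1 - 1 + oy, x1 - 1 + ox) +=
            cv.submat(y0, x0, y1 - 1, x1 - 1);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2 mean pooling, factor fixed at 2; spatial dims must be even.
// [[Rcpp::export]]
arma::cube cpp_avgpool2_fwd(const arma::cube& x) {
  const int h = x.n_rows / 2, w = x.n_cols / 2, c = x.n_slices;
  cube out(h, w, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        out(i, j, ch) = 0.25 * (x(2 * i, 2 * j, ch) + x(2 * i + 1, 2 * j, ch) +
                                x(2 * i, 2 * j + 1, ch) + x(2 * i + 1, 2 * j + 1, ch));
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bwd(const arma::cube& g, int h, int w) {
  const int c = g.n_slices;
  cube gx(h, w, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        gx(i, j, ch) = 0.25 * g(i / 2, j / 2, ch);
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upnn_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  cube out(2 * h, 2 * w, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < 2 * w; ++j)
      for (int i = 0; i < 2 * h; ++i)
        out(i, j, ch) = x(i / 2, j / 2, ch);
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upnn_bwd(const arma::cube& g) {
  const int h = g.n_rows / 2, w = g.n_cols / 2, c = g.n_slices;
  cube gx(h, w, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < 2 * w; ++j)
      for (int i = 0; i < 2 * h; ++i)
        gx(i / 2, j / 2, ch) += g(i, j, ch);
  return gx;
}

// Factor-2 bilinear interpolation with half-pixel centers (no corner
// alignment): source coordinate of output o is (o + 0.5)/2 - 0.5, clamped.
static void bilin_axis(int n_out, int n_in, ivec& i0, ivec& i1, vec& w0) {
  i0.set_size(n_out);
  i1.set_size(n_out);
  w0.set_size(n_out);
  for (int o = 0; o < n_out; ++o) {
    double p = 0.5 * o - 0.25;
    int f = (int)std::floor(p);
    double t = p - f;
    int a = std::min(std::max(f, 0), n_in - 1);
    int b = std::min(std::max(f + 1, 0), n_in - 1);
    i0[o] = a;
    i1[o] = b;
    w0[o] = 1.0 - t;
  }
}

// [[Rcpp::export]]
arma::cube cpp_upbl_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int H = 2 * h, W = 2 * w;
  ivec y0, y1, x0, x1;
  vec wy, wx;
  bilin_axis(H, h, y0, y1, wy);
  bilin_axis(W, w, x0, x1, wx);
  cube out(H, W, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, ch) =
          wy[i] * (wx[j] * x(y0[i], x0[j], ch) + (1 - wx[j]) * x(y0[i], x1[j], ch)) +
          (1 - wy[i]) * (wx[j] * x(y1[i], x0[j], ch) + (1 - wx[j]) * x(y1[i], x1[j], ch));
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upbl_bwd(const arma::cube& g) {
  const int H = g.n_rows, W = g.n_cols, c = g.n_slices;
  const int h = H / 2, w = W / 2;
  ivec y0, y1, x0, x1;
  vec wy, wx;
  bilin_axis(H, h, y0, y1, wy);
  bilin_axis(W, w, x0, x1, wx);
  cube gx(h, w, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double gv = g(i, j, ch);
        gx(y0[i], x0[j], ch) += wy[i] * wx[j] * gv;
        gx(y0[i], x1[j], ch) += wy[i] * (1 - wx[j]) * gv;
        gx(y1[i], x0[j], ch) += (1 - wy[i]) * wx[j] * gv;
        gx(y1[i], x1[j], ch) += (1 - wy[i]) * (1 - wx[j]) * gv;
      }
  return gx;
}

// 8-connected component labelling of a binary mask (BFS flood fill).
// Returns an integer matrix of labels, 0 = background, components 1..n.
// [[Rcpp::export]]
arma::imat cpp_label8(const arma::imat& mask) {
  const int h = mask.n_rows, w = mask.n_cols;
  imat lab(h, w, fill::zeros);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= h || nj >= w) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
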