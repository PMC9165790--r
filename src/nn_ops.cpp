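#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Feature maps are (H, W, C) cubes; kernels are flattened to a
// (k*k*Cin) x Cout matrix so the convolution is one BLAS gemm per call.
// Column order within a kernel block: row index fastest (R column-major),
// then kernel column, then input channel.

static mat im2col_dil(const cube& x, int k, int r, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int span = r * (k - 1) + 1;
  const int Ho = H + 2 * pad - span + 1;
  const int Wo = W + 2 * pad - span + 1;
  if (Ho <= 0 || Wo <= 0) Rcpp::stop("kernel span exceeds input size");
  mat col((uword)Ho * Wo, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int colIdx = c * k * k + kj * k + ki;
        const int di = ki * r - pad, dj = kj * r - pad;
        const int i0 = std::max(0, -di), i1 = std::min(Ho, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(Wo, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* dst = col.colptr(colIdx) + (uword)j * Ho;
          const double* src = xs.colptr(j + dj) + di;
          for (int i = i0; i < i1; ++i) dst[i] = src[i];
        }
      }
    }
  }
  return col;
}

static cube col2im_dil(const mat& dcol, int H, int W, int C, int k, int r,
                       int pad) {
  const int span = r * (k - 1) + 1;
  const int Ho = H + 2 * pad - span + 1;
  const int Wo = W + 2 * pad - span + 1;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int colIdx = c * k * k + kj * k + ki;
        const int di = ki * r - pad, dj = kj * r - pad;
        const int i0 = std::max(0, -di), i1 = std::min(Ho, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(Wo, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = dcol.colptr(colIdx) + (uword)j * Ho;
          double* dst = xs.colptr(j + dj) + di;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_conv_forward(const arma::cube& x, const arma::mat& W,
                            const arma::vec& b, int k, int rate, int pad) {
  mat col = im2col_dil(x, k, rate, pad);
  mat out = col * W;
  out.each_row() += b.t();
  const int span = rate * (k - 1) + 1;
  const int Ho = x.n_rows + 2 * pad - span + 1;
  const int Wo = x.n_cols + 2 * pad - span + 1;
  cube y(Ho, Wo, W.n_cols);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::cube& x, const arma::mat& W,
                             const arma::cube& gy, int k, int rate, int pad) {
  mat col = im2col_dil(x, k, rate, pad);
  const uword n = gy.n_rows * gy.n_cols;
  mat gmat(const_cast<double*>(gy.memptr()), n, gy.n_slices, false, true);
  mat dW = col.t() * gmat;
  vec db = sum(gmat, 0).t();
  mat dcol = gmat * W.t();
  cube dx = col2im_dil(dcol, x.n_rows, x.n_cols, x.n_slices, k, rate, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Non-overlapping 2x2 max pooling, stride 2. Odd trailing rows/columns are
// dropped. Ties resolve to the first cell in row-major window scan order
// (top-left, top-right, bottom-left, bottom-right). Indices are 1-based
// column-major linear positions within the input H x W slice (R convention).
// [[Rcpp::export]]
Rcpp::List cpp_maxpool(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) Rcpp::stop("map too small to pool");
  cube y(Ho, Wo, C);
  Rcpp::IntegerVector idx((R_xlen_t)Ho * Wo * C);
  R_xlen_t t;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int ri = 2 * i, cj = 2 * j;
        // row-major scan of the 2x2 window
        const int rr[4] = {ri, ri, ri + 1, ri + 1};
        const int cc[4] = {cj, cj + 1, cj, cj + 1};
        double best = xs(rr[0], cc[0]);
        int bi = rr[0], bj = cc[0];
        for (int s = 1; s < 4; ++s) {
          const double v = xs(rr[s], cc[s]);
          if (v > best) { best = v; bi = rr[s]; bj = cc[s]; }
        }
        y(i, j, c) = best;
        t = (R_xlen_t)c * Ho * Wo + (R_xlen_t)j * Ho + i;
        idx[t] = bi + bj * H + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("pooled") = y,
                            Rcpp::Named("indices") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_unpool(const arma::cube& p, const Rcpp::IntegerVector& idx,
                      int H, int W) {
  const int Ho = p.n_rows, Wo = p.n_cols, C = p.n_slices;
  if ((R_xlen_t)idx.size() != (R_xlen_t)Ho * Wo * C)
    Rcpp::stop("index length does not match pooled map");
  cube y(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& ys = y.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int lin = idx[(R_xlen_t)c * Ho * Wo + (R_xlen_t)j * Ho + i] - 1;
        if (lin < 0 || lin >= H * W) Rcpp::stop("pool index out of range");
        ys(lin) = p(i, j, c);
      }
    }
  }
  return y;
}
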