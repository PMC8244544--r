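// Low-level numerical kernels for the segmentation network.
// Layout convention: feature maps are H x W x C cubes; standard-convolution
// weights arrive flattened as kh x kw x (Cin*Cout) with slice index
// ci + Cin*co; depthwise weights are kh x kw x C. Zero padding, integer
// stride, cross-correlation orientation (no kernel flip), matching the usual
// deep-learning convention.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col: columns indexed by output pixel p = io + Ho*jo, rows by
// r = ki + kh*(kj + kw*ci); zero padding materializes as zero rows
static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  mat C(kh * kw * cin, Ho * Wo, fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    const mat& xs = x.slice(ci);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          double* col = C.colptr(jo * Ho) + r;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride - pad + ki;
            if (ii >= 0 && ii < H) col[(size_t)io * C.n_rows] = xs(ii, jj);
          }
        }
      }
    }
  }
  return C;
}

// weight cube (kh x kw x cin*cout, slice ci + cin*co) -> (kh*kw*cin) x cout
static mat weights_as_mat(const cube& w, int cin, int cout) {
  const int kh = w.n_rows, kw = w.n_cols;
  mat Wm(kh * kw * cin, cout);
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < cin; ++ci) {
      const mat& ws = w.slice(ci + cin * co);
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          Wm(ki + kh * (kj + kw * ci), co) = ws(ki, kj);
        }
      }
    }
  }
  return Wm;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::cube& w,
                      const arma::vec& b, int cin, int cout,
                      int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = w.n_rows, kw = w.n_cols;
  const int Ho = out_extent(H, kh, stride, pad);
  const int Wo = out_extent(W, kw, stride, pad);
  mat C = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat OutM = C.t() * weights_as_mat(w, cin, cout);   // (Ho*Wo) x cout
  OutM.each_row() += b.t();
  cube out(Ho, Wo, cout);
  std::memcpy(out.memptr(), OutM.memptr(),
              sizeof(double) * (size_t)Ho * Wo * cout);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::cube& w,
                      const arma::cube& gout, int cin, int cout,
                      int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = w.n_rows, kw = w.n_cols;
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  const mat GoutM((double*)gout.memptr(), Ho * Wo, cout);
  mat C = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat GWm = C * GoutM;                               // (kh*kw*cin) x cout
  cube gw(kh, kw, cin * cout);
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < cin; ++ci) {
      mat& gws = gw.slice(ci + cin * co);
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          gws(ki, kj) = GWm(ki + kh * (kj + kw * ci), co);
        }
      }
    }
  }
  vec gb = sum(GoutM, 0).t();
  // col2im scatter of Wm * GoutM^T back onto the input grid
  mat Gcol = weights_as_mat(w, cin, cout) * GoutM.t();  // rows x (Ho*Wo)
  cube gx(H, W, cin, fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    mat& gxs = gx.slice(ci);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          const double* col = Gcol.colptr(jo * Ho) + r;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride - pad + ki;
            if (ii >= 0 && ii < H) {
              gxs(ii, jj) += col[(size_t)io * Gcol.n_rows];
            }
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube dwconv2d_fwd(const arma::cube& x, const arma::cube& w,
                        const arma::vec& b, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int kh = w.n_rows, kw = w.n_cols;
  const int Ho = out_extent(H, kh, stride, pad);
  const int Wo = out_extent(W, kw, stride, pad);
  cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    const mat& ws = w.slice(c);
    mat& os = out.slice(c);
    os.fill(b(c));
    for (int jo = 0; jo < Wo; ++jo) {
      const int j0 = jo * stride - pad;
      for (int io = 0; io < Ho; ++io) {
        const int i0 = io * stride - pad;
        double acc = 0.0;
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = j0 + kj;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int ii = i0 + ki;
            if (ii < 0 || ii >= H) continue;
            acc += xs(ii, jj) * ws(ki, kj);
          }
        }
        os(io, jo) += acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List dwconv2d_bwd(const arma::cube& x, const arma::cube& w,
                        const arma::cube& gout, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int kh = w.n_rows, kw = w.n_cols;
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  cube gx(H, W, C, fill::zeros);
  cube gw(kh, kw, C, fill::zeros);
  vec gb(C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    const mat& ws = w.slice(c);
    const mat& gs = gout.slice(c);
    mat& gxs = gx.slice(c);
    mat& gws = gw.slice(c);
    gb(c) = accu(gs);
    for (int jo = 0; jo < Wo; ++jo) {
      const int j0 = jo * stride - pad;
      for (int io = 0; io < Ho; ++io) {
        const int i0 = io * stride - pad;
        const double g = gs(io, jo);
        if (g == 0.0) continue;
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = j0 + kj;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int ii = i0 + ki;
            if (ii < 0 || ii >= H) continue;
            gws(ki, kj) += g * xs(ii, jj);
            gxs(ii, jj) += g * ws(ki, kj);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Bilinear 2x upsampling with half-pixel centre alignment
// (source coordinate of output pixel i is (i + 0.5)/2 - 0.5).
// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  cube out(Ho, Wo, C);
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> wi(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s);
    i1[i] = std::min(i0[i] + 1, H - 1);
    wi[i] = s - i0[i];
  }
  std::vector<int> j0(Wo), j1(Wo);
  std::vector<double> wj(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s);
    j1[j] = std::min(j0[j] + 1, W - 1);
    wj[j] = s - j0[j];
  }
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    mat& os = out.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        os(i, j) =
          (1 - wi[i]) * (1 - wj[j]) * xs(i0[i], j0[j]) +
          (1 - wi[i]) * wj[j]       * xs(i0[i], j1[j]) +
          wi[i]       * (1 - wj[j]) * xs(i1[i], j0[j]) +
          wi[i]       * wj[j]       * xs(i1[i], j1[j]);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& gout, int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  cube gx(H, W, C, fill::zeros);
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> wi(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s);
    i1[i] = std::min(i0[i] + 1, H - 1);
    wi[i] = s - i0[i];
  }
  std::vector<int> j0(Wo), j1(Wo);
  std::vector<double> wj(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s);
    j1[j] = std::min(j0[j] + 1, W - 1);
    wj[j] = s - j0[j];
  }
  for (int c = 0; c < C; ++c) {
    const mat& gs = gout.slice(c);
    mat& gxs = gx.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double g = gs(i, j);
        gxs(i0[i], j0[j]) += (1 - wi[i]) * (1 - wj[j]) * g;
        gxs(i0[i], j1[j]) += (1 - wi[i]) * wj[j] * g;
        gxs(i1[i], j0[j]) += wi[i] * (1 - wj[j]) * g;
        gxs(i1[i], j1[j]) += wi[i] * wj[j] * g;
      }
    }
  }
  return gx;
}
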