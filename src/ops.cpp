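// Low-level numerical kernels for the network and resampling code.
// Feature maps are arma::cube with (rows, cols, slices) = (H, W, C),
// matching an R array of dim c(H, W, C).  Convolution weights are a
// matrix [C_out, C_in*k*k] whose column index is c*k*k + dj*k + di.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(C * k * k, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            col(r, j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int k, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_rows;
  arma::mat out;
  if (k == 1) {
    arma::mat xm(const_cast<double*>(x.memptr()), H * Wd, x.n_slices, false);
    out = W * xm.t();
  } else {
    out = W * im2col(x, k, pad);
  }
  out.each_col() += b;
  arma::cube y(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c) {
    arma::mat plane(out.row(c));
    y.slice(c) = arma::reshape(plane, H, Wd);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                    const arma::cube& gout, int k, int pad) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  arma::mat gmat(Cout, H * Wd);
  for (int c = 0; c < Cout; ++c)
    gmat.row(c) = arma::vectorise(gout.slice(c)).t();
  arma::vec gb = arma::sum(gmat, 1);
  arma::mat gW, gcol;
  arma::cube gx(H, Wd, Cin, arma::fill::zeros);
  if (k == 1) {
    arma::mat xm(const_cast<double*>(x.memptr()), H * Wd, Cin, false);
    gW = gmat * xm;
    arma::mat gxm = W.t() * gmat;  // Cin x HW
    for (int c = 0; c < Cin; ++c)
      gx.slice(c) = arma::reshape(arma::mat(gxm.row(c)), H, Wd);
    return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
  }
  arma::mat col = im2col(x, k, pad);
  gW = gmat * col.t();
  gcol = W.t() * gmat;  // (Cin*k*k) x HW
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        for (int j = 0; j < Wd; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= Wd) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += gcol(r, j * H + i);
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even.  Returns pooled map and
// the linear (within-plane, 0-based) argmax indices for unpooling.
// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  arma::ucube idx(h, w, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = (arma::uword)(bj * H + bi);
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& g, const arma::ucube& idx,
                            int H, int W) {
  const int C = g.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* plane = gx.slice_memptr(c);
    for (arma::uword p = 0; p < g.n_rows * g.n_cols; ++p)
      plane[idx.slice(c)(p)] += g.slice(c)(p);
  }
  return gx;
}

// When the stack being unpooled has more channels than the stored indices
// (filter-doubling variants), index channels are recycled.
// [[Rcpp::export]]
arma::cube cpp_maxunpool2(const arma::cube& x, const arma::ucube& idx,
                          int H, int W) {
  const int C = x.n_slices, Ci = idx.n_slices;
  arma::cube y(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* plane = y.slice_memptr(c);
    const arma::umat& ip = idx.slice(c % Ci);
    for (arma::uword p = 0; p < x.n_rows * x.n_cols; ++p)
      plane[ip(p)] = x.slice(c)(p);
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_maxunpool2_bwd(const arma::cube& g, const arma::ucube& idx,
                              int h, int w) {
  const int C = g.n_slices, Ci = idx.n_slices;
  arma::cube gx(h, w, C);
  for (int c = 0; c < C; ++c) {
    const double* plane = g.slice_memptr(c);
    const arma::umat& ip = idx.slice(c % Ci);
    for (arma::uword p = 0; p < gx.n_rows * gx.n_cols; ++p)
      gx.slice(c)(p) = plane[ip(p)];
  }
  return gx;
}

// Bilinear resize with the half-pixel-center convention (no corner
// alignment): src = (dst + 0.5) * in/out - 0.5, edges clamped.
static inline void lin_coeff(int o, int n_in, int n_out,
                             int& i0, int& i1, double& w1) {
  double s = (o + 0.5) * ((double)n_in / n_out) - 0.5;
  if (s < 0) s = 0;
  if (s > n_in - 1) s = n_in - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = s - i0;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(oh, ow, C);
  std::vector<int> r0(oh), r1(oh), c0(ow), c1(ow);
  std::vector<double> rw(oh), cw(ow);
  for (int i = 0; i < oh; ++i) lin_coeff(i, H, oh, r0[i], r1[i], rw[i]);
  for (int j = 0; j < ow; ++j) lin_coeff(j, W, ow, c0[j], c1[j], cw[j]);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i)
        y(i, j, c) =
          (1 - rw[i]) * ((1 - cw[j]) * x(r0[i], c0[j], c) + cw[j] * x(r0[i], c1[j], c)) +
          rw[i] * ((1 - cw[j]) * x(r1[i], c0[j], c) + cw[j] * x(r1[i], c1[j], c));
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_bwd(const arma::cube& g, int ih, int iw) {
  const int oh = g.n_rows, ow = g.n_cols, C = g.n_slices;
  arma::cube gx(ih, iw, C, arma::fill::zeros);
  std::vector<int> r0(oh), r1(oh), c0(ow), c1(ow);
  std::vector<double> rw(oh), cw(ow);
  for (int i = 0; i < oh; ++i) lin_coeff(i, ih, oh, r0[i], r1[i], rw[i]);
  for (int j = 0; j < ow; ++j) lin_coeff(j, iw, ow, c0[j], c1[j], cw[j]);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double gv = g(i, j, c);
        gx(r0[i], c0[j], c) += (1 - rw[i]) * (1 - cw[j]) * gv;
        gx(r0[i], c1[j], c) += (1 - rw[i]) * cw[j] * gv;
        gx(r1[i], c0[j], c) += rw[i] * (1 - cw[j]) * gv;
        gx(r1[i], c1[j], c) += rw[i] * cw[j] * gv;
      }
  return gx;
}

// Trilinear resize of a 3D intensity grid, same half-pixel convention.
// [[Rcpp::export]]
arma::cube cpp_resize_trilinear(const arma::cube& x, int o1, int o2, int o3) {
  const int n1 = x.n_rows, n2 = x.n_cols, n3 = x.n_slices;
  std::vector<int> a0(o1), a1(o1), b0(o2), b1(o2), d0(o3), d1(o3);
  std::vector<double> aw(o1), bw(o2), dw(o3);
  for (int i = 0; i < o1; ++i) lin_coeff(i, n1, o1, a0[i], a1[i], aw[i]);
  for (int j = 0; j < o2; ++j) lin_coeff(j, n2, o2, b0[j], b1[j], bw[j]);
  for (int k = 0; k < o3; ++k) lin_coeff(k, n3, o3, d0[k], d1[k], dw[k]);
  arma::cube y(o1, o2, o3);
  for (int k = 0; k < o3; ++k)
    for (int j = 0; j < o2; ++j)
      for (int i = 0; i < o1; ++i) {
        double v = 0;
        const double wi[2] = {1 - aw[i], aw[i]};
        const double wj[2] = {1 - bw[j], bw[j]};
        const double wk[2] = {1 - dw[k], dw[k]};
        const int ii[2] = {a0[i], a1[i]}, jj[2] = {b0[j], b1[j]},
                  kk[2] = {d0[k], d1[k]};
        for (int u = 0; u < 2; ++u)
          for (int v2 = 0; v2 < 2; ++v2)
            for (int w = 0; w < 2; ++w)
              v += wi[u] * wj[v2] * wk[w] * x(ii[u], jj[v2], kk[w]);
        y(i, j, k) = v;
      }
  return y;
}

// Separable 'valid' correlation of a 2D image with a 1D kernel applied
// along rows then columns (for local window statistics, e.g. SSIM).
// [[Rcpp::export]]
arma::mat cpp_sepconv_valid(const arma::mat& x, const arma::vec& k) {
  const int L = k.n_elem;
  const int H = x.n_rows, W = x.n_cols;
  arma::mat tmp(H - L + 1, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i + L <= H; ++i) {
      double s = 0;
      for (int t = 0; t < L; ++t) s += k(t) * x(i + t, j);
      tmp(i, j) = s;
    }
  arma::mat y(H - L + 1, W - L + 1);
  for (int j = 0; j + L <= W; ++j)
    for (int i = 0; i < (int)tmp.n_rows; ++i) {
      double s = 0;
      for (int t = 0; t < L; ++t) s += k(t) * tmp(i, j + t);
      y(i, j) = s;
    }
  return y;
}

// In-plane rotation about the image centre with bilinear interpolation and
// zero fill, angle in degrees (counter-clockwise in index space).
// [[Rcpp::export]]
arma::mat cpp_rotate_bilinear(const arma::mat& x, double angle_deg) {
  const int H = x.n_rows, W = x.n_cols;
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  arma::mat y(H, W, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double dy = i - cy, dx = j - cx;
      const double si = ct * dy + st * dx + cy;
      const double sj = -st * dy + ct * dx + cx;
      const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      if (i0 < -1 || i0 > H - 1 || j0 < -1 || j0 > W - 1) continue;
      const double wi = si - i0, wj = sj - j0;
      double v = 0;
      for (int u = 0; u < 2; ++u)
        for (int t = 0; t < 2; ++t) {
          const int ii = i0 + u, jj = j0 + t;
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          v += (u ? wi : 1 - wi) * (t ? wj : 1 - wj) * x(ii, jj);
        }
      y(i, j) = v;
    }
  return y;
}
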