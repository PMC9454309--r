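// Numeric kernels: im2col convolutions with exact adjoints, batched window
// matmuls, and the gamma-index search. All arrays are column-major with
// spatial layout (H, W, C); weights are (kh, kw, Cin, Cout).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// borrow R memory without copying
static arma::cube borrow_cube(const NumericVector& x, int H, int W, int C) {
  return arma::cube(const_cast<double*>(x.begin()), H, W, C, false, true);
}
static arma::vec borrow_vec(const NumericVector& x) {
  return arma::vec(const_cast<double*>(x.begin()), x.size(), false, true);
}
static arma::mat borrow_mat(const NumericMatrix& x) {
  return arma::mat(const_cast<double*>(x.begin()), x.nrow(), x.ncol(),
                   false, true);
}
static IntegerVector cube_dims(const NumericVector& x) {
  return x.attr("dim");
}

static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(Ho * (long)Wo, (long)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const long col = di + (long)kh * dj + (long)kh * kw * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride + di - pad;
            if (ii < 0 || ii >= H) continue;
            cols(io + (long)Ho * jo, col) = x(ii, jj, c);
          }
        }
      }
  return cols;
}

static void col2im_add(arma::cube& dx, const arma::mat& dcols, int kh, int kw,
                       int stride, int pad, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const long col = di + (long)kh * dj + (long)kh * kw * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride + di - pad;
            if (ii < 0 || ii >= H) continue;
            dx(ii, jj, c) += dcols(io + (long)Ho * jo, col);
          }
        }
      }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const NumericVector& x_, const NumericVector& w_,
                          const arma::vec& b, int kh, int kw, int cout,
                          int stride, int pad) {
  const IntegerVector xd = cube_dims(x_);
  const arma::cube x = borrow_cube(x_, xd[0], xd[1], xd[2]);
  const arma::vec w = borrow_vec(w_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.memptr()), (long)kh * kw * C, cout, false);
  arma::mat out = im2col(x, kh, kw, stride, pad, Ho, Wo) * Wm;
  out.each_row() += b.t();
  return arma::cube(out.memptr(), Ho, Wo, cout);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const NumericVector& x_, const NumericVector& w_,
                    const NumericVector& gout_, int kh, int kw,
                    int stride, int pad) {
  const IntegerVector xd = cube_dims(x_);
  const IntegerVector gd = cube_dims(gout_);
  const arma::cube x = borrow_cube(x_, xd[0], xd[1], xd[2]);
  const arma::vec w = borrow_vec(w_);
  const arma::cube gout = borrow_cube(gout_, gd[0], gd[1], gd[2]);
  const int C = x.n_slices, cout = gout.n_slices;
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  arma::mat Wm(const_cast<double*>(w.memptr()), (long)kh * kw * C, cout, false);
  arma::mat Gm(const_cast<double*>(gout.memptr()), (long)Ho * Wo, cout, false);
  arma::mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat dW = cols.t() * Gm;
  arma::vec db = arma::sum(Gm, 0).t();
  arma::mat dcols = Gm * Wm.t();
  arma::cube dx(x.n_rows, x.n_cols, C, arma::fill::zeros);
  col2im_add(dx, dcols, kh, kw, stride, pad, Ho, Wo);
  return List::create(_["dx"] = dx, _["dw"] = arma::vec(dW.memptr(), dW.n_elem),
                      _["db"] = db);
}

// transposed convolution, kernel 2x2, stride 2; w laid out (2, 2, Cin, Cout)
// [[Rcpp::export]]
arma::cube cpp_convt2_fwd(const arma::cube& x, const arma::vec& w,
                          const arma::vec& b, int cout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, cout);
  for (int co = 0; co < cout; ++co) out.slice(co).fill(b(co));
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double wv = w(di + 2 * dj + 4 * (ci + (long)C * co));
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              out(2 * i + di, 2 * j + dj, co) += wv * x(i, j, ci);
        }
  return out;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(const arma::cube& x, const arma::vec& w,
                    const arma::cube& gout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int cout = gout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  arma::vec dw(4 * (long)C * cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  for (int co = 0; co < cout; ++co) db(co) = arma::accu(gout.slice(co));
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const long wi = di + 2 * dj + 4 * (ci + (long)C * co);
          const double wv = w(wi);
          double acc = 0.0;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              const double g = gout(2 * i + di, 2 * j + dj, co);
              dx(i, j, ci) += wv * g;
              acc += x(i, j, ci) * g;
            }
          dw(wi) = acc;
        }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// depth-wise convolution, per-channel (kh, kw) kernels, zero padding
// [[Rcpp::export]]
arma::cube cpp_dwconv_fwd(const NumericVector& x_, const NumericVector& w_,
                          const arma::vec& b, int kh, int kw,
                          int pad_h, int pad_w) {
  const IntegerVector xd = cube_dims(x_);
  const arma::cube x = borrow_cube(x_, xd[0], xd[1], xd[2]);
  const arma::vec w = borrow_vec(w_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H + 2 * pad_h - kh + 1, Wo = W + 2 * pad_w - kw + 1;
  arma::cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    out.slice(c).fill(b(c));
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const double wv = w(di + (long)kh * dj + (long)kh * kw * c);
        if (wv == 0.0) continue;
        // output rows io in [io0, io1], input rows ii = io + di - pad_h
        const int io0 = std::max(0, pad_h - di);
        const int io1 = std::min(Ho - 1, H - 1 - di + pad_h);
        const int jo0 = std::max(0, pad_w - dj);
        const int jo1 = std::min(Wo - 1, W - 1 - dj + pad_w);
        if (io0 > io1 || jo0 > jo1) continue;
        out.slice(c).submat(io0, jo0, io1, jo1) +=
          wv * x.slice(c).submat(io0 + di - pad_h, jo0 + dj - pad_w,
                                 io1 + di - pad_h, jo1 + dj - pad_w);
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(const NumericVector& x_, const NumericVector& w_,
                    const NumericVector& gout_, int kh, int kw,
                    int pad_h, int pad_w) {
  const IntegerVector xd = cube_dims(x_);
  const IntegerVector gd = cube_dims(gout_);
  const arma::cube x = borrow_cube(x_, xd[0], xd[1], xd[2]);
  const arma::vec w = borrow_vec(w_);
  const arma::cube gout = borrow_cube(gout_, gd[0], gd[1], gd[2]);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  arma::cube dx(H, W, C, arma::fill::zeros);
  arma::vec dw((long)kh * kw * C, arma::fill::zeros);
  arma::vec db(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    db(c) = arma::accu(gout.slice(c));
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const long wi = di + (long)kh * dj + (long)kh * kw * c;
        const double wv = w(wi);
        const int io0 = std::max(0, pad_h - di);
        const int io1 = std::min(Ho - 1, H - 1 - di + pad_h);
        const int jo0 = std::max(0, pad_w - dj);
        const int jo1 = std::min(Wo - 1, W - 1 - dj + pad_w);
        if (io0 > io1 || jo0 > jo1) continue;
        const arma::mat gsub = gout.slice(c).submat(io0, jo0, io1, jo1);
        const arma::mat xsub = x.slice(c).submat(
            io0 + di - pad_h, jo0 + dj - pad_w,
            io1 + di - pad_h, jo1 + dj - pad_w);
        dx.slice(c).submat(io0 + di - pad_h, jo0 + dj - pad_w,
                           io1 + di - pad_h, jo1 + dj - pad_w) += wv * gsub;
        dw(wi) = arma::accu(xsub % gsub);
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// batched matrix multiply over cube slices: out_s = op(A_s) * op(B_s)
// [[Rcpp::export]]
arma::cube cpp_bmm(const arma::cube& A, const arma::cube& B,
                   bool transA, bool transB) {
  const int n = A.n_slices;
  const int m = transA ? A.n_cols : A.n_rows;
  const int p = transB ? B.n_rows : B.n_cols;
  arma::cube out(m, p, n);
  for (int s = 0; s < n; ++s) {
    const arma::mat& a = A.slice(s);
    const arma::mat& b = B.slice(s);
    if (!transA && !transB)      out.slice(s) = a * b;
    else if (!transA && transB)  out.slice(s) = a * b.t();
    else if (transA && !transB)  out.slice(s) = a.t() * b;
    else                         out.slice(s) = a.t() * b.t();
  }
  return out;
}

static double trilinear(const arma::cube& v, double x, double y, double z,
                        bool& ok) {
  const int H = v.n_rows, W = v.n_cols, D = v.n_slices;
  if (x < 0 || y < 0 || z < 0 || x > H - 1 || y > W - 1 || z > D - 1) {
    ok = false; return 0.0;
  }
  ok = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == H - 1) i0--; if (j0 == W - 1) j0--; if (k0 == D - 1) k0--;
  if (H == 1) i0 = 0; if (W == 1) j0 = 0; if (D == 1) k0 = 0;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1),
            k1 = std::min(k0 + 1, D - 1);
  return
    v(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    v(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    v(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
    v(i1, j1, k0) * fx * fy * (1 - fz) +
    v(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    v(i1, j0, k1) * fx * (1 - fy) * fz +
    v(i0, j1, k1) * (1 - fx) * fy * fz +
    v(i1, j1, k1) * fx * fy * fz;
}

// gamma index with candidate offsets sorted by distance so the spatial term
// bounds the search; offsets are absolute mm displacements (n x 3 matrix,
// including the zero offset). Non-evaluated voxels (below dose threshold)
// return NA.
// [[Rcpp::export]]
arma::cube cpp_gamma(const arma::cube& ref, const arma::cube& test,
                     const arma::vec& spacing, const arma::mat& offsets,
                     double dose_crit_abs, double dta_mm, double thresh_abs) {
  const int H = ref.n_rows, W = ref.n_cols, D = ref.n_slices;
  const int nOff = offsets.n_rows;
  arma::vec r2(nOff);
  for (int o = 0; o < nOff; ++o)
    r2(o) = offsets(o, 0) * offsets(o, 0) + offsets(o, 1) * offsets(o, 1) +
            offsets(o, 2) * offsets(o, 2);
  arma::uvec ord = arma::sort_index(r2);
  arma::cube gamma(H, W, D);
  gamma.fill(NA_REAL);
  const double dta2 = dta_mm * dta_mm;
  for (int k = 0; k < D; ++k)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double dref = ref(i, j, k);
        if (dref < thresh_abs) continue;
        double best = arma::datum::inf;
        for (int oo = 0; oo < nOff; ++oo) {
          const int o = ord(oo);
          const double spatial2 = r2(o) / dta2;
          if (spatial2 >= best) break;  // sorted: no later offset can win
          bool ok;
          const double dt = trilinear(
              test,
              i + offsets(o, 0) / spacing(0),
              j + offsets(o, 1) / spacing(1),
              k + offsets(o, 2) / spacing(2), ok);
          if (!ok) continue;
          const double dd = (dt - dref) / dose_crit_abs;
          const double g2 = dd * dd + spatial2;
          if (g2 < best) best = g2;
        }
        gamma(i, j, k) = std::sqrt(best);
      }
  return gamma;
}

// scatter-add: dst[idx[i]] += src[i] (1-based idx), for gather adjoints
// [[Rcpp::export]]
NumericVector cpp_scatter_add(const IntegerVector& idx,
                              const NumericVector& src, int n_out) {
  NumericVector out(n_out);
  for (R_xlen_t i = 0; i < src.size(); ++i) out[idx[i] - 1] += src[i];
  return out;
}

// fused multi-head window attention. qkv: (nw*m, 3C) window-major rows;
// bias: (m, m, k); mask: (m, m, nw) or empty. Returns output (nw*m, C) and
// the softmax weights A (m, m, nw*k) cached for the adjoint.
// [[Rcpp::export]]
List cpp_attn_fwd(const NumericMatrix& qkv_, const arma::cube& bias,
                  const arma::cube& mask, bool has_mask,
                  int nw, int m, int k, double scale) {
  const arma::mat qkv = borrow_mat(qkv_);
  const int C = qkv.n_cols / 3;
  const int d = C / k;
  arma::mat out(nw * m, C);
  arma::cube A(m, m, (long)nw * k);
  arma::mat Qw(m, d), Kw(m, d), Vw(m, d);
  for (int h = 0; h < k; ++h) {
    for (int w = 0; w < nw; ++w) {
      for (int j = 0; j < d; ++j) {
        const int r0 = w * m;
        Qw.col(j) = qkv.col(h * d + j).subvec(r0, r0 + m - 1);
        Kw.col(j) = qkv.col(C + h * d + j).subvec(r0, r0 + m - 1);
        Vw.col(j) = qkv.col(2 * C + h * d + j).subvec(r0, r0 + m - 1);
      }
      arma::mat S = scale * (Qw * Kw.t()) + bias.slice(h);
      if (has_mask) S += mask.slice(w);
      for (int i = 0; i < m; ++i) {
        arma::rowvec row = S.row(i);
        row -= row.max();
        row = arma::exp(row);
        S.row(i) = row / arma::accu(row);
      }
      A.slice((long)h * nw + w) = S;
      arma::mat O = S * Vw;
      for (int j = 0; j < d; ++j)
        out.col(h * d + j).subvec(w * m, w * m + m - 1) = O.col(j);
    }
  }
  return List::create(_["out"] = out, _["A"] = A);
}

// [[Rcpp::export]]
List cpp_attn_bwd(const NumericMatrix& qkv_, const NumericVector& A_,
                  const NumericMatrix& g_, int nw, int m, int k,
                  double scale) {
  const arma::mat qkv = borrow_mat(qkv_);
  const arma::mat g = borrow_mat(g_);
  const arma::cube A = borrow_cube(A_, m, m, (long)nw * k);
  const int C = qkv.n_cols / 3;
  const int d = C / k;
  arma::mat dqkv(nw * m, 3 * C, arma::fill::zeros);
  arma::cube dbias(m, m, k, arma::fill::zeros);
  arma::mat Qw(m, d), Kw(m, d), Vw(m, d), gO(m, d);
  for (int h = 0; h < k; ++h) {
    for (int w = 0; w < nw; ++w) {
      const int r0 = w * m;
      for (int j = 0; j < d; ++j) {
        Qw.col(j) = qkv.col(h * d + j).subvec(r0, r0 + m - 1);
        Kw.col(j) = qkv.col(C + h * d + j).subvec(r0, r0 + m - 1);
        Vw.col(j) = qkv.col(2 * C + h * d + j).subvec(r0, r0 + m - 1);
        gO.col(j) = g.col(h * d + j).subvec(r0, r0 + m - 1);
      }
      const arma::mat& Aw = A.slice((long)h * nw + w);
      arma::mat dA = gO * Vw.t();
      arma::mat dV = Aw.t() * gO;
      arma::vec rs = arma::sum(dA % Aw, 1);
      arma::mat dS = Aw % (dA.each_col() - rs);
      dbias.slice(h) += dS;
      arma::mat dQ = scale * (dS * Kw);
      arma::mat dK = scale * (dS.t() * Qw);
      for (int j = 0; j < d; ++j) {
        dqkv.col(h * d + j).subvec(r0, r0 + m - 1) = dQ.col(j);
        dqkv.col(C + h * d + j).subvec(r0, r0 + m - 1) = dK.col(j);
        dqkv.col(2 * C + h * d + j).subvec(r0, r0 + m - 1) = dV.col(j);
      }
    }
  }
  return List::create(_["dqkv"] = dqkv, _["dbias"] = dbias);
}

// exact GELU returning value and Phi(x) for a cheap adjoint
// [[Rcpp::export]]
List cpp_gelu_fwd2(const NumericVector& x) {
  const R_xlen_t n = x.size();
  NumericVector y(n), phi(n);
  const double isq2 = 1.0 / std::sqrt(2.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    phi[i] = 0.5 * (1.0 + std::erf(x[i] * isq2));
    y[i] = x[i] * phi[i];
  }
  return List::create(_["y"] = y, _["phi"] = phi);
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bwd2(const NumericVector& x, const NumericVector& phi,
                            const NumericVector& g) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  const double c = 1.0 / std::sqrt(2.0 * M_PI);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = g[i] * (phi[i] + x[i] * c * std::exp(-0.5 * x[i] * x[i]));
  return out;
}
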