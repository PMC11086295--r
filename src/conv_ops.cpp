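// Convolution, transposed convolution and pooling primitives for the
// compact CNN. Data layout follows R's column-major arrays:
//   activations (H, W, C, N), spatial index p = i + H*j
//   conv kernels (kh, kw, Cin, Cout)
// "Same" padding uses ceil-mode output sizes, extra padding on the
// bottom/right; this is what maps 85 -> 43 in the reference architecture.
//
// Convolutions are evaluated as a sum over kernel offsets of gathered
// row-block matrix products (one GEMM per offset), which keeps memory
// bounded for the large generator layers where an im2col buffer would
// not fit comfortably.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvGeom {
  int H, W, oH, oW, kh, kw, sh, sw, ph, pw;
  std::vector<arma::uvec> in_idx, out_idx;  // one pair per kernel offset
};

// Geometry for a SAME-padded strided convolution H x W -> oH x oW with
// oH = ceil(H/sh). For each kernel offset (di, dj) we precompute the
// matching (input position, output position) index pairs.
ConvGeom make_geom(int H, int W, int kh, int kw, int sh, int sw) {
  ConvGeom g;
  g.H = H; g.W = W; g.kh = kh; g.kw = kw; g.sh = sh; g.sw = sw;
  g.oH = (H + sh - 1) / sh;
  g.oW = (W + sw - 1) / sw;
  int pad_h = std::max((g.oH - 1) * sh + kh - H, 0);
  int pad_w = std::max((g.oW - 1) * sw + kw - W, 0);
  g.ph = pad_h / 2;
  g.pw = pad_w / 2;
  g.in_idx.resize((size_t)kh * kw);
  g.out_idx.resize((size_t)kh * kw);
  for (int dj = 0; dj < kw; ++dj) {
    for (int di = 0; di < kh; ++di) {
      std::vector<arma::uword> vin, vout;
      vin.reserve((size_t)g.oH * g.oW);
      vout.reserve((size_t)g.oH * g.oW);
      for (int oj = 0; oj < g.oW; ++oj) {
        int j = oj * sw + dj - g.pw;
        if (j < 0 || j >= W) continue;
        for (int oi = 0; oi < g.oH; ++oi) {
          int i = oi * sh + di - g.ph;
          if (i < 0 || i >= H) continue;
          vin.push_back((arma::uword)i + (arma::uword)H * j);
          vout.push_back((arma::uword)oi + (arma::uword)g.oH * oj);
        }
      }
      size_t o = (size_t)di + (size_t)kh * dj;
      g.in_idx[o] = arma::uvec(vin);
      g.out_idx[o] = arma::uvec(vout);
    }
  }
  return g;
}

// Batched im2col patch matrix: one row per (image, output position), one
// column per (kernel offset, input channel); a single GEMM against the
// (kh*kw*Cin) x Cout kernel matrix (which is exactly the column-major
// layout of the kernel array) then evaluates the whole batch.
arma::mat im2col_batch(const double* xp, const ConvGeom& g, int Cin, int N,
                       arma::uword HW, arma::uword oHW) {
  size_t kk = g.in_idx.size();
  arma::mat A((arma::uword)N * oHW, (arma::uword)kk * Cin, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (R_xlen_t)n * HW * Cin;
    for (size_t o = 0; o < kk; ++o) {
      const arma::uvec& iin = g.in_idx[o];
      const arma::uvec& iout = g.out_idx[o];
      for (int ci = 0; ci < Cin; ++ci) {
        double* col = A.colptr(o + kk * ci);
        const double* src = xn + (arma::uword)ci * HW;
        for (arma::uword q = 0; q < iin.n_elem; ++q)
          col[(arma::uword)n * oHW + iout[q]] = src[iin[q]];
      }
    }
  }
  return A;
}

// Keep the im2col buffer below ~300 MB; fall back to the per-image
// product-scatter path (one GEMM per image plus light index traffic) for
// very large patch matrices such as the generator's wide layers.
bool use_im2col(double n_rows, double n_cols) {
  return n_rows * n_cols <= 4.0e7;
}

// kernel array (kh,kw,Cin,Cout) -> (Cin x kk*Cout) with column o + kk*co
arma::mat kernel_cin_by_kkcout(const NumericVector& w, int kh, int kw,
                               int cin, int cout) {
  size_t kk = (size_t)kh * kw;
  arma::mat W6(cin, kk * cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (size_t o = 0; o < kk; ++o) {
        int di = (int)(o % kh), dj = (int)(o / kh);
        W6(ci, o + kk * co) =
          wp[(R_xlen_t)di + (R_xlen_t)kh * (dj + (R_xlen_t)kw * (ci + (R_xlen_t)cin * co))];
      }
  return W6;
}

}  // namespace

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w, NumericVector b,
                                 int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("kernel input channels do not match activation channels");
  ConvGeom g = make_geom(H, W, kh, kw, sh, sw);
  arma::uword HW = (arma::uword)H * W, oHW = (arma::uword)g.oH * g.oW;
  NumericVector y((R_xlen_t)oHW * Cout * N);
  y.attr("dim") = IntegerVector::create(g.oH, g.oW, Cout, N);
  size_t kk = (size_t)kh * kw;
  if (use_im2col((double)N * oHW, (double)kk * Cin)) {
    arma::mat A = im2col_batch(x.begin(), g, Cin, N, HW, oHW);
    arma::mat Wm(const_cast<double*>(w.begin()), kk * Cin, Cout, false, true);
    arma::mat Yall = A * Wm;
    for (int n = 0; n < N; ++n) {
      arma::mat Yn(y.begin() + (R_xlen_t)n * oHW * Cout, oHW, Cout, false, true);
      Yn = Yall.rows((arma::uword)n * oHW, (arma::uword)(n + 1) * oHW - 1);
      for (int co = 0; co < Cout; ++co) Yn.col(co) += b[co];
    }
    return y;
  }
  // product-scatter path: one GEMM per image, then indexed accumulation
  arma::mat W6 = kernel_cin_by_kkcout(w, kh, kw, Cin, Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (R_xlen_t)n * HW * Cin, HW, Cin, false, true);
    arma::mat Yn(y.begin() + (R_xlen_t)n * oHW * Cout, oHW, Cout, false, true);
    for (int co = 0; co < Cout; ++co) Yn.col(co).fill(b[co]);
    arma::mat P = Xn * W6;  // (HW x kk*Cout)
    for (int co = 0; co < Cout; ++co)
      for (size_t o = 0; o < kk; ++o) {
        const arma::uvec& iin = g.in_idx[o];
        const arma::uvec& iout = g.out_idx[o];
        const double* pc = P.colptr(o + kk * co);
        double* yc = Yn.colptr(co);
        for (arma::uword q = 0; q < iin.n_elem; ++q) yc[iout[q]] += pc[iin[q]];
      }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  ConvGeom g = make_geom(H, W, kh, kw, sh, sw);
  if (yd[0] != g.oH || yd[1] != g.oW || yd[2] != Cout)
    stop("gradient shape does not match convolution geometry");
  arma::uword HW = (arma::uword)H * W, oHW = (arma::uword)g.oH * g.oW;
  NumericVector dx((R_xlen_t)HW * Cin * N);
  dx.attr("dim") = xd;
  size_t kk = (size_t)kh * kw;
  if (use_im2col((double)N * oHW, (double)kk * Cin)) {
    arma::mat A = im2col_batch(x.begin(), g, Cin, N, HW, oHW);
    arma::mat dYall((arma::uword)N * oHW, Cout);
    for (int n = 0; n < N; ++n) {
      arma::mat dYn(const_cast<double*>(dy.begin()) + (R_xlen_t)n * oHW * Cout,
                    oHW, Cout, false, true);
      dYall.rows((arma::uword)n * oHW, (arma::uword)(n + 1) * oHW - 1) = dYn;
    }
    NumericVector dw((R_xlen_t)kk * Cin * Cout);
    dw.attr("dim") = wd;
    arma::mat dWm(dw.begin(), kk * Cin, Cout, false, true);
    dWm = A.t() * dYall;
    arma::rowvec db = arma::sum(dYall, 0);
    arma::mat Wm(const_cast<double*>(w.begin()), kk * Cin, Cout, false, true);
    arma::mat dA = dYall * Wm.t();
    for (int n = 0; n < N; ++n) {  // col2im scatter-add
      double* dxn = dx.begin() + (R_xlen_t)n * HW * Cin;
      for (size_t o = 0; o < kk; ++o) {
        const arma::uvec& iin = g.in_idx[o];
        const arma::uvec& iout = g.out_idx[o];
        for (int ci = 0; ci < Cin; ++ci) {
          const double* col = dA.colptr(o + kk * ci);
          double* dst = dxn + (arma::uword)ci * HW;
          for (arma::uword q = 0; q < iin.n_elem; ++q)
            dst[iin[q]] += col[(arma::uword)n * oHW + iout[q]];
        }
      }
    }
    return List::create(_["dx"] = dx, _["dw"] = dw,
                        _["db"] = NumericVector(db.begin(), db.end()));
  }
  // gather-GEMM path: patch matrix built from the output gradient
  arma::mat W6 = kernel_cin_by_kkcout(w, kh, kw, Cin, Cout);
  arma::mat dW6(Cin, kk * Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (R_xlen_t)n * HW * Cin, HW, Cin, false, true);
    arma::mat dYn(const_cast<double*>(dy.begin()) + (R_xlen_t)n * oHW * Cout, oHW, Cout, false, true);
    arma::mat dXn(dx.begin() + (R_xlen_t)n * HW * Cin, HW, Cin, false, true);
    db += arma::sum(dYn, 0).t();
    arma::mat A(HW, kk * Cout, arma::fill::zeros);  // A[p, o+kk*co] = dY at the
    for (int co = 0; co < Cout; ++co)               // position p feeds via offset o
      for (size_t o = 0; o < kk; ++o) {
        const arma::uvec& iin = g.in_idx[o];
        const arma::uvec& iout = g.out_idx[o];
        double* ac = A.colptr(o + kk * co);
        const double* dc = dYn.colptr(co);
        for (arma::uword q = 0; q < iin.n_elem; ++q) ac[iin[q]] = dc[iout[q]];
      }
    dXn = A * W6.t();
    dW6 += Xn.t() * A;
  }
  NumericVector dw((R_xlen_t)kk * Cin * Cout);
  dw.attr("dim") = wd;
  double* dwp = dw.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (size_t o = 0; o < kk; ++o) {
        int di = (int)(o % kh), dj = (int)(o / kh);
        dwp[(R_xlen_t)di + (R_xlen_t)kh * (dj + (R_xlen_t)kw * (ci + (R_xlen_t)Cin * co))] =
          dW6(ci, o + kk * co);
      }
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution: output is stride times the input size (SAME
// semantics); implemented as the adjoint of the matching strided SAME
// convolution big -> small.  Kernel layout (kh, kw, Cin, Cout) with Cin
// the (small) input side.
// [[Rcpp::export]]
NumericVector tconv2d_forward_cpp(NumericVector x, NumericVector w, NumericVector b,
                                  int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("kernel input channels do not match activation channels");
  int oH = H * sh, oW = W * sw;
  ConvGeom g = make_geom(oH, oW, kh, kw, sh, sw);  // big -> small geometry
  arma::uword HW = (arma::uword)H * W, oHW = (arma::uword)oH * oW;
  size_t kk = (size_t)kh * kw;
  arma::mat W6 = kernel_cin_by_kkcout(w, kh, kw, Cin, Cout);
  NumericVector y((R_xlen_t)oHW * Cout * N);
  y.attr("dim") = IntegerVector::create(oH, oW, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (R_xlen_t)n * HW * Cin, HW, Cin, false, true);
    arma::mat Yn(y.begin() + (R_xlen_t)n * oHW * Cout, oHW, Cout, false, true);
    for (int co = 0; co < Cout; ++co) Yn.col(co).fill(b[co]);
    arma::mat P = Xn * W6;  // (small HW x kk*Cout)
    for (int co = 0; co < Cout; ++co)
      for (size_t o = 0; o < kk; ++o) {
        const arma::uvec& ibig = g.in_idx[o];
        const arma::uvec& ismall = g.out_idx[o];
        const double* pc = P.colptr(o + kk * co);
        double* yc = Yn.colptr(co);
        for (arma::uword q = 0; q < ibig.n_elem; ++q) yc[ibig[q]] += pc[ismall[q]];
      }
  }
  return y;
}

// [[Rcpp::export]]
List tconv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                          int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int oH = H * sh, oW = W * sw;
  ConvGeom g = make_geom(oH, oW, kh, kw, sh, sw);
  arma::uword HW = (arma::uword)H * W, oHW = (arma::uword)oH * oW;
  size_t kk = (size_t)kh * kw;
  arma::mat W6 = kernel_cin_by_kkcout(w, kh, kw, Cin, Cout);
  arma::mat dW6(Cin, kk * Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)HW * Cin * N);
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (R_xlen_t)n * HW * Cin, HW, Cin, false, true);
    arma::mat dYn(const_cast<double*>(dy.begin()) + (R_xlen_t)n * oHW * Cout, oHW, Cout, false, true);
    arma::mat dXn(dx.begin() + (R_xlen_t)n * HW * Cin, HW, Cin, false, true);
    db += arma::sum(dYn, 0).t();
    arma::mat A(HW, kk * Cout, arma::fill::zeros);  // small-side patch matrix
    for (int co = 0; co < Cout; ++co)
      for (size_t o = 0; o < kk; ++o) {
        const arma::uvec& ibig = g.in_idx[o];
        const arma::uvec& ismall = g.out_idx[o];
        double* ac = A.colptr(o + kk * co);
        const double* dc = dYn.colptr(co);
        for (arma::uword q = 0; q < ibig.n_elem; ++q) ac[ismall[q]] = dc[ibig[q]];
      }
    dXn = A * W6.t();
    dW6 += Xn.t() * A;
  }
  NumericVector dw((R_xlen_t)kk * Cin * Cout);
  dw.attr("dim") = wd;
  double* dwp = dw.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (size_t o = 0; o < kk; ++o) {
        int di = (int)(o % kh), dj = (int)(o / kh);
        dwp[(R_xlen_t)di + (R_xlen_t)kh * (dj + (R_xlen_t)kw * (ci + (R_xlen_t)Cin * co))] =
          dW6(ci, o + kk * co);
      }
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Fused Adam update: advances the first/second moment buffers in place
// (they are owned exclusively by the optimiser state) and returns the
// updated parameter array. One pass instead of half a dozen vectorised
// temporaries, which matters for the generator's 15M-parameter dense
// kernel.
// [[Rcpp::export]]
NumericVector adam_update_cpp(NumericVector p, NumericVector g,
                              NumericVector m, NumericVector v,
                              double lr, double beta1, double beta2,
                              double eps, double corr1, double corr2) {
  R_xlen_t n = p.size();
  NumericVector out(n);
  out.attr("dim") = p.attr("dim");
  double* mp = m.begin(); double* vp = v.begin();
  const double* gp = g.begin(); const double* pp = p.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
    op[i] = pp[i] - lr * (mp[i] / corr1) / (std::sqrt(vp[i] / corr2) + eps);
  }
  return out;
}

// ---- batch-norm helpers (fused single-pass kernels) ----------------------
// Channel layout: x is (H, W, C, N); element (p, c, n) at p + HW*c + HW*C*n.

// [[Rcpp::export]]
List channel_moments_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t q = 0; q < HW; ++q) { s += p[q]; s2 += p[q] * p[q]; }
    }
    double m = s / ((double)HW * N);
    mean[c] = m;
    var[c] = std::max(s2 / ((double)HW * N) - m * m, 0.0);
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = x * a[c] + b[c]
// [[Rcpp::export]]
NumericVector scale_shift_cpp(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + (R_xlen_t)C * n);
      double* q = y.begin() + HW * (c + (R_xlen_t)C * n);
      double ac = a[c], bc = b[c];
      for (R_xlen_t k = 0; k < HW; ++k) q[k] = p[k] * ac + bc;
    }
  return y;
}

// per-channel sums of dy and of dy * xhat in one pass
// [[Rcpp::export]]
List bn_reduce_cpp(NumericVector dy, NumericVector xhat) {
  IntegerVector xd = dy.attr("dim");
  R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector sdy(C), sdyx(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, sx = 0;
    for (int n = 0; n < N; ++n) {
      R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* d = dy.begin() + off;
      const double* h = xhat.begin() + off;
      for (R_xlen_t q = 0; q < HW; ++q) { s += d[q]; sx += d[q] * h[q]; }
    }
    sdy[c] = s; sdyx[c] = sx;
  }
  return List::create(_["sdy"] = sdy, _["sdyx"] = sdyx);
}

// dx = coef[c] * (dy - sdy[c]/m - xhat * sdyx[c]/m)
// [[Rcpp::export]]
NumericVector bn_dx_cpp(NumericVector dy, NumericVector xhat, NumericVector sdy,
                        NumericVector sdyx, NumericVector coef, double m) {
  IntegerVector xd = dy.attr("dim");
  R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* d = dy.begin() + off;
      const double* h = xhat.begin() + off;
      double* o = dx.begin() + off;
      double a = sdy[c] / m, b = sdyx[c] / m, cf = coef[c];
      for (R_xlen_t q = 0; q < HW; ++q) o[q] = cf * (d[q] - a - h[q] * b);
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector relu_forward_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_backward_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0;
  return dx;
}

// [[Rcpp::export]]
NumericVector leaky_relu_forward_cpp(NumericVector x, double alpha) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : alpha * x[i];
  return y;
}

// [[Rcpp::export]]
NumericVector leaky_relu_backward_cpp(NumericVector dy, NumericVector x, double alpha) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = x[i] > 0 ? dy[i] : alpha * dy[i];
  return dx;
}

// Max pooling, SAME/ceil mode; windows are clipped to the valid region so
// padding never participates. Returns the pooled values and the 0-based
// spatial argmax index used by the backward pass.
// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int kh, int kw, int sh, int sw) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  ConvGeom g = make_geom(H, W, kh, kw, sh, sw);
  arma::uword HW = (arma::uword)H * W, oHW = (arma::uword)g.oH * g.oW;
  NumericVector y((R_xlen_t)oHW * C * N);
  IntegerVector idx((R_xlen_t)oHW * C * N);
  y.attr("dim") = IntegerVector::create(g.oH, g.oW, C, N);
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (R_xlen_t)(n * (R_xlen_t)C + c) * HW;
      R_xlen_t obase = ((R_xlen_t)n * C + c) * oHW;
      for (int oj = 0; oj < g.oW; ++oj) {
        int j0 = std::max(oj * sw - g.pw, 0);
        int j1 = std::min(oj * sw - g.pw + kw, W);
        for (int oi = 0; oi < g.oH; ++oi) {
          int i0 = std::max(oi * sh - g.ph, 0);
          int i1 = std::min(oi * sh - g.ph + kh, H);
          double best = R_NegInf; int bestp = i0 + H * j0;
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i) {
              double v = plane[(R_xlen_t)i + (R_xlen_t)H * j];
              if (v > best) { best = v; bestp = i + H * j; }
            }
          y[obase + oi + (R_xlen_t)g.oH * oj] = best;
          idx[obase + oi + (R_xlen_t)g.oH * oj] = bestp;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx,
                                   int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int oH = yd[0], oW = yd[1], C = yd[2], N = yd[3];
  arma::uword HW = (arma::uword)H * W, oHW = (arma::uword)oH * oW;
  NumericVector dx((R_xlen_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    double* dplane = dx.begin() + cn * HW;
    const double* dyp = dy.begin() + cn * oHW;
    const int* ip = idx.begin() + cn * oHW;
    for (arma::uword q = 0; q < oHW; ++q) dplane[ip[q]] += dyp[q];
  }
  return dx;
}

// Average pooling, SAME/ceil mode, averaging over valid (unpadded) cells.
// [[Rcpp::export]]
NumericVector avgpool_forward_cpp(NumericVector x, int kh, int kw, int sh, int sw) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  ConvGeom g = make_geom(H, W, kh, kw, sh, sw);
  arma::uword HW = (arma::uword)H * W, oHW = (arma::uword)g.oH * g.oW;
  NumericVector y((R_xlen_t)oHW * C * N);
  y.attr("dim") = IntegerVector::create(g.oH, g.oW, C, N);
  const double* xp = x.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* plane = xp + cn * HW;
    double* yp = y.begin() + cn * oHW;
    for (int oj = 0; oj < g.oW; ++oj) {
      int j0 = std::max(oj * sw - g.pw, 0);
      int j1 = std::min(oj * sw - g.pw + kw, W);
      for (int oi = 0; oi < g.oH; ++oi) {
        int i0 = std::max(oi * sh - g.ph, 0);
        int i1 = std::min(oi * sh - g.ph + kh, H);
        double s = 0.0;
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i) s += plane[(R_xlen_t)i + (R_xlen_t)H * j];
        yp[oi + (R_xlen_t)g.oH * oj] = s / ((i1 - i0) * (j1 - j0));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_backward_cpp(NumericVector dy, int H, int W,
                                   int kh, int kw, int sh, int sw) {
  IntegerVector yd = dy.attr("dim");
  int oH = yd[0], oW = yd[1], C = yd[2], N = yd[3];
  ConvGeom g = make_geom(H, W, kh, kw, sh, sw);
  arma::uword HW = (arma::uword)H * W, oHW = (arma::uword)oH * oW;
  NumericVector dx((R_xlen_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    double* dplane = dx.begin() + cn * HW;
    const double* dyp = dy.begin() + cn * oHW;
    for (int oj = 0; oj < oW; ++oj) {
      int j0 = std::max(oj * sw - g.pw, 0);
      int j1 = std::min(oj * sw - g.pw + kw, W);
      for (int oi = 0; oi < oH; ++oi) {
        int i0 = std::max(oi * sh - g.ph, 0);
        int i1 = std::min(oi * sh - g.ph + kh, H);
        double v = dyp[oi + (R_xlen_t)oH * oj] / ((i1 - i0) * (j1 - j0));
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i) dplane[(R_xlen_t)i + (R_xlen_t)H * j] += v;
      }
    }
  }
  return dx;
}
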