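// Generalized 4D (R x D x H x W) valid/padded cross-correlation with
// multi-channel input, plus 2x pooling over the three spatial axes.
// Arrays use R's column-major layout with dim (C, R, D, H, W) for
// activations and (C_out, C_in, Kr, Kd, Kh, Kw) for kernels; the GEMM
// formulation (im2col) keeps the training loop on BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void out_extents(const IntegerVector& xd, const IntegerVector& kd,
                        const IntegerVector& pad, int* od) {
  for (int a = 0; a < 4; ++a) {
    od[a] = xd[a + 1] + 2 * pad[a] - kd[a] + 1;
    if (od[a] < 1) stop("kernel extent exceeds padded input extent on axis %d", a + 1);
  }
}

static arma::mat im2col4(const double* x, const IntegerVector& xd,
                         const IntegerVector& kd, const IntegerVector& pad,
                         const int* od) {
  const int C = xd[0], R = xd[1], D = xd[2], H = xd[3];
  const int Kr = kd[0], Kd = kd[1], Kh = kd[2], Kw = kd[3];
  const int Ro = od[0], Do = od[1], Ho = od[2], Wo = od[3];
  const arma::uword nrow = (arma::uword)C * Kr * Kd * Kh * Kw;
  arma::mat K(nrow, (arma::uword)Ro * Do * Ho * Wo, arma::fill::zeros);
  arma::uword col = 0;
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d)
        for (int r = 0; r < Ro; ++r, ++col) {
          double* Kc = K.colptr(col);
          for (int kw = 0; kw < Kw; ++kw) {
            const int iw = w - pad[3] + kw;
            if (iw < 0 || iw >= xd[4]) continue;
            for (int kh = 0; kh < Kh; ++kh) {
              const int ih = h - pad[2] + kh;
              if (ih < 0 || ih >= H) continue;
              for (int kdd = 0; kdd < Kd; ++kdd) {
                const int id = d - pad[1] + kdd;
                if (id < 0 || id >= D) continue;
                for (int kr = 0; kr < Kr; ++kr) {
                  const int ir = r - pad[0] + kr;
                  if (ir < 0 || ir >= R) continue;
                  const double* src = x + (arma::uword)C *
                    (ir + (arma::uword)R * (id + (arma::uword)D * (ih + (arma::uword)H * iw)));
                  double* dst = Kc + (arma::uword)C *
                    (kr + (arma::uword)Kr * (kdd + (arma::uword)Kd * (kh + (arma::uword)Kh * kw)));
                  std::copy(src, src + C, dst);
                }
              }
            }
          }
        }
  return K;
}

static void col2im4(const arma::mat& K, double* gx, const IntegerVector& xd,
                    const IntegerVector& kd, const IntegerVector& pad,
                    const int* od) {
  const int C = xd[0], R = xd[1], D = xd[2], H = xd[3];
  const int Kr = kd[0], Kd = kd[1], Kh = kd[2], Kw = kd[3];
  const int Ro = od[0], Do = od[1], Ho = od[2], Wo = od[3];
  arma::uword col = 0;
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d)
        for (int r = 0; r < Ro; ++r, ++col) {
          const double* Kc = K.colptr(col);
          for (int kw = 0; kw < Kw; ++kw) {
            const int iw = w - pad[3] + kw;
            if (iw < 0 || iw >= xd[4]) continue;
            for (int kh = 0; kh < Kh; ++kh) {
              const int ih = h - pad[2] + kh;
              if (ih < 0 || ih >= H) continue;
              for (int kdd = 0; kdd < Kd; ++kdd) {
                const int id = d - pad[1] + kdd;
                if (id < 0 || id >= D) continue;
                for (int kr = 0; kr < Kr; ++kr) {
                  const int ir = r - pad[0] + kr;
                  if (ir < 0 || ir >= R) continue;
                  double* dst = gx + (arma::uword)C *
                    (ir + (arma::uword)R * (id + (arma::uword)D * (ih + (arma::uword)H * iw)));
                  const double* src = Kc + (arma::uword)C *
                    (kr + (arma::uword)Kr * (kdd + (arma::uword)Kd * (kh + (arma::uword)Kh * kw)));
                  for (int c = 0; c < C; ++c) dst[c] += src[c];
                }
              }
            }
          }
        }
}

// [[Rcpp::export]]
NumericVector cpp_conv4d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, IntegerVector pad,
                                 double bias_sign) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 5 || wd.size() != 6) stop("bad tensor rank");
  if (xd[0] != wd[1]) stop("input has %d channels but kernel expects %d", xd[0], wd[1]);
  IntegerVector kd = IntegerVector::create(wd[2], wd[3], wd[4], wd[5]);
  int od[4];
  out_extents(xd, kd, pad, od);
  const int Cout = wd[0];
  arma::mat K = im2col4(REAL(x), xd, kd, pad, od);
  const arma::mat Wm(const_cast<double*>(REAL(w)), Cout, K.n_rows, false, true);
  const arma::vec bv(const_cast<double*>(REAL(b)), Cout, false, true);
  arma::mat Y = Wm * K;
  Y.each_col() += bias_sign * bv;
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Cout, od[0], od[1], od[2], od[3]);
  return out;
}

// [[Rcpp::export]]
List cpp_conv4d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         IntegerVector pad, double bias_sign) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector kd = IntegerVector::create(wd[2], wd[3], wd[4], wd[5]);
  int od[4];
  out_extents(xd, kd, pad, od);
  const int Cout = wd[0];
  const arma::uword npos = (arma::uword)od[0] * od[1] * od[2] * od[3];
  arma::mat K = im2col4(REAL(x), xd, kd, pad, od);
  const arma::mat Wm(const_cast<double*>(REAL(w)), Cout, K.n_rows, false, true);
  const arma::mat Gy(const_cast<double*>(REAL(gy)), Cout, npos, false, true);
  arma::mat Gw = Gy * K.t();
  arma::vec Gb = bias_sign * arma::sum(Gy, 1);
  arma::mat Gcols = Wm.t() * Gy;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  col2im4(Gcols, REAL(gx), xd, kd, pad, od);
  NumericVector gw(Gw.begin(), Gw.end());
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(Gb.begin(), Gb.end()));
}

// Pool D, H, W by 2 (extents must be even); the R axis is never pooled.
// Ties go to the first element in scan order, so backward is exact.
// [[Rcpp::export]]
List cpp_maxpool3_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], R = xd[1], D = xd[2], H = xd[3], W = xd[4];
  if (D % 2 || H % 2 || W % 2) stop("pooled extents must be even");
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const double* xp = REAL(x);
  NumericVector y((arma::uword)C * R * Do * Ho * Wo);
  IntegerVector idx(y.size());
  double* yp = REAL(y);
  arma::uword o = 0;
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d)
        for (int r = 0; r < R; ++r)
          for (int c = 0; c < C; ++c, ++o) {
            double best = -std::numeric_limits<double>::infinity();
            arma::uword besti = 0;
            for (int dw = 0; dw < 2; ++dw)
              for (int dh = 0; dh < 2; ++dh)
                for (int dd = 0; dd < 2; ++dd) {
                  arma::uword i = c + (arma::uword)C *
                    (r + (arma::uword)R * ((2 * d + dd) + (arma::uword)D *
                      ((2 * h + dh) + (arma::uword)H * (2 * w + dw))));
                  if (xp[i] > best) { best = xp[i]; besti = i; }
                }
            yp[o] = best;
            idx[o] = (int)besti;
          }
  y.attr("dim") = IntegerVector::create(C, R, Do, Ho, Wo);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3_backward(NumericVector gy, IntegerVector idx,
                                    IntegerVector xdim) {
  arma::uword n = 1;
  for (int a = 0; a < 5; ++a) n *= xdim[a];
  NumericVector gx(n);
  double* gp = REAL(gx);
  const double* gyp = REAL(gy);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gp[idx[i]] += gyp[i];
  gx.attr("dim") = xdim;
  return gx;
}

// ---- single-precision training path -------------------------------------
// The public conv4d op stays in double precision; the training loop uses
// float GEMMs (half the memory traffic) and caches the forward im2col
// matrix for reuse in the backward pass.

static arma::fmat im2col4f(const double* x, const IntegerVector& xd,
                           const IntegerVector& kd, const IntegerVector& pad,
                           const int* od) {
  const int C = xd[0], R = xd[1], D = xd[2], H = xd[3];
  const int Kr = kd[0], Kd = kd[1], Kh = kd[2], Kw = kd[3];
  const int Ro = od[0], Do = od[1], Ho = od[2], Wo = od[3];
  const arma::uword nrow = (arma::uword)C * Kr * Kd * Kh * Kw;
  arma::fmat K(nrow, (arma::uword)Ro * Do * Ho * Wo, arma::fill::zeros);
  arma::uword col = 0;
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d)
        for (int r = 0; r < Ro; ++r, ++col) {
          float* Kc = K.colptr(col);
          for (int kw = 0; kw < Kw; ++kw) {
            const int iw = w - pad[3] + kw;
            if (iw < 0 || iw >= xd[4]) continue;
            for (int kh = 0; kh < Kh; ++kh) {
              const int ih = h - pad[2] + kh;
              if (ih < 0 || ih >= H) continue;
              for (int kdd = 0; kdd < Kd; ++kdd) {
                const int id = d - pad[1] + kdd;
                if (id < 0 || id >= D) continue;
                for (int kr = 0; kr < Kr; ++kr) {
                  const int ir = r - pad[0] + kr;
                  if (ir < 0 || ir >= R) continue;
                  const double* src = x + (arma::uword)C *
                    (ir + (arma::uword)R * (id + (arma::uword)D * (ih + (arma::uword)H * iw)));
                  float* dst = Kc + (arma::uword)C *
                    (kr + (arma::uword)Kr * (kdd + (arma::uword)Kd * (kh + (arma::uword)Kh * kw)));
                  for (int c = 0; c < C; ++c) dst[c] = (float)src[c];
                }
              }
            }
          }
        }
  return K;
}

static void col2im4f(const arma::fmat& K, double* gx, const IntegerVector& xd,
                     const IntegerVector& kd, const IntegerVector& pad,
                     const int* od) {
  const int C = xd[0], R = xd[1], D = xd[2], H = xd[3];
  const int Kr = kd[0], Kd = kd[1], Kh = kd[2], Kw = kd[3];
  const int Ro = od[0], Do = od[1], Ho = od[2], Wo = od[3];
  arma::uword col = 0;
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d)
        for (int r = 0; r < Ro; ++r, ++col) {
          const float* Kc = K.colptr(col);
          for (int kw = 0; kw < Kw; ++kw) {
            const int iw = w - pad[3] + kw;
            if (iw < 0 || iw >= xd[4]) continue;
            for (int kh = 0; kh < Kh; ++kh) {
              const int ih = h - pad[2] + kh;
              if (ih < 0 || ih >= H) continue;
              for (int kdd = 0; kdd < Kd; ++kdd) {
                const int id = d - pad[1] + kdd;
                if (id < 0 || id >= D) continue;
                for (int kr = 0; kr < Kr; ++kr) {
                  const int ir = r - pad[0] + kr;
                  if (ir < 0 || ir >= R) continue;
                  double* dst = gx + (arma::uword)C *
                    (ir + (arma::uword)R * (id + (arma::uword)D * (ih + (arma::uword)H * iw)));
                  const float* src = Kc + (arma::uword)C *
                    (kr + (arma::uword)Kr * (kdd + (arma::uword)Kd * (kh + (arma::uword)Kh * kw)));
                  for (int c = 0; c < C; ++c) dst[c] += (double)src[c];
                }
              }
            }
          }
        }
}

static arma::fmat as_fmat(const double* p, arma::uword nr, arma::uword nc) {
  arma::fmat M(nr, nc);
  const arma::uword n = nr * nc;
  float* dst = M.memptr();
  for (arma::uword i = 0; i < n; ++i) dst[i] = (float)p[i];
  return M;
}

// [[Rcpp::export]]
List cpp_conv4d_forward_train(NumericVector x, NumericVector w,
                              NumericVector b, IntegerVector pad,
                              bool want_cache) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd[0] != wd[1]) stop("input has %d channels but kernel expects %d", xd[0], wd[1]);
  IntegerVector kd = IntegerVector::create(wd[2], wd[3], wd[4], wd[5]);
  int od[4];
  out_extents(xd, kd, pad, od);
  const int Cout = wd[0];
  arma::fmat K = im2col4f(REAL(x), xd, kd, pad, od);
  arma::fmat Wm = as_fmat(REAL(w), Cout, K.n_rows);
  arma::fmat Y = Wm * K;
  arma::fvec bv(Cout);
  for (int c = 0; c < Cout; ++c) bv[c] = (float)REAL(b)[c];
  Y.each_col() += bv;
  NumericVector out(Y.n_elem);
  double* op = REAL(out);
  const float* yp = Y.memptr();
  for (arma::uword i = 0; i < Y.n_elem; ++i) op[i] = (double)yp[i];
  out.attr("dim") = IntegerVector::create(Cout, od[0], od[1], od[2], od[3]);
  if (!want_cache) return List::create(_["y"] = out);
  XPtr<arma::fmat> kp(new arma::fmat(std::move(K)), true);
  return List::create(_["y"] = out, _["k"] = kp);
}

// [[Rcpp::export]]
List cpp_conv4d_backward_train(SEXP kptr, NumericVector w, NumericVector gy,
                               IntegerVector pad, IntegerVector xdim,
                               bool need_gx) {
  XPtr<arma::fmat> K(kptr);
  IntegerVector wd = w.attr("dim");
  IntegerVector kd = IntegerVector::create(wd[2], wd[3], wd[4], wd[5]);
  int od[4];
  out_extents(xdim, kd, pad, od);
  const int Cout = wd[0];
  const arma::uword npos = (arma::uword)od[0] * od[1] * od[2] * od[3];
  arma::fmat Gy = as_fmat(REAL(gy), Cout, npos);
  arma::fmat Gw = Gy * K->t();
  arma::fvec Gb = arma::sum(Gy, 1);
  NumericVector gw(Gw.n_elem);
  for (arma::uword i = 0; i < Gw.n_elem; ++i) REAL(gw)[i] = (double)Gw.memptr()[i];
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  for (int c = 0; c < Cout; ++c) REAL(gb)[c] = (double)Gb[c];
  if (!need_gx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);
  arma::fmat Wm = as_fmat(REAL(w), Cout, K->n_rows);
  arma::fmat Gcols = Wm.t() * Gy;
  arma::uword n = 1;
  for (int a = 0; a < 5; ++a) n *= xdim[a];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  col2im4f(Gcols, REAL(gx), xdim, kd, pad, od);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
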