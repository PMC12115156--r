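// Batched 2-D convolution (cross-correlation) via im2col + GEMM.
// Feature maps are R arrays with dim c(B, C, H, W): element (b,c,h,w) sits
// at b + B*(c + C*(h + H*w)) (0-based). The im2col matrix is laid out
// transposed, [N x C*kh*kw] with N = B*Ho*Wo and n = b + B*(oh + Ho*ow),
// so that every copy runs contiguously over the batch dimension.
// The forward pass can hand the im2col matrix back as an external pointer
// for reuse by the backward pass.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p, int d) {
  return (in + 2 * p - ((k - 1) * d + 1)) / s + 1;
}

struct ConvGeom {
  int B, C, H, W, O, kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo;
};

static ConvGeom geom(IntegerVector xd, IntegerVector wd, IntegerVector stride,
                     IntegerVector pad, IntegerVector dil) {
  ConvGeom g;
  g.B = xd[0]; g.C = xd[1]; g.H = xd[2]; g.W = xd[3];
  g.O = wd[0]; g.kh = wd[2]; g.kw = wd[3];
  g.sh = stride[0]; g.sw = stride[1]; g.ph = pad[0]; g.pw = pad[1];
  g.dh = dil[0]; g.dw = dil[1];
  g.Ho = out_size(g.H, g.kh, g.sh, g.ph, g.dh);
  g.Wo = out_size(g.W, g.kw, g.sw, g.pw, g.dw);
  return g;
}

// cols: [B*Ho*Wo x C*kh*kw]; accumulate=false fills cols from x,
// accumulate=true scatter-adds cols back into x (col2im).
template <bool Accumulate>
static void im2col_t(double* x, const ConvGeom& g, arma::mat& cols) {
  const arma::uword B = g.B;
  for (int j = 0; j < g.kw; ++j) {
    for (int i = 0; i < g.kh; ++i) {
      for (int c = 0; c < g.C; ++c) {
        double* colp = cols.colptr(c + (arma::uword)g.C * (i + g.kh * j));
        for (int ow = 0; ow < g.Wo; ++ow) {
          int w = ow * g.sw - g.pw + j * g.dw;
          if (w < 0 || w >= g.W) continue;
          for (int oh = 0; oh < g.Ho; ++oh) {
            int h = oh * g.sh - g.ph + i * g.dh;
            if (h < 0 || h >= g.H) continue;
            double* src = x + B * (c + (arma::uword)g.C * (h + (arma::uword)g.H * w));
            double* dst = colp + B * (oh + (arma::uword)g.Ho * ow);
            if (Accumulate)
              for (arma::uword b = 0; b < B; ++b) src[b] += dst[b];
            else
              std::memcpy(dst, src, B * sizeof(double));
          }
        }
      }
    }
  }
}

// scatter [N x O] GEMM result into a [B,O,Ho,Wo] array (and the reverse)
static void scatter_out(const arma::mat& Yt, const ConvGeom& g,
                        const double* bias, double* out) {
  const arma::uword B = g.B, HoWo = (arma::uword)g.Ho * g.Wo;
  for (int o = 0; o < g.O; ++o) {
    const double* src = Yt.colptr(o);
    for (arma::uword n = 0; n < HoWo; ++n) {
      double* dst = out + B * (o + (arma::uword)g.O * n);
      const double* s = src + B * n;
      if (bias) {
        double bo = bias[o];
        for (arma::uword b = 0; b < B; ++b) dst[b] = s[b] + bo;
      } else {
        std::memcpy(dst, s, B * sizeof(double));
      }
    }
  }
}

static void gather_out(const double* gy, const ConvGeom& g, arma::mat& Gyt) {
  const arma::uword B = g.B, HoWo = (arma::uword)g.Ho * g.Wo;
  Gyt.set_size(B * HoWo, g.O);
  for (int o = 0; o < g.O; ++o) {
    double* dst = Gyt.colptr(o);
    for (arma::uword n = 0; n < HoWo; ++n)
      std::memcpy(dst + B * n, gy + B * (o + (arma::uword)g.O * n),
                  B * sizeof(double));
  }
}

// [[Rcpp::export]]
List conv2d_fwd_cache(NumericVector x, IntegerVector xd,
                      NumericVector w, IntegerVector wd,
                      NumericVector bias,
                      IntegerVector stride, IntegerVector pad,
                      IntegerVector dil, bool keep_cols) {
  ConvGeom g = geom(xd, wd, stride, pad, dil);
  if (g.Ho < 1 || g.Wo < 1) stop("convolution output would be empty");
  const arma::uword N = (arma::uword)g.B * g.Ho * g.Wo;
  const arma::uword Q = (arma::uword)g.C * g.kh * g.kw;
  arma::mat* cols = new arma::mat();
  if (g.ph == 0 && g.pw == 0) cols->set_size(N, Q);  // every entry written
  else cols->zeros(N, Q);
  im2col_t<false>(x.begin(), g, *cols);
  arma::mat Wm(const_cast<double*>(w.begin()), g.O, Q, false, true);
  arma::mat Yt = (*cols) * Wm.t();           // [N x O]
  NumericVector out((R_xlen_t)g.B * g.O * g.Ho * g.Wo);
  scatter_out(Yt, g, bias.size() == g.O ? bias.begin() : nullptr, out.begin());
  out.attr("dim") = IntegerVector::create(g.B, g.O, g.Ho, g.Wo);
  if (keep_cols) {
    XPtr<arma::mat> xp(cols, true);
    return List::create(Named("y") = out, Named("cols") = xp);
  }
  delete cols;
  return List::create(Named("y") = out);
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias,
                             IntegerVector stride, IntegerVector pad,
                             IntegerVector dil) {
  List r = conv2d_fwd_cache(x, xd, w, wd, bias, stride, pad, dil, false);
  return r["y"];
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(SEXP cols_xp, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector gy,
                    IntegerVector stride, IntegerVector pad,
                    IntegerVector dil, bool need_gx) {
  ConvGeom g = geom(xd, wd, stride, pad, dil);
  XPtr<arma::mat> cols(cols_xp);
  arma::mat Gyt;
  gather_out(gy.begin(), g, Gyt);            // [N x O]
  arma::mat Gwt = cols->t() * Gyt;           // [Q x O]
  NumericVector gw((R_xlen_t)g.O * g.C * g.kh * g.kw);
  {
    const arma::uword Q = Gwt.n_rows;
    for (int o = 0; o < g.O; ++o) {
      const double* src = Gwt.colptr(o);
      for (arma::uword q = 0; q < Q; ++q) gw[o + (arma::uword)g.O * q] = src[q];
    }
  }
  gw.attr("dim") = wd;
  arma::rowvec Gb = arma::sum(Gyt, 0);
  NumericVector gb(Gb.begin(), Gb.end());
  List res = List::create(Named("gw") = gw, Named("gb") = gb);
  if (need_gx) {
    const arma::uword Q = (arma::uword)g.C * g.kh * g.kw;
    arma::mat Wm(const_cast<double*>(w.begin()), g.O, Q, false, true);
    arma::mat Gct = Gyt * Wm;                // [N x Q]
    NumericVector gx((R_xlen_t)g.B * g.C * g.H * g.W);
    im2col_t<true>(gx.begin(), g, Gct);
    gx.attr("dim") = xd;
    res["gx"] = gx;
  }
  return res;
}

// in-place elementwise add: a += b (a must be privately owned by the caller)
// [[Rcpp::export]]
NumericVector add_inplace(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  const double* pb = b.begin();
  double* pa = a.begin();
  for (R_xlen_t i = 0; i < n; ++i) pa[i] += pb[i];
  return a;
}

// fused SiLU: y = x * sigmoid(x); returns y and sigmoid for the backward
// [[Rcpp::export]]
List silu_fwd(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n), s(n);
  const double* px = x.begin();
  double* py = y.begin(); double* ps = s.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double si = 1.0 / (1.0 + std::exp(-px[i]));
    ps[i] = si; py[i] = px[i] * si;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(Named("y") = y, Named("s") = s);
}

// [[Rcpp::export]]
NumericVector silu_bwd(NumericVector g, NumericVector x, NumericVector s) {
  R_xlen_t n = g.size();
  NumericVector out(n);
  const double* pg = g.begin(); const double* px = x.begin();
  const double* ps = s.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double si = ps[i];
    po[i] = pg[i] * (si + px[i] * si * (1.0 - si));
  }
  out.attr("dim") = g.attr("dim");
  return out;
}

// fused ReLU forward and masked backward
// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  const double* px = x.begin(); double* py = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) py[i] = px[i] > 0 ? px[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector g, NumericVector x) {
  R_xlen_t n = g.size();
  NumericVector out(n);
  const double* pg = g.begin(); const double* px = x.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = px[i] > 0 ? pg[i] : 0.0;
  out.attr("dim") = g.attr("dim");
  return out;
}

// y = x * s + t with per-(b,c) vectors recycled over the spatial dims
// [[Rcpp::export]]
NumericVector bc_affine(NumericVector x, NumericVector s, NumericVector t) {
  R_xlen_t n = x.size(), m = s.size();
  NumericVector y(n);
  const double* px = x.begin(); const double* ps = s.begin();
  const double* pt = t.begin();
  double* py = y.begin();
  for (R_xlen_t i = 0, j = 0; i < n; ++i, ++j) {
    if (j == m) j = 0;
    py[i] = px[i] * ps[j] + pt[j];
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// paired per-(b,c) reductions over the spatial dims of a [B,C,H,W] array:
// sg[bc] = sum g, sgx[bc] = sum g*x  (x may equal g for raw moments)
// [[Rcpp::export]]
List bc_sums(NumericVector g, NumericVector x, int BC) {
  R_xlen_t n = g.size();
  NumericVector sg(BC), sgx(BC);
  double* psg = sg.begin(); double* psgx = sgx.begin();
  const double* pg = g.begin(); const double* px = x.begin();
  for (R_xlen_t base = 0; base < n; base += BC) {
    const double* gg = pg + base; const double* xx = px + base;
    for (int j = 0; j < BC; ++j) { psg[j] += gg[j]; psgx[j] += gg[j] * xx[j]; }
  }
  return List::create(Named("s") = sg, Named("sx") = sgx);
}

// y = a*g + b*x + c with per-(b,c) coefficient vectors recycled spatially
// [[Rcpp::export]]
NumericVector bc_lincomb(NumericVector g, NumericVector x,
                         NumericVector a, NumericVector b, NumericVector c) {
  R_xlen_t n = g.size();
  int m = a.size();
  NumericVector y(n);
  double* py = y.begin();
  const double* pg = g.begin(); const double* px = x.begin();
  const double* pa = a.begin(); const double* pb = b.begin();
  const double* pc = c.begin();
  for (R_xlen_t base = 0; base < n; base += m) {
    const double* gg = pg + base; const double* xx = px + base;
    double* yy = py + base;
    for (int j = 0; j < m; ++j) yy[j] = pa[j] * gg[j] + pb[j] * xx[j] + pc[j];
  }
  y.attr("dim") = g.attr("dim");
  return y;
}
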