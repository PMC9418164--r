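#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// C (m x n, ldc) <- alpha * op(A) * op(B) + beta * C, straight BLAS so that
// submatrices of the padded plane stacks can be multiplied in place without
// the copies an expression library would make.
static void dgemm_raw(char ta, char tb, int m, int n, int k, double alpha,
                      const double* A, int lda, const double* B, int ldb,
                      double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, const_cast<double*>(A), &lda,
                  const_cast<double*>(B), &ldb, &beta, C, &ldc FCONE FCONE);
}

// Tensors are plain R arrays in [H, W, C, B] layout (column-major), weights
// [k, k, Cin, Cout].  Convolutions are stride 1 with "same" zero padding and
// odd kernel size.
//
// The convolution is computed on zero-padded planes as k*k shifted GEMMs:
// with Xpad a ((H+2p)(W+2p)*B) x Cin matrix of padded channel planes (all
// batch items stacked) and Ypad the padded output, each kernel tap (dh, dw)
// contributes  Ypad.rows(r) += Xpad.rows(r + delta) * W[dh, dw, , ]  where
// delta is the linear offset of the tap inside a padded plane.  Because the
// halo entries of Xpad are zero, taps never leak across image borders or
// between stacked items, and the halo rows of Ypad are simply cropped.
// This avoids the 9x memory expansion of an explicit im2col.

struct PadShape {
  int H, W, Cin, B, k, pad, Hp, Wp;
  size_t P;  // padded plane size
};

static PadShape pad_shape(IntegerVector xd, IntegerVector wd) {
  PadShape s;
  s.H = xd[0]; s.W = xd[1]; s.Cin = xd[2]; s.B = xd[3];
  s.k = wd[0]; s.pad = s.k / 2;
  s.Hp = s.H + 2 * s.pad; s.Wp = s.W + 2 * s.pad;
  s.P = (size_t)s.Hp * s.Wp;
  return s;
}

// Copy the channel planes of every batch item into the (padded, zeroed)
// stacked matrix: column c, rows [b*P, (b+1)*P).
static void fill_padded(const double* x, const PadShape& s, arma::mat& Xpad) {
  Xpad.zeros();
  for (int b = 0; b < s.B; b++) {
    const double* xb = x + (size_t)b * s.H * s.W * s.Cin;
    for (int c = 0; c < s.Cin; c++) {
      const double* xc = xb + (size_t)c * s.H * s.W;
      double* dst = Xpad.colptr(c) + (size_t)b * s.P;
      for (int w = 0; w < s.W; w++)
        std::copy(xc + (size_t)w * s.H, xc + (size_t)(w + 1) * s.H,
                  dst + (size_t)(w + s.pad) * s.Hp + s.pad);
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x_, NumericVector w_, NumericVector b_) {
  IntegerVector xd = x_.attr("dim");
  IntegerVector wd = w_.attr("dim");
  if (wd[2] != xd[2]) stop("conv2d_fwd: input has %d channels, kernel expects %d",
                           (int)xd[2], (int)wd[2]);
  PadShape s = pad_shape(xd, wd);
  int Cout = wd[3];
  const size_t BP = (size_t)s.B * s.P;
  arma::mat Xpad(BP, s.Cin);
  fill_padded(x_.begin(), s, Xpad);
  arma::mat Ypad(BP, Cout, arma::fill::zeros);
  arma::mat Wab(s.Cin, Cout);
  for (int dw = 0; dw < s.k; dw++) {
    for (int dh = 0; dh < s.k; dh++) {
      for (int ci = 0; ci < s.Cin; ci++)
        for (int co = 0; co < Cout; co++)
          Wab(ci, co) = w_[dh + s.k * (dw + s.k * (ci + (size_t)s.Cin * co))];
      long delta = (dh - s.pad) + (long)s.Hp * (dw - s.pad);
      size_t r0 = delta < 0 ? (size_t)(-delta) : 0;
      size_t r1 = BP - 1 - (delta > 0 ? (size_t)delta : 0);
      dgemm_raw('N', 'N', (int)(r1 - r0 + 1), Cout, s.Cin, 1.0,
                Xpad.memptr() + r0 + delta, (int)BP, Wab.memptr(), s.Cin,
                1.0, Ypad.memptr() + r0, (int)BP);
    }
  }
  NumericVector y_((size_t)s.H * s.W * Cout * s.B);
  y_.attr("dim") = IntegerVector::create(s.H, s.W, Cout, s.B);
  for (int b = 0; b < s.B; b++) {
    double* yb = y_.begin() + (size_t)b * s.H * s.W * Cout;
    for (int co = 0; co < Cout; co++) {
      const double* src = Ypad.colptr(co) + (size_t)b * s.P;
      double* dst = yb + (size_t)co * s.H * s.W;
      double bias = b_[co];
      for (int w = 0; w < s.W; w++) {
        const double* sc = src + (size_t)(w + s.pad) * s.Hp + s.pad;
        double* dc = dst + (size_t)w * s.H;
        for (int h = 0; h < s.H; h++) dc[h] = sc[h] + bias;
      }
    }
  }
  return y_;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x_, NumericVector w_, NumericVector dy_) {
  IntegerVector xd = x_.attr("dim");
  IntegerVector wd = w_.attr("dim");
  PadShape s = pad_shape(xd, wd);
  int Cout = wd[3];
  const size_t BP = (size_t)s.B * s.P;
  arma::mat Xpad(BP, s.Cin);
  fill_padded(x_.begin(), s, Xpad);
  // dYpad: padded copy of dy (halo rows zero)
  arma::mat dYpad(BP, Cout, arma::fill::zeros);
  for (int b = 0; b < s.B; b++) {
    const double* db = dy_.begin() + (size_t)b * s.H * s.W * Cout;
    for (int co = 0; co < Cout; co++) {
      const double* sc = db + (size_t)co * s.H * s.W;
      double* dst = dYpad.colptr(co) + (size_t)b * s.P;
      for (int w = 0; w < s.W; w++)
        std::copy(sc + (size_t)w * s.H, sc + (size_t)(w + 1) * s.H,
                  dst + (size_t)(w + s.pad) * s.Hp + s.pad);
    }
  }
  NumericVector dw_((size_t)s.k * s.k * s.Cin * Cout);
  dw_.attr("dim") = IntegerVector::create(s.k, s.k, s.Cin, Cout);
  NumericVector db_(Cout);
  for (int co = 0; co < Cout; co++) db_[co] = arma::accu(dYpad.col(co));
  arma::mat Wab(s.Cin, Cout);
  arma::mat dXpad(BP, s.Cin, arma::fill::zeros);
  for (int dw2 = 0; dw2 < s.k; dw2++) {
    for (int dh = 0; dh < s.k; dh++) {
      long delta = (dh - s.pad) + (long)s.Hp * (dw2 - s.pad);
      size_t r0 = delta < 0 ? (size_t)(-delta) : 0;
      size_t r1 = BP - 1 - (delta > 0 ? (size_t)delta : 0);
      int m = (int)(r1 - r0 + 1);
      // dW tap: Xpad(shifted)^T * dYpad
      arma::mat dWab(s.Cin, Cout);
      dgemm_raw('T', 'N', s.Cin, Cout, m, 1.0,
                Xpad.memptr() + r0 + delta, (int)BP,
                dYpad.memptr() + r0, (int)BP, 0.0, dWab.memptr(), s.Cin);
      for (int ci = 0; ci < s.Cin; ci++)
        for (int co = 0; co < Cout; co++) {
          dw_[dh + s.k * (dw2 + s.k * (ci + (size_t)s.Cin * co))] = dWab(ci, co);
          Wab(ci, co) = w_[dh + s.k * (dw2 + s.k * (ci + (size_t)s.Cin * co))];
        }
      // dX tap: dYpad * W^T accumulated at the shifted rows
      dgemm_raw('N', 'T', m, s.Cin, Cout, 1.0,
                dYpad.memptr() + r0, (int)BP, Wab.memptr(), s.Cin,
                1.0, dXpad.memptr() + r0 + delta, (int)BP);
    }
  }
  NumericVector dx_((size_t)s.H * s.W * s.Cin * s.B);
  dx_.attr("dim") = IntegerVector::create(s.H, s.W, s.Cin, s.B);
  for (int b = 0; b < s.B; b++) {
    double* xb = dx_.begin() + (size_t)b * s.H * s.W * s.Cin;
    for (int ci = 0; ci < s.Cin; ci++) {
      const double* src = dXpad.colptr(ci) + (size_t)b * s.P;
      double* dst = xb + (size_t)ci * s.H * s.W;
      for (int w = 0; w < s.W; w++)
        std::copy(src + (size_t)(w + s.pad) * s.Hp + s.pad,
                  src + (size_t)(w + s.pad) * s.Hp + s.pad + s.H,
                  dst + (size_t)w * s.H);
    }
  }
  return List::create(_["dx"] = dx_, _["dw"] = dw_, _["db"] = db_);
}

// 2x2 max pooling, stride 2; idx stores the within-plane linear offset of the
// argmax (0-based), needed for the backward scatter.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x_) {
  IntegerVector xd = x_.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y_((size_t)Ho * Wo * C * B);
  y_.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx_((size_t)Ho * Wo * C * B);
  size_t q = 0;
  for (int b = 0; b < B; b++) {
    for (int c = 0; c < C; c++) {
      const double* xp = x_.begin() + ((size_t)b * C + c) * H * W;
      for (int wo = 0; wo < Wo; wo++) {
        for (int ho = 0; ho < Ho; ho++) {
          int h0 = 2 * ho, w0 = 2 * wo;
          int best = h0 + H * w0;
          double bv = xp[best];
          int cand[3] = {h0 + 1 + H * w0, h0 + H * (w0 + 1), h0 + 1 + H * (w0 + 1)};
          for (int t = 0; t < 3; t++)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          y_[q] = bv;
          idx_[q] = best;
          q++;
        }
      }
    }
  }
  return List::create(_["y"] = y_, _["idx"] = idx_);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx_, NumericVector dy_, int H, int W) {
  IntegerVector yd = dy_.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  NumericVector dx_((size_t)H * W * C * B);
  dx_.attr("dim") = IntegerVector::create(H, W, C, B);
  size_t q = 0;
  for (int b = 0; b < B; b++) {
    for (int c = 0; c < C; c++) {
      double* dxp = dx_.begin() + ((size_t)b * C + c) * H * W;
      for (size_t p = 0; p < (size_t)Ho * Wo; p++, q++) dxp[idx_[q]] += dy_[q];
    }
  }
  return dx_;
}

// Transposed convolution, kernel 2, stride 2 (the decoder upsampler):
// y[2i+a, 2j+b, co] = sum_ci x[i, j, ci] * w[a, b, ci, co] + bias[co]
// [[Rcpp::export]]
NumericVector upconv2_fwd(NumericVector x_, NumericVector w_, NumericVector b_) {
  IntegerVector xd = x_.attr("dim");
  IntegerVector wd = w_.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W;
  NumericVector y_((size_t)Ho * Wo * Cout * B);
  y_.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  // stack the batch: X is (B*HW) x Cin
  arma::mat X((size_t)B * HW, Cin);
  for (int bb = 0; bb < B; bb++) {
    const double* xp = x_.begin() + (size_t)bb * HW * Cin;
    for (int ci = 0; ci < Cin; ci++)
      std::copy(xp + (size_t)ci * HW, xp + (size_t)(ci + 1) * HW,
                X.colptr(ci) + (size_t)bb * HW);
  }
  arma::mat Wab(Cin, Cout);
  for (int a = 0; a < 2; a++) {
    for (int bq = 0; bq < 2; bq++) {
      for (int ci = 0; ci < Cin; ci++)
        for (int co = 0; co < Cout; co++)
          Wab(ci, co) = w_[a + 2 * bq + 4 * (ci + (size_t)Cin * co)];
      arma::mat Y = X * Wab;  // (B*HW) x Cout
      for (int bb = 0; bb < B; bb++) {
        double* yp = y_.begin() + (size_t)bb * Ho * Wo * Cout;
        for (int co = 0; co < Cout; co++) {
          double* dst = yp + (size_t)co * Ho * Wo;
          const double* src = Y.colptr(co) + (size_t)bb * HW;
          for (int w2 = 0; w2 < W; w2++) {
            double* dcol = dst + (size_t)Ho * (2 * w2 + bq) + a;
            const double* scol = src + (size_t)H * w2;
            for (int h2 = 0; h2 < H; h2++) dcol[2 * h2] += scol[h2];
          }
        }
      }
    }
  }
  for (int bb = 0; bb < B; bb++) {
    double* yp = y_.begin() + (size_t)bb * Ho * Wo * Cout;
    for (int co = 0; co < Cout; co++) {
      double bias = b_[co];
      double* dst = yp + (size_t)co * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; p++) dst[p] += bias;
    }
  }
  return y_;
}

// [[Rcpp::export]]
List upconv2_bwd(NumericVector x_, NumericVector w_, NumericVector dy_) {
  IntegerVector xd = x_.attr("dim");
  IntegerVector wd = w_.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W;
  NumericVector dx_(HW * Cin * B);
  dx_.attr("dim") = IntegerVector::create(H, W, Cin, B);
  NumericVector dw_((size_t)4 * Cin * Cout);
  dw_.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  NumericVector db_(Cout);
  arma::mat X((size_t)B * HW, Cin);
  arma::mat dX((size_t)B * HW, Cin, arma::fill::zeros);
  arma::mat dYab((size_t)B * HW, Cout);
  for (int bb = 0; bb < B; bb++) {
    const double* xp = x_.begin() + (size_t)bb * HW * Cin;
    for (int ci = 0; ci < Cin; ci++)
      std::copy(xp + (size_t)ci * HW, xp + (size_t)(ci + 1) * HW,
                X.colptr(ci) + (size_t)bb * HW);
    const double* dyp = dy_.begin() + (size_t)bb * Ho * Wo * Cout;
    for (int co = 0; co < Cout; co++) {
      const double* src = dyp + (size_t)co * Ho * Wo;
      double acc = 0.0;
      for (size_t p = 0; p < (size_t)Ho * Wo; p++) acc += src[p];
      db_[co] += acc;
    }
  }
  arma::mat Wab(Cin, Cout);
  for (int a = 0; a < 2; a++) {
    for (int bq = 0; bq < 2; bq++) {
      for (int bb = 0; bb < B; bb++) {
        const double* dyp = dy_.begin() + (size_t)bb * Ho * Wo * Cout;
        for (int co = 0; co < Cout; co++) {
          const double* src = dyp + (size_t)co * Ho * Wo;
          double* dst = dYab.colptr(co) + (size_t)bb * HW;
          for (int w2 = 0; w2 < W; w2++) {
            const double* scol = src + (size_t)Ho * (2 * w2 + bq) + a;
            double* dcol = dst + (size_t)H * w2;
            for (int h2 = 0; h2 < H; h2++) dcol[h2] = scol[2 * h2];
          }
        }
      }
      for (int ci = 0; ci < Cin; ci++)
        for (int co = 0; co < Cout; co++)
          Wab(ci, co) = w_[a + 2 * bq + 4 * (ci + (size_t)Cin * co)];
      dX += dYab * Wab.t();
      arma::mat dW = X.t() * dYab;  // Cin x Cout
      for (int ci = 0; ci < Cin; ci++)
        for (int co = 0; co < Cout; co++)
          dw_[a + 2 * bq + 4 * (ci + (size_t)Cin * co)] += dW(ci, co);
    }
  }
  for (int bb = 0; bb < B; bb++) {
    double* dxp = dx_.begin() + (size_t)bb * HW * Cin;
    for (int ci = 0; ci < Cin; ci++)
      std::copy(dX.colptr(ci) + (size_t)bb * HW,
                dX.colptr(ci) + (size_t)(bb + 1) * HW,
                dxp + (size_t)ci * HW);
  }
  return List::create(_["dx"] = dx_, _["dw"] = dw_, _["db"] = db_);
}

// ---- attention helpers ------------------------------------------------------

// Per-pixel statistics over the channel axis of x[H,W,C,B]: mean, max and the
// 1-based linear index (into the full array) of the argmax channel.
// [[Rcpp::export]]
List ch_stats(NumericVector x_) {
  IntegerVector xd = x_.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector mean_(HW * B), max_(HW * B);
  IntegerVector amax_(HW * B);
  for (int b = 0; b < B; b++) {
    const double* xb = x_.begin() + (size_t)b * HW * C;
    double* mn = mean_.begin() + (size_t)b * HW;
    double* mx = max_.begin() + (size_t)b * HW;
    int* am = amax_.begin() + (size_t)b * HW;
    for (size_t p = 0; p < HW; p++) {
      double s = xb[p], best = xb[p];
      int bi = 0;
      for (int c = 1; c < C; c++) {
        double v = xb[p + (size_t)c * HW];
        s += v;
        if (v > best) { best = v; bi = c; }
      }
      mn[p] = s / C;
      mx[p] = best;
      am[p] = (int)((size_t)b * HW * C + (size_t)bi * HW + p + 1);
    }
  }
  return List::create(_["mean"] = mean_, _["max"] = max_, _["amax"] = amax_);
}

// Per-pixel channel inner product sum_c a[.,.,c,b] * x[.,.,c,b] -> HW*B.
// [[Rcpp::export]]
NumericVector ch_dot(NumericVector a_, NumericVector x_) {
  IntegerVector xd = x_.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector out_(HW * B);
  for (int b = 0; b < B; b++) {
    const double* ab = a_.begin() + (size_t)b * HW * C;
    const double* xb = x_.begin() + (size_t)b * HW * C;
    double* ob = out_.begin() + (size_t)b * HW;
    for (int c = 0; c < C; c++) {
      const double* ac = ab + (size_t)c * HW;
      const double* xc = xb + (size_t)c * HW;
      for (size_t p = 0; p < HW; p++) ob[p] += ac[p] * xc[p];
    }
  }
  return out_;
}

// Per-column max and 1-based argmax row of x viewed as (nrow x ncol).
// [[Rcpp::export]]
List colmax_idx(NumericVector x_, int nrow) {
  size_t n = x_.size();
  int ncol = (int)(n / nrow);
  NumericVector max_(ncol);
  IntegerVector idx_(ncol);
  for (int j = 0; j < ncol; j++) {
    const double* cp = x_.begin() + (size_t)j * nrow;
    double best = cp[0];
    int bi = 0;
    for (int i = 1; i < nrow; i++)
      if (cp[i] > best) { best = cp[i]; bi = i; }
    max_[j] = best;
    idx_[j] = bi + 1;
  }
  return List::create(_["max"] = max_, _["idx"] = idx_);
}

// ---- instance normalization -------------------------------------------------

// Per-(channel, batch-item) plane normalization with learnable per-channel
// scale and shift: y = g[c] * (x - mean) / sqrt(var + eps) + b[c].
// No running statistics are kept: inference uses the same per-sample
// statistics, so teacher and student need no buffer synchronisation.
// [[Rcpp::export]]
List instnorm_fwd(NumericVector x_, NumericVector g_, NumericVector b_,
                  double eps) {
  IntegerVector xd = x_.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y_(x_.size()), xhat_(x_.size());
  y_.attr("dim") = xd;
  xhat_.attr("dim") = xd;
  NumericVector istd_((size_t)C * B);
  for (int b = 0; b < B; b++) {
    for (int c = 0; c < C; c++) {
      const double* xp = x_.begin() + ((size_t)b * C + c) * HW;
      double* yp = y_.begin() + ((size_t)b * C + c) * HW;
      double* hp = xhat_.begin() + ((size_t)b * C + c) * HW;
      double mu = 0.0;
      for (size_t p = 0; p < HW; p++) mu += xp[p];
      mu /= HW;
      double var = 0.0;
      for (size_t p = 0; p < HW; p++) { double d = xp[p] - mu; var += d * d; }
      var /= HW;
      double is = 1.0 / std::sqrt(var + eps);
      istd_[(size_t)b * C + c] = is;
      double gc = g_[c], bc = b_[c];
      for (size_t p = 0; p < HW; p++) {
        double h = (xp[p] - mu) * is;
        hp[p] = h;
        yp[p] = gc * h + bc;
      }
    }
  }
  return List::create(_["y"] = y_, _["xhat"] = xhat_, _["istd"] = istd_);
}

// [[Rcpp::export]]
List instnorm_bwd(NumericVector xhat_, NumericVector istd_, NumericVector g_,
                  NumericVector dy_) {
  IntegerVector xd = xhat_.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector dx_(xhat_.size());
  dx_.attr("dim") = xd;
  NumericVector dg_(C), db_(C);
  for (int b = 0; b < B; b++) {
    for (int c = 0; c < C; c++) {
      const double* hp = xhat_.begin() + ((size_t)b * C + c) * HW;
      const double* dp = dy_.begin() + ((size_t)b * C + c) * HW;
      double* xp = dx_.begin() + ((size_t)b * C + c) * HW;
      double sum_dy = 0.0, sum_dyh = 0.0;
      for (size_t p = 0; p < HW; p++) {
        sum_dy += dp[p];
        sum_dyh += dp[p] * hp[p];
      }
      dg_[c] += sum_dyh;
      db_[c] += sum_dy;
      double gc = g_[c], is = istd_[(size_t)b * C + c];
      double m_dy = sum_dy / HW, m_dyh = sum_dyh / HW;
      for (size_t p = 0; p < HW; p++)
        xp[p] = gc * is * (dp[p] - m_dy - hp[p] * m_dyh);
    }
  }
  return List::create(_["dx"] = dx_, _["dg"] = dg_, _["db"] = db_);
}
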