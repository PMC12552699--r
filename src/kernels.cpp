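#include <Rcpp.h>
using namespace Rcpp;

// Column-major tensor layout throughout: x[h + H*(w + W*c)] for an H x W x C array,
// matching how R stores array(dim = c(H, W, C)).

// Grouped 2-D convolution, stride 1, zero padding (k-1)/2 ("same").
// x: H x W x Cin; w: k x k x cin_g x Cout (cin_g = Cin/groups); b: Cout.
// Output channel oc belongs to group oc / (Cout/groups) and sees input channels
// [g*cin_g, (g+1)*cin_g).
// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int H, int W, int Cin, int Cout, int k, int groups) {
  const int cin_g = Cin / groups;
  const int cout_g = Cout / groups;
  const int pad = (k - 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout);
  const double *px = x.begin();
  const double *pw = w.begin();
  double *py = y.begin();

  for (int oc = 0; oc < Cout; ++oc) {
    const int g = oc / cout_g;
    const double bias = b[oc];
    double *yc = py + static_cast<R_xlen_t>(H) * W * oc;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        yc[i + H * j] = bias;
    for (int icl = 0; icl < cin_g; ++icl) {
      const int ic = g * cin_g + icl;
      const double *xc = px + static_cast<R_xlen_t>(H) * W * ic;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          // weight index: kh + k*(kw + k*(icl + cin_g*oc))
          const double wv = pw[kh + k * (kw + k * (icl + cin_g * oc))];
          if (wv == 0.0) continue;
          const int di = kh - pad, dj = kw - pad;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          for (int j = j0; j < j1; ++j) {
            const double *xcol = xc + H * (j + dj) + di;
            double *ycol = yc + H * j;
            for (int i = i0; i < i1; ++i)
              ycol[i] += wv * xcol[i];
          }
        }
      }
    }
  }
  return y;
}

// Backward pass of conv2d_fwd. gy: H x W x Cout. Returns gx, gw, gb.
// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int H, int W, int Cin, int Cout, int k, int groups) {
  const int cin_g = Cin / groups;
  const int cout_g = Cout / groups;
  const int pad = (k - 1) / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * Cin);
  NumericVector gw(w.size());
  NumericVector gb(Cout);
  const double *px = x.begin();
  const double *pw = w.begin();
  const double *pg = gy.begin();
  double *pgx = gx.begin();
  double *pgw = gw.begin();

  for (int oc = 0; oc < Cout; ++oc) {
    const int g = oc / cout_g;
    const double *gc = pg + static_cast<R_xlen_t>(H) * W * oc;
    double s = 0.0;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        s += gc[i + H * j];
    gb[oc] = s;
    for (int icl = 0; icl < cin_g; ++icl) {
      const int ic = g * cin_g + icl;
      const double *xc = px + static_cast<R_xlen_t>(H) * W * ic;
      double *gxc = pgx + static_cast<R_xlen_t>(H) * W * ic;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const int widx = kh + k * (kw + k * (icl + cin_g * oc));
          const double wv = pw[widx];
          const int di = kh - pad, dj = kw - pad;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          double acc = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double *xcol = xc + H * (j + dj) + di;
            double *gxcol = gxc + H * (j + dj) + di;
            const double *gcol = gc + H * j;
            for (int i = i0; i < i1; ++i) {
              acc += gcol[i] * xcol[i];
              gxcol[i] += gcol[i] * wv;
            }
          }
          pgw[widx] += acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 3x3 max pooling, stride 2, zero-padding 1 (padded values treated as -Inf so
// they never win). Output is ceil(H/2) x ceil(W/2) per channel; for even H this
// is H/2. Also returns the within-plane argmax (0-based h + H*w) for backward.
// [[Rcpp::export]]
List maxpool3_fwd(NumericVector x, int H, int W, int C) {
  const int Ho = (H + 2 - 3) / 2 + 1;
  const int Wo = (W + 2 - 3) / 2 + 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  IntegerVector am(static_cast<R_xlen_t>(Ho) * Wo * C);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = am.begin();

  for (int c = 0; c < C; ++c) {
    const double *xc = px + static_cast<R_xlen_t>(H) * W * c;
    double *yc = py + static_cast<R_xlen_t>(Ho) * Wo * c;
    int *ac = pa + static_cast<R_xlen_t>(Ho) * Wo * c;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int i_base = 2 * io - 1, j_base = 2 * jo - 1;
        double best = R_NegInf;
        int best_idx = -1;
        for (int dj = 0; dj < 3; ++dj) {
          const int j = j_base + dj;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < 3; ++di) {
            const int i = i_base + di;
            if (i < 0 || i >= H) continue;
            const double v = xc[i + H * j];
            if (v > best) { best = v; best_idx = i + H * j; }
          }
        }
        yc[io + Ho * jo] = best;
        ac[io + Ho * jo] = best_idx;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am, _["Ho"] = Ho, _["Wo"] = Wo);
}

// [[Rcpp::export]]
NumericVector maxpool3_bwd(IntegerVector argmax, NumericVector gy,
                           int H, int W, int C, int Ho, int Wo) {
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C);
  const int *pa = argmax.begin();
  const double *pg = gy.begin();
  double *pgx = gx.begin();
  for (int c = 0; c < C; ++c) {
    const int *ac = pa + static_cast<R_xlen_t>(Ho) * Wo * c;
    const double *gc = pg + static_cast<R_xlen_t>(Ho) * Wo * c;
    double *gxc = pgx + static_cast<R_xlen_t>(H) * W * c;
    const int n = Ho * Wo;
    for (int t = 0; t < n; ++t)
      gxc[ac[t]] += gc[t];
  }
  return gx;
}

// y = x * scale[col] + shift[col] for an n x C column-major matrix.
// [[Rcpp::export]]
NumericVector affine_cols(NumericVector x, NumericVector scale,
                          NumericVector shift, int n, int C) {
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double s = scale[c], b = shift[c];
    const double *xc = px + static_cast<R_xlen_t>(n) * c;
    double *yc = py + static_cast<R_xlen_t>(n) * c;
    for (int i = 0; i < n; ++i) yc[i] = xc[i] * s + b;
  }
  return y;
}

// Training-mode batch-norm backward for per-column statistics.
// gm, xhat: n x C; returns gx plus per-column gamma/beta gradients.
// [[Rcpp::export]]
List bn_bwd_core(NumericVector gm, NumericVector xhat, NumericVector gamma,
                 NumericVector invstd, int n, int C) {
  NumericVector gx(gm.size()), ggamma(C), gbeta(C);
  const double *pg = gm.begin();
  const double *px = xhat.begin();
  double *pgx = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double *gc = pg + static_cast<R_xlen_t>(n) * c;
    const double *xc = px + static_cast<R_xlen_t>(n) * c;
    double sg = 0.0, sgx = 0.0;
    for (int i = 0; i < n; ++i) { sg += gc[i]; sgx += gc[i] * xc[i]; }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    const double g_ = gamma[c];
    const double m1 = g_ * sg / n;          // mean of gxhat
    const double m2 = g_ * sgx / n;         // mean of gxhat * xhat
    const double is = invstd[c];
    double *gxc = pgx + static_cast<R_xlen_t>(n) * c;
    for (int i = 0; i < n; ++i)
      gxc[i] = (g_ * gc[i] - m1 - xc[i] * m2) * is;
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) py[i] = px[i] > 0.0 ? px[i] : 0.0;
  return y;
}

// gx = gy where y > 0 else 0 (post-activation mask).
// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector y, NumericVector gy) {
  NumericVector gx(y.size());
  const double *py = y.begin();
  const double *pg = gy.begin();
  double *pgx = gx.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) pgx[i] = py[i] > 0.0 ? pg[i] : 0.0;
  return gx;
}
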