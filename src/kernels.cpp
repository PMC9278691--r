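// Low-level 3D convolution / pooling / upsampling kernels.
//
// Feature maps are passed as dense matrices with one row per voxel and one
// column per channel; voxels are ordered column-major in (x, y, z), i.e. the
// linear index of voxel (x, y, z) is x + y*d1 + z*d1*d2 (0-based), matching
// how an R array of dim c(d1, d2, d3) flattens.
//
// Convolution weights are stored as a (k^3 * C_in) x C_out matrix whose rows
// are grouped in k^3 blocks, one per kernel tap, channels contiguous within a
// block. Tap order: z-offset outermost, then y, then x (each -1..1 for the
// "same" 3x3x3 case, 0..1 for the stride-2 2x2x2 case).
//
// The 3x3x3 "same" convolution exploits the fact that a voxel shift by
// (ox, oy, oz) is a constant offset s = ox + oy*d1 + oz*d1*d2 in the linear
// row index: each kernel tap is one GEMM over the overlapping row ranges of
// the input itself (no im2col copy), followed by a correction pass over the
// few rows where the x or y coordinate wraps across a grid face. Rows whose
// z coordinate leaves the grid fall outside the clamped row range, so they
// need no correction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Row indices v inside [lo, hi] whose shifted voxel v + s crosses an x or y
// grid face for tap offset (ox, oy): these received a wrong contribution
// from the range GEMM and must be corrected.
static std::vector<uword> wrap_rows(int d1, int d2, int d3,
                                    int ox, int oy,
                                    uword lo, uword hi) {
  std::vector<uword> idx;
  if (ox == 0 && oy == 0) return idx;
  const int ybad = (oy == 1) ? d2 - 1 : 0;
  const int xbad = (ox == 1) ? d1 - 1 : 0;
  for (int z = 0; z < d3; ++z) {
    const uword zb = (uword)z * d1 * d2;
    if (oy != 0) {
      // whole x-run at the wrapped y face
      const uword r = zb + (uword)ybad * d1;
      for (int x = 0; x < d1; ++x) {
        const uword v = r + x;
        if (v >= lo && v <= hi) idx.push_back(v);
      }
    }
    if (ox != 0) {
      // single wrapped x per (y, z), skipping the already-counted y face
      for (int y = 0; y < d2; ++y) {
        if (oy != 0 && y == ybad) continue;
        const uword v = zb + (uword)y * d1 + xbad;
        if (v >= lo && v <= hi) idx.push_back(v);
      }
    }
  }
  return idx;
}

template <typename MT, typename VT>
static MT conv3_fwd_impl(const MT &Xf, int d1, int d2, int d3,
                         const MT &Wf, const VT &bf) {
  const uword C = Xf.n_cols, F = Wf.n_cols, n = Xf.n_rows;
  MT Y(n, F);
  Y.each_row() = bf.t();
  int o = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox, ++o) {
        const long s = ox + (long)oy * d1 + (long)oz * d1 * d2;
        const uword lo = (s < 0) ? (uword)(-s) : 0;
        const uword hi = (s > 0) ? n - 1 - (uword)s : n - 1;
        if (hi < lo || hi >= n) continue;
        const MT Wo = Wf.rows(o * C, (o + 1) * C - 1);
        Y.rows(lo, hi) += Xf.rows(lo + s, hi + s) * Wo;
        const std::vector<uword> bad = wrap_rows(d1, d2, d3, ox, oy, lo, hi);
        if (!bad.empty()) {
          MT Xg(bad.size(), C);
          for (uword i = 0; i < bad.size(); ++i)
            Xg.row(i) = Xf.row(bad[i] + s);
          const MT Cg = Xg * Wo;
          for (uword i = 0; i < bad.size(); ++i)
            Y.row(bad[i]) -= Cg.row(i);
        }
      }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat &X, int d1, int d2, int d3,
                        const arma::mat &W, const arma::vec &b,
                        bool use_double = false) {
  if (use_double) return conv3_fwd_impl<mat, vec>(X, d1, d2, d3, W, b);
  // single-precision compute path: the network trains in float32, the
  // interface stays double
  const fmat Xf = conv_to<fmat>::from(X);
  const fmat Wf = conv_to<fmat>::from(W);
  const fvec bf = conv_to<fvec>::from(b);
  return conv_to<mat>::from(conv3_fwd_impl<fmat, fvec>(Xf, d1, d2, d3, Wf, bf));
}

template <typename MT>
static void conv3_bwd_impl(const MT &Xf, int d1, int d2, int d3,
                           const MT &Wf, const MT &gYf,
                           MT &gW, MT &gX) {
  const uword C = Xf.n_cols, n = Xf.n_rows;
  gW.zeros(27 * C, Wf.n_cols);
  gX.zeros(n, C);
  int o = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox, ++o) {
        const long s = ox + (long)oy * d1 + (long)oz * d1 * d2;
        const uword lo = (s < 0) ? (uword)(-s) : 0;
        const uword hi = (s > 0) ? n - 1 - (uword)s : n - 1;
        if (hi < lo || hi >= n) continue;
        const MT Wo = Wf.rows(o * C, (o + 1) * C - 1);
        gW.rows(o * C, (o + 1) * C - 1) =
          Xf.rows(lo + s, hi + s).t() * gYf.rows(lo, hi);
        {
          const MT T = gYf.rows(lo, hi) * Wo.t();
          gX.rows(lo + s, hi + s) += T;
        }
        const std::vector<uword> bad = wrap_rows(d1, d2, d3, ox, oy, lo, hi);
        if (!bad.empty()) {
          MT Xg(bad.size(), C), Gg(bad.size(), Wf.n_cols);
          for (uword i = 0; i < bad.size(); ++i) {
            Xg.row(i) = Xf.row(bad[i] + s);
            Gg.row(i) = gYf.row(bad[i]);
          }
          gW.rows(o * C, (o + 1) * C - 1) -= Xg.t() * Gg;
          const MT Tg = Gg * Wo.t();
          for (uword i = 0; i < bad.size(); ++i)
            gX.row(bad[i] + s) -= Tg.row(i);
        }
      }
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd(const arma::mat &X, int d1, int d2, int d3,
                         const arma::mat &W, const arma::mat &gY,
                         bool use_double = false) {
  vec gb = sum(gY, 0).t();
  if (use_double) {
    mat gW, gX;
    conv3_bwd_impl<mat>(X, d1, d2, d3, W, gY, gW, gX);
    return Rcpp::List::create(Rcpp::Named("gX") = gX,
                              Rcpp::Named("gW") = gW,
                              Rcpp::Named("gb") = gb);
  }
  const fmat Xf = conv_to<fmat>::from(X);
  const fmat Wf = conv_to<fmat>::from(W);
  const fmat gYf = conv_to<fmat>::from(gY);
  fmat gW, gX;
  conv3_bwd_impl<fmat>(Xf, d1, d2, d3, Wf, gYf, gW, gX);
  return Rcpp::List::create(Rcpp::Named("gX") = conv_to<mat>::from(gX),
                            Rcpp::Named("gW") = conv_to<mat>::from(gW),
                            Rcpp::Named("gb") = gb);
}

// 2x2x2 convolution with stride 2 (no padding); input dims must be even.
// [[Rcpp::export]]
arma::mat cpp_conv2s2_fwd(const arma::mat &X, int d1, int d2, int d3,
                          const arma::mat &W, const arma::vec &b) {
  const uword C = X.n_cols, F = W.n_cols;
  const int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  const uword m = (uword)e1 * e2 * e3;
  mat Y(m, F);
  Y.each_row() = b.t();
  mat G(m, C);
  int o = 0;
  for (int oz = 0; oz <= 1; ++oz)
    for (int oy = 0; oy <= 1; ++oy)
      for (int ox = 0; ox <= 1; ++ox, ++o) {
        for (int z = 0; z < e3; ++z)
          for (int y = 0; y < e2; ++y)
            for (int x = 0; x < e1; ++x) {
              const uword u = x + (uword)y * e1 + (uword)z * e1 * e2;
              const uword v = (2 * x + ox) + (uword)(2 * y + oy) * d1 +
                              (uword)(2 * z + oz) * d1 * d2;
              G.row(u) = X.row(v);
            }
        Y += G * W.rows(o * C, (o + 1) * C - 1);
      }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2s2_bwd(const arma::mat &X, int d1, int d2, int d3,
                           const arma::mat &W, const arma::mat &gY) {
  const uword C = X.n_cols, n = X.n_rows;
  const int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  const uword m = (uword)e1 * e2 * e3;
  mat gW(8 * C, W.n_cols), gX(n, C, fill::zeros), G(m, C);
  vec gb = sum(gY, 0).t();
  int o = 0;
  for (int oz = 0; oz <= 1; ++oz)
    for (int oy = 0; oy <= 1; ++oy)
      for (int ox = 0; ox <= 1; ++ox, ++o) {
        for (int z = 0; z < e3; ++z)
          for (int y = 0; y < e2; ++y)
            for (int x = 0; x < e1; ++x) {
              const uword u = x + (uword)y * e1 + (uword)z * e1 * e2;
              const uword v = (2 * x + ox) + (uword)(2 * y + oy) * d1 +
                              (uword)(2 * z + oz) * d1 * d2;
              G.row(u) = X.row(v);
            }
        gW.rows(o * C, (o + 1) * C - 1) = G.t() * gY;
        mat T = gY * W.rows(o * C, (o + 1) * C - 1).t();
        for (int z = 0; z < e3; ++z)
          for (int y = 0; y < e2; ++y)
            for (int x = 0; x < e1; ++x) {
              const uword u = x + (uword)y * e1 + (uword)z * e1 * e2;
              const uword v = (2 * x + ox) + (uword)(2 * y + oy) * d1 +
                              (uword)(2 * z + oz) * d1 * d2;
              gX.row(v) += T.row(u);
            }
      }
  return Rcpp::List::create(Rcpp::Named("gX") = gX,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2x2 max pooling, stride 2; returns pooled values and 1-based argmax rows.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::mat &X, int d1, int d2, int d3) {
  const uword C = X.n_cols;
  const int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  const uword m = (uword)e1 * e2 * e3;
  mat Y(m, C);
  umat IDX(m, C);
  for (int z = 0; z < e3; ++z)
    for (int y = 0; y < e2; ++y)
      for (int x = 0; x < e1; ++x) {
        const uword u = x + (uword)y * e1 + (uword)z * e1 * e2;
        uword vs[8];
        int q = 0;
        for (int oz = 0; oz <= 1; ++oz)
          for (int oy = 0; oy <= 1; ++oy)
            for (int ox = 0; ox <= 1; ++ox)
              vs[q++] = (2 * x + ox) + (uword)(2 * y + oy) * d1 +
                        (uword)(2 * z + oz) * d1 * d2;
        for (uword c = 0; c < C; ++c) {
          double best = X(vs[0], c);
          uword bi = vs[0];
          for (int t = 1; t < 8; ++t)
            if (X(vs[t], c) > best) { best = X(vs[t], c); bi = vs[t]; }
          Y(u, c) = best;
          IDX(u, c) = bi + 1;
        }
      }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = IDX);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::mat &gY, const arma::umat &IDX, int n) {
  const uword C = gY.n_cols, m = gY.n_rows;
  mat gX(n, C, fill::zeros);
  for (uword c = 0; c < C; ++c)
    for (uword u = 0; u < m; ++u)
      gX(IDX(u, c) - 1, c) += gY(u, c);
  return gX;
}

// Nearest-neighbour x2 upsampling of a coarse map with dims (e1, e2, e3).
// [[Rcpp::export]]
arma::mat cpp_upsample2_fwd(const arma::mat &X, int e1, int e2, int e3) {
  const uword C = X.n_cols;
  const int d1 = 2 * e1, d2 = 2 * e2, d3 = 2 * e3;
  mat Y((uword)d1 * d2 * d3, C);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        const uword v = x + (uword)y * d1 + (uword)z * d1 * d2;
        const uword u = (x / 2) + (uword)(y / 2) * e1 + (uword)(z / 2) * e1 * e2;
        Y.row(v) = X.row(u);
      }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_upsample2_bwd(const arma::mat &gY, int e1, int e2, int e3) {
  const uword C = gY.n_cols;
  const int d1 = 2 * e1, d2 = 2 * e2, d3 = 2 * e3;
  mat gX((uword)e1 * e2 * e3, C, fill::zeros);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        const uword v = x + (uword)y * d1 + (uword)z * d1 * d2;
        const uword u = (x / 2) + (uword)(y / 2) * e1 + (uword)(z / 2) * e1 * e2;
        gX.row(u) += gY.row(v);
      }
  return gX;
}
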