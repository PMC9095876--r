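// Convolution and pooling kernels for the network engine.
// Layout convention: arrays are column-major with spatial axes first and the
// channel axis last, i.e. (X, Y, C) in 2D and (X, Y, Z, C) in 3D.  Weights are
// dense matrices of shape C_out x (prod(kernel) * C_in) whose column order is
// (dx, dy[, dz], c_in) with dx fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline size_t idx2(int ix, int iy, int c, int X, int Y) {
  return (size_t)ix + (size_t)X * ((size_t)iy + (size_t)Y * c);
}
static inline size_t idx3(int ix, int iy, int iz, int c, int X, int Y, int Z) {
  return (size_t)ix + (size_t)X * ((size_t)iy + (size_t)Y * ((size_t)iz + (size_t)Z * c));
}

static arma::mat im2col2(const double* x, int X, int Y, int C,
                         int kx, int ky, int sx, int sy, int px, int py,
                         int Xo, int Yo) {
  arma::mat K((size_t)kx * ky * C, (size_t)Xo * Yo, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dy = 0; dy < ky; ++dy)
      for (int dx = 0; dx < kx; ++dx) {
        size_t row = (size_t)dx + kx * ((size_t)dy + (size_t)ky * c);
        for (int oy = 0; oy < Yo; ++oy) {
          int iy = oy * sy + dy - py;
          if (iy < 0 || iy >= Y) continue;
          for (int ox = 0; ox < Xo; ++ox) {
            int ix = ox * sx + dx - px;
            if (ix < 0 || ix >= X) continue;
            K(row, (size_t)ox + (size_t)Xo * oy) = x[idx2(ix, iy, c, X, Y)];
          }
        }
      }
  return K;
}

static void col2im2(const arma::mat& K, double* gx, int X, int Y, int C,
                    int kx, int ky, int sx, int sy, int px, int py,
                    int Xo, int Yo) {
  for (int c = 0; c < C; ++c)
    for (int dy = 0; dy < ky; ++dy)
      for (int dx = 0; dx < kx; ++dx) {
        size_t row = (size_t)dx + kx * ((size_t)dy + (size_t)ky * c);
        for (int oy = 0; oy < Yo; ++oy) {
          int iy = oy * sy + dy - py;
          if (iy < 0 || iy >= Y) continue;
          for (int ox = 0; ox < Xo; ++ox) {
            int ix = ox * sx + dx - px;
            if (ix < 0 || ix >= X) continue;
            gx[idx2(ix, iy, c, X, Y)] += K(row, (size_t)ox + (size_t)Xo * oy);
          }
        }
      }
}

static arma::mat im2col3(const double* x, int X, int Y, int Z, int C,
                         int kx, int ky, int kz, int sx, int sy, int sz,
                         int px, int py, int pz, int Xo, int Yo, int Zo) {
  arma::mat K((size_t)kx * ky * kz * C, (size_t)Xo * Yo * Zo, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx) {
          size_t row = (size_t)dx + kx * ((size_t)dy + ky * ((size_t)dz + (size_t)kz * c));
          for (int oz = 0; oz < Zo; ++oz) {
            int iz = oz * sz + dz - pz;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < Yo; ++oy) {
              int iy = oy * sy + dy - py;
              if (iy < 0 || iy >= Y) continue;
              for (int ox = 0; ox < Xo; ++ox) {
                int ix = ox * sx + dx - px;
                if (ix < 0 || ix >= X) continue;
                K(row, (size_t)ox + (size_t)Xo * ((size_t)oy + (size_t)Yo * oz)) =
                  x[idx3(ix, iy, iz, c, X, Y, Z)];
              }
            }
          }
        }
  return K;
}

static void col2im3(const arma::mat& K, double* gx, int X, int Y, int Z, int C,
                    int kx, int ky, int kz, int sx, int sy, int sz,
                    int px, int py, int pz, int Xo, int Yo, int Zo) {
  for (int c = 0; c < C; ++c)
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx) {
          size_t row = (size_t)dx + kx * ((size_t)dy + ky * ((size_t)dz + (size_t)kz * c));
          for (int oz = 0; oz < Zo; ++oz) {
            int iz = oz * sz + dz - pz;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < Yo; ++oy) {
              int iy = oy * sy + dy - py;
              if (iy < 0 || iy >= Y) continue;
              for (int ox = 0; ox < Xo; ++ox) {
                int ix = ox * sx + dx - px;
                if (ix < 0 || ix >= X) continue;
                gx[idx3(ix, iy, iz, c, X, Y, Z)] +=
                  K(row, (size_t)ox + (size_t)Xo * ((size_t)oy + (size_t)Yo * oz));
              }
            }
          }
        }
}

// [[Rcpp::export]]
List cpp_conv_fwd(NumericVector x, IntegerVector sdim, int cin,
                  NumericMatrix w, NumericVector b,
                  IntegerVector kernel, IntegerVector stride, IntegerVector pad) {
  int nd = sdim.size();
  int cout = w.nrow();
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat K;
  IntegerVector odim(nd);
  if (nd == 2) {
    int Xo = (sdim[0] + 2 * pad[0] - kernel[0]) / stride[0] + 1;
    int Yo = (sdim[1] + 2 * pad[1] - kernel[1]) / stride[1] + 1;
    odim[0] = Xo; odim[1] = Yo;
    K = im2col2(x.begin(), sdim[0], sdim[1], cin, kernel[0], kernel[1],
                stride[0], stride[1], pad[0], pad[1], Xo, Yo);
  } else {
    int Xo = (sdim[0] + 2 * pad[0] - kernel[0]) / stride[0] + 1;
    int Yo = (sdim[1] + 2 * pad[1] - kernel[1]) / stride[1] + 1;
    int Zo = (sdim[2] + 2 * pad[2] - kernel[2]) / stride[2] + 1;
    odim[0] = Xo; odim[1] = Yo; odim[2] = Zo;
    K = im2col3(x.begin(), sdim[0], sdim[1], sdim[2], cin,
                kernel[0], kernel[1], kernel[2], stride[0], stride[1], stride[2],
                pad[0], pad[1], pad[2], Xo, Yo, Zo);
  }
  arma::mat O = W * K;               // cout x npos
  O.each_col() += arma::vec(b.begin(), b.size());
  arma::mat Ot = O.t();              // npos x cout, column-major = spatial-first
  NumericVector out(Ot.begin(), Ot.end());
  return List::create(_["out"] = out, _["odim"] = odim);
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector gout, NumericVector x, IntegerVector sdim, int cin,
                  NumericMatrix w, IntegerVector kernel, IntegerVector stride,
                  IntegerVector pad, bool need_gx, bool need_gw) {
  int nd = sdim.size();
  int cout = w.nrow();
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  int Xo, Yo, Zo = 1;
  Xo = (sdim[0] + 2 * pad[0] - kernel[0]) / stride[0] + 1;
  Yo = (sdim[1] + 2 * pad[1] - kernel[1]) / stride[1] + 1;
  if (nd == 3) Zo = (sdim[2] + 2 * pad[2] - kernel[2]) / stride[2] + 1;
  size_t npos = (size_t)Xo * Yo * Zo;
  // gout arrives spatial-first (npos x cout); transpose to cout x npos
  arma::mat Gt(gout.begin(), npos, cout, false);
  arma::mat G = Gt.t();
  NumericVector gb_out(cout);
  arma::vec gb = arma::sum(G, 1);
  std::copy(gb.begin(), gb.end(), gb_out.begin());

  NumericVector gw_out;
  if (need_gw) {
    arma::mat K;
    if (nd == 2)
      K = im2col2(x.begin(), sdim[0], sdim[1], cin, kernel[0], kernel[1],
                  stride[0], stride[1], pad[0], pad[1], Xo, Yo);
    else
      K = im2col3(x.begin(), sdim[0], sdim[1], sdim[2], cin,
                  kernel[0], kernel[1], kernel[2], stride[0], stride[1], stride[2],
                  pad[0], pad[1], pad[2], Xo, Yo, Zo);
    arma::mat GW = G * K.t();        // cout x (k*cin)
    gw_out = NumericVector(GW.begin(), GW.end());
    gw_out.attr("dim") = IntegerVector::create(GW.n_rows, GW.n_cols);
  }

  NumericVector gx_out;
  if (need_gx) {
    arma::mat GK = W.t() * G;        // (k*cin) x npos
    size_t nx = (size_t)cin;
    for (int d = 0; d < nd; ++d) nx *= sdim[d];
    gx_out = NumericVector(nx);      // zero-initialized
    if (nd == 2)
      col2im2(GK, gx_out.begin(), sdim[0], sdim[1], cin, kernel[0], kernel[1],
              stride[0], stride[1], pad[0], pad[1], Xo, Yo);
    else
      col2im3(GK, gx_out.begin(), sdim[0], sdim[1], sdim[2], cin,
              kernel[0], kernel[1], kernel[2], stride[0], stride[1], stride[2],
              pad[0], pad[1], pad[2], Xo, Yo, Zo);
  }
  return List::create(_["gx"] = gx_out, _["gw"] = gw_out, _["gb"] = gb_out);
}

// Max pooling with window `win`, stride `s`, symmetric zero-pad `p` treated as
// -Inf (ignored).  Returns pooled values plus 0-based argmax linear indices.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector sdim, int C,
                     int win, int s, int p) {
  int nd = sdim.size();
  int X = sdim[0], Y = sdim[1], Z = (nd == 3) ? sdim[2] : 1;
  int Xo = (X + 2 * p - win) / s + 1;
  int Yo = (Y + 2 * p - win) / s + 1;
  int Zo = (nd == 3) ? (Z + 2 * p - win) / s + 1 : 1;
  size_t nout = (size_t)Xo * Yo * Zo * C;
  NumericVector out(nout);
  IntegerVector amax(nout);
  for (int c = 0; c < C; ++c)
    for (int oz = 0; oz < Zo; ++oz)
      for (int oy = 0; oy < Yo; ++oy)
        for (int ox = 0; ox < Xo; ++ox) {
          double best = R_NegInf; size_t bidx = 0;
          int z0 = (nd == 3) ? oz * s - p : 0;
          int zlo = (nd == 3) ? std::max(0, z0) : 0;
          int zhi = (nd == 3) ? std::min(Z, z0 + win) : 1;
          for (int iz = zlo; iz < zhi; ++iz)
            for (int iy = std::max(0, oy * s - p); iy < std::min(Y, oy * s - p + win); ++iy)
              for (int ix = std::max(0, ox * s - p); ix < std::min(X, ox * s - p + win); ++ix) {
                size_t ii = idx3(ix, iy, iz, c, X, Y, Z);
                if (x[ii] > best) { best = x[ii]; bidx = ii; }
              }
          size_t oo = (size_t)ox + (size_t)Xo * ((size_t)oy + (size_t)Yo * ((size_t)oz + (size_t)Zo * c));
          out[oo] = (best == R_NegInf) ? 0.0 : best;
          amax[oo] = (int)bidx;
        }
  IntegerVector odim(nd);
  odim[0] = Xo; odim[1] = Yo; if (nd == 3) odim[2] = Zo;
  return List::create(_["out"] = out, _["argmax"] = amax, _["odim"] = odim);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gout, IntegerVector amax, double n_in) {
  NumericVector gx((R_xlen_t)n_in);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[amax[i]] += gout[i];
  return gx;
}
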