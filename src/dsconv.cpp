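#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Depthwise 3x3x3 convolution with zero 'same' padding on a [X,Y,Z,C]
// array. Weight layout: w(k, c) with tap index k = (dx+1) + 3*(dy+1) +
// 9*(dz+1), dx/dy/dz in {-1,0,1}. out[v, c] = sum_k w(k,c) * x[v + o_k, c].
// The input gradient is the same operation with the tap order reversed
// (w[26-k]), done on the R side.

// [[Rcpp::export]]
NumericVector dwconv3_fwd(NumericVector x, NumericMatrix w) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) stop("x must be a 4D [X,Y,Z,C] array");
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  if (w.nrow() != 27 || w.ncol() != C) stop("w must be 27 x channels");
  NumericVector out(x.size());
  out.attr("dim") = dims;
  const double *xp = REAL(x);
  double *op = REAL(out);
  const size_t plane = (size_t)X * Y, volume = plane * Z;

  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (size_t)c * volume;
    double *oc = op + (size_t)c * volume;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int k = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          const double wk = w(k, c);
          if (wk == 0.0) continue;
          const int z0 = std::max(0, -dz), z1 = Z - 1 - std::max(0, dz);
          const int y0 = std::max(0, -dy), y1 = Y - 1 - std::max(0, dy);
          const int x0 = std::max(0, -dx), x1 = X - 1 - std::max(0, dx);
          for (int z = z0; z <= z1; ++z) {
            const size_t zo = (size_t)z * plane, zi = (size_t)(z + dz) * plane;
            for (int y = y0; y <= y1; ++y) {
              double *orow = oc + zo + (size_t)y * X;
              const double *xrow = xc + zi + (size_t)(y + dy) * X + dx;
              for (int xi = x0; xi <= x1; ++xi) orow[xi] += wk * xrow[xi];
            }
          }
        }
  }
  return out;
}

// Weight gradient of the depthwise convolution above:
// gw(k, c) = sum_v gout[v, c] * x[v + o_k, c].

// [[Rcpp::export]]
NumericMatrix dwconv3_wgrad(NumericVector x, NumericVector gout) {
  IntegerVector dims = x.attr("dim");
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  NumericMatrix gw(27, C);
  const double *xp = REAL(x), *gp = REAL(gout);
  const size_t plane = (size_t)X * Y, volume = plane * Z;

  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (size_t)c * volume;
    const double *gc = gp + (size_t)c * volume;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int k = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          const int z0 = std::max(0, -dz), z1 = Z - 1 - std::max(0, dz);
          const int y0 = std::max(0, -dy), y1 = Y - 1 - std::max(0, dy);
          const int x0 = std::max(0, -dx), x1 = X - 1 - std::max(0, dx);
          double acc = 0.0;
          for (int z = z0; z <= z1; ++z) {
            const size_t zo = (size_t)z * plane, zi = (size_t)(z + dz) * plane;
            for (int y = y0; y <= y1; ++y) {
              const double *grow = gc + zo + (size_t)y * X;
              const double *xrow = xc + zi + (size_t)(y + dy) * X + dx;
              for (int xi = x0; xi <= x1; ++xi) acc += grow[xi] * xrow[xi];
            }
          }
          gw(k, c) = acc;
        }
  }
  return gw;
}

// Group normalization over a [voxels, C] channel matrix: channels are
// partitioned into ng contiguous groups, each normalized by the mean/sd of
// all its entries, then scaled/shifted per channel.

// [[Rcpp::export]]
List gn_fwd_cpp(NumericMatrix m, NumericVector gamma, NumericVector beta,
                int ng) {
  const int v = m.nrow(), C = m.ncol(), cg = C / ng;
  const double n_g = (double)v * cg;
  NumericMatrix xhat(v, C), out(v, C);
  NumericVector inv_g(ng);
  const double *mp = REAL(m);
  double *xp = REAL(xhat), *op = REAL(out);
  for (int g = 0; g < ng; ++g) {
    double s = 0.0, ss = 0.0;
    const double *blk = mp + (size_t)g * cg * v;
    for (size_t i = 0; i < (size_t)cg * v; ++i) { s += blk[i]; ss += blk[i] * blk[i]; }
    const double mu = s / n_g;
    double var = ss / n_g - mu * mu;
    if (var < 0) var = 0;
    const double inv = 1.0 / std::sqrt(var + 1e-5);
    inv_g[g] = inv;
    for (int c = g * cg; c < (g + 1) * cg; ++c) {
      const double ga = gamma[c], be = beta[c];
      const double *mc = mp + (size_t)c * v;
      double *xc = xp + (size_t)c * v, *oc = op + (size_t)c * v;
      for (int i = 0; i < v; ++i) {
        const double xh = (mc[i] - mu) * inv;
        xc[i] = xh;
        oc[i] = xh * ga + be;
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv_g"] = inv_g);
}

// [[Rcpp::export]]
List gn_bwd_cpp(NumericMatrix gm, NumericMatrix xhat, NumericVector inv_g,
                NumericVector gamma, int ng) {
  const int v = gm.nrow(), C = gm.ncol(), cg = C / ng;
  const double n_g = (double)v * cg;
  NumericMatrix gx(v, C);
  NumericVector ggamma(C), gbeta(C);
  const double *gp = REAL(gm), *xp = REAL(xhat);
  double *op = REAL(gx);
  for (int g = 0; g < ng; ++g) {
    double sd = 0.0, sdx = 0.0;
    for (int c = g * cg; c < (g + 1) * cg; ++c) {
      const double *gc = gp + (size_t)c * v, *xc = xp + (size_t)c * v;
      double sg = 0.0, sgx = 0.0;
      for (int i = 0; i < v; ++i) { sg += gc[i]; sgx += gc[i] * xc[i]; }
      gbeta[c] = sg;
      ggamma[c] = sgx;
      sd += gamma[c] * sg;
      sdx += gamma[c] * sgx;
    }
    const double md = sd / n_g, mdx = sdx / n_g, inv = inv_g[g];
    for (int c = g * cg; c < (g + 1) * cg; ++c) {
      const double ga = gamma[c];
      const double *gc = gp + (size_t)c * v, *xc = xp + (size_t)c * v;
      double *oc = op + (size_t)c * v;
      for (int i = 0; i < v; ++i) {
        oc[i] = (gc[i] * ga - md - xc[i] * mdx) * inv;
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Separable 1D convolution along one axis of a 3D array with replicate
// edge handling; used by the phantom generator's Gaussian blur.

// [[Rcpp::export]]
NumericVector blur1d_cpp(NumericVector x, NumericVector w, int axis) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 3) stop("x must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = (w.size() - 1) / 2;
  NumericVector out(x.size());
  out.attr("dim") = dims;
  const double *xp = REAL(x), *wp = REAL(w);
  double *op = REAL(out);
  const size_t plane = (size_t)nx * ny;

  const int n_axis = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xi = 0; xi < nx; ++xi) {
        const int pos = (axis == 1) ? xi : (axis == 2) ? y : z;
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int q = pos + k;
          if (q < 0) q = 0;
          if (q >= n_axis) q = n_axis - 1;
          const size_t src = (axis == 1)
            ? (size_t)z * plane + (size_t)y * nx + q
            : (axis == 2)
              ? (size_t)z * plane + (size_t)q * nx + xi
              : (size_t)q * plane + (size_t)y * nx + xi;
          acc += wp[k + r] * xp[src];
        }
        op[(size_t)z * plane + (size_t)y * nx + xi] = acc;
      }
  return out;
}
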