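// Low-level numeric kernels for 3D convolutional networks and phantoms.
// Volumes are base-R arrays, column-major, dims (nx, ny, nz, channels):
// the spatial index runs fastest, the channel index slowest, so an
// (nvox x channels) matrix view shares memory layout with the array.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int stride) {
  // kernel 3, pad 1: floor((n - 1) / stride) + 1  (== n for stride 1, ceil(n/2) for 2)
  return (n - 1) / stride + 1;
}

// im2col over a block of output lines. A "line" is one (zo, yo) pair, i.e.
// ox contiguous output voxels. Filling and multiplying small line blocks
// keeps the column buffer cache-resident, which matters a great deal on
// hosts with limited memory write bandwidth; out-of-bounds taps are zero
// (pad 1). Column index = ci * 27 + (kx + 3*ky + 9*kz).
static void im2col_lines(const double* x, double* col, int nx, int ny, int nz,
                         int cin, int stride, int ox, int oy,
                         long l0, long nlines) {
  const long nrows = nlines * ox;
  std::memset(col, 0, sizeof(double) * nrows * 27 * cin);
  const long plane = (long)nx * ny, volsz = (long)nx * ny * nz;
  for (long li = 0; li < nlines; ++li) {
    const long L = l0 + li;
    const int zo = (int)(L / oy), yo = (int)(L % oy);
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = x + (long)ci * volsz;
      for (int kz = 0; kz < 3; ++kz) {
        const int zi = zo * stride + kz - 1;
        if (zi < 0 || zi >= nz) continue;
        for (int ky = 0; ky < 3; ++ky) {
          const int yi = yo * stride + ky - 1;
          if (yi < 0 || yi >= ny) continue;
          const double* src = xc + (long)zi * plane + (long)yi * nx;
          for (int kx = 0; kx < 3; ++kx) {
            double* d = col + ((long)ci * 27 + kx + 3 * ky + 9 * kz) * nrows + li * ox;
            if (stride == 1) {
              const int x0 = std::max(0, 1 - kx);
              const int x1 = std::min(ox, nx + 1 - kx);
              if (x1 > x0) std::memcpy(d + x0, src + x0 + kx - 1,
                                       sizeof(double) * (x1 - x0));
            } else {
              for (int xo = 0; xo < ox; ++xo) {
                const int xi = xo * stride + kx - 1;
                if (xi >= 0 && xi < nx) d[xo] = src[xi];
              }
            }
          }
        }
      }
    }
  }
}

// Lines per block sized so the column buffer stays around 1 MiB.
static long block_lines(int ox, int cin) {
  long lp = (1L << 17) / ((long)ox * 27 * cin);
  return std::max(1L, lp);
}

// y (nvox_out x cout, column-major on the output array) = conv(x, W) [+ b]
static void conv3_run(const double* x, int nx, int ny, int nz, int cin,
                      const arma::mat& Wm, const double* b, int stride,
                      double* y) {
  const int ox = out_size(nx, stride), oy = out_size(ny, stride), oz = out_size(nz, stride);
  const int cout = (int)Wm.n_cols;
  const arma::uword nvox = (arma::uword)ox * oy * oz;
  const long total_lines = (long)oy * oz;
  const long lp = block_lines(ox, cin);
  arma::mat col((arma::uword)(lp * ox), (arma::uword)27 * cin);
  arma::mat Y(y, nvox, cout, false);
  for (long l0 = 0; l0 < total_lines; l0 += lp) {
    const long nl = std::min(lp, total_lines - l0);
    const arma::uword r0 = (arma::uword)(l0 * ox), nr = (arma::uword)(nl * ox);
    im2col_lines(x, col.memptr(), nx, ny, nz, cin, stride, ox, oy, l0, nl);
    const arma::mat colv(col.memptr(), nr, (arma::uword)27 * cin, false);
    Y.rows(r0, r0 + nr - 1) = colv * Wm;
  }
  if (b != nullptr)
    Y.each_row() += arma::rowvec(const_cast<double*>(b), cout, false);
}

// dW += im2col(x)^T * G, accumulated line-block by line-block.
static void conv3_dw(const double* x, int nx, int ny, int nz, int cin,
                     const double* g, int cout, int stride, arma::mat& dW) {
  const int ox = out_size(nx, stride), oy = out_size(ny, stride), oz = out_size(nz, stride);
  const arma::uword nvox = (arma::uword)ox * oy * oz;
  const long total_lines = (long)oy * oz;
  const long lp = block_lines(ox, cin);
  arma::mat col((arma::uword)(lp * ox), (arma::uword)27 * cin);
  const arma::mat G(const_cast<double*>(g), nvox, cout, false);
  for (long l0 = 0; l0 < total_lines; l0 += lp) {
    const long nl = std::min(lp, total_lines - l0);
    const arma::uword r0 = (arma::uword)(l0 * ox), nr = (arma::uword)(nl * ox);
    im2col_lines(x, col.memptr(), nx, ny, nz, cin, stride, ox, oy, l0, nl);
    const arma::mat colv(col.memptr(), nr, (arma::uword)27 * cin, false);
    dW += colv.t() * G.rows(r0, r0 + nr - 1);
  }
}

// Scatter-add of one line block of dcol into dx (input gradient, strided path).
static void col2im_lines(const double* dcol, double* dx, int nx, int ny, int nz,
                         int cin, int stride, int ox, int oy, long l0, long nlines) {
  const long nrows = nlines * ox;
  const long plane = (long)nx * ny, volsz = (long)nx * ny * nz;
  for (long li = 0; li < nlines; ++li) {
    const long L = l0 + li;
    const int zo = (int)(L / oy), yo = (int)(L % oy);
    for (int ci = 0; ci < cin; ++ci) {
      double* xc = dx + (long)ci * volsz;
      for (int kz = 0; kz < 3; ++kz) {
        const int zi = zo * stride + kz - 1;
        if (zi < 0 || zi >= nz) continue;
        for (int ky = 0; ky < 3; ++ky) {
          const int yi = yo * stride + ky - 1;
          if (yi < 0 || yi >= ny) continue;
          double* d = xc + (long)zi * plane + (long)yi * nx;
          for (int kx = 0; kx < 3; ++kx) {
            const double* src = dcol + ((long)ci * 27 + kx + 3 * ky + 9 * kz) * nrows + li * ox;
            for (int xo = 0; xo < ox; ++xo) {
              const int xi = xo * stride + kx - 1;
              if (xi >= 0 && xi < nx) d[xi] += src[xo];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, NumericMatrix W, NumericVector b, int stride) {
  IntegerVector dm = x.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2], cin = dm[3];
  int cout = W.ncol();
  int ox = out_size(nx, stride), oy = out_size(ny, stride), oz = out_size(nz, stride);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  NumericVector out((long)ox * oy * oz * cout);
  conv3_run(x.begin(), nx, ny, nz, cin, Wm, b.begin(), stride, out.begin());
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return out;
}

// Backward pass. dW and db accumulate block-wise; the input gradient is, for
// stride 1, a convolution of gy with the flipped transposed kernel (so it
// reuses the tiled forward machinery), and for stride 2 the explicit
// block-wise col2im scatter (strided convolutions only ever see the smaller
// encoder grids).
// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, NumericMatrix W, NumericVector gy, int stride) {
  IntegerVector dm = x.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2], cin = dm[3];
  int cout = W.ncol();
  int ox = out_size(nx, stride), oy = out_size(ny, stride), oz = out_size(nz, stride);
  arma::uword nvox = (arma::uword)ox * oy * oz;
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat G((double*)gy.begin(), nvox, cout, false);

  arma::mat dW((arma::uword)27 * cin, (arma::uword)cout, arma::fill::zeros);
  conv3_dw(x.begin(), nx, ny, nz, cin, gy.begin(), cout, stride, dW);
  arma::rowvec db = arma::sum(G, 0);

  NumericVector dx((long)nx * ny * nz * cin);
  if (stride == 1) {
    // Wt[(co*27 + kflip), ci] = W[(ci*27 + k), co]
    arma::mat Wt((arma::uword)27 * cout, cin);
    for (int ci = 0; ci < cin; ++ci)
      for (int co = 0; co < cout; ++co)
        for (int k = 0; k < 27; ++k) {
          int kf = 26 - k;  // flipping all three axes reverses the 27-tap order
          Wt((arma::uword)co * 27 + kf, ci) = Wm((arma::uword)ci * 27 + k, co);
        }
    conv3_run(gy.begin(), ox, oy, oz, cout, Wt, nullptr, 1, dx.begin());
  } else {
    const long total_lines = (long)oy * oz;
    const long lp = block_lines(ox, cin);
    arma::mat dcol((arma::uword)(lp * ox), (arma::uword)27 * cin);
    for (long l0 = 0; l0 < total_lines; l0 += lp) {
      const long nl = std::min(lp, total_lines - l0);
      const arma::uword r0 = (arma::uword)(l0 * ox), nr = (arma::uword)(nl * ox);
      arma::mat dcolv(dcol.memptr(), nr, (arma::uword)27 * cin, false);
      dcolv = G.rows(r0, r0 + nr - 1) * Wm.t();
      col2im_lines(dcol.memptr(), dx.begin(), nx, ny, nz, cin, stride, ox, oy, l0, nl);
    }
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  NumericMatrix dWr(dW.n_rows, dW.n_cols, dW.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2x2 max pooling, stride 2, ceil mode (edge windows are clipped).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2], nc = dm[3];
  int ox = (nx + 1) / 2, oy = (ny + 1) / 2, oz = (nz + 1) / 2;
  long onvox = (long)ox * oy * oz * nc;
  NumericVector y(onvox);
  IntegerVector idx(onvox);  // 0-based linear index into x of each window max
  const double* xv = x.begin();
  long o = 0;
  for (int c = 0; c < nc; ++c) {
    long coff = (long)c * nx * ny * nz;
    for (int zo = 0; zo < oz; ++zo)
      for (int yo = 0; yo < oy; ++yo)
        for (int xo = 0; xo < ox; ++xo, ++o) {
          double best = -INFINITY; long bi = -1;
          for (int dz = 0; dz < 2; ++dz) {
            int zi = 2 * zo + dz; if (zi >= nz) break;
            for (int dy = 0; dy < 2; ++dy) {
              int yi = 2 * yo + dy; if (yi >= ny) break;
              for (int dxk = 0; dxk < 2; ++dxk) {
                int xi = 2 * xo + dxk; if (xi >= nx) break;
                long li = coff + (long)zi * nx * ny + (long)yi * nx + xi;
                if (xv[li] > best) { best = xv[li]; bi = li; }
              }
            }
          }
          y[o] = best; idx[o] = (int)bi;
        }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  long n = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  for (long i = 0; i < gy.size(); ++i) dx[idx[i]] += gy[i];
  dx.attr("dim") = xdim;
  return dx;
}

struct LinW { int i0, i1; double w0, w1; };
static std::vector<LinW> axis_weights(int n_in, int n_out) {
  std::vector<LinW> w(n_out);
  double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double c = (o + 0.5) * scale - 0.5;
    if (c < 0) c = 0; if (c > n_in - 1) c = n_in - 1;
    int i0 = (int)std::floor(c);
    int i1 = std::min(i0 + 1, n_in - 1);
    double f = c - i0;
    w[o] = {i0, i1, 1.0 - f, f};
  }
  return w;
}

// Trilinear resize of (nx,ny,nz,C) to target spatial dims (per channel).
// [[Rcpp::export]]
NumericVector cpp_resize3_fwd(NumericVector x, IntegerVector tdim) {
  IntegerVector dm = x.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2], nc = dm[3];
  int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  auto wx = axis_weights(nx, tx), wy = axis_weights(ny, ty), wz = axis_weights(nz, tz);
  NumericVector y((long)tx * ty * tz * nc);
  const double* xv = x.begin();
  long o = 0;
  for (int c = 0; c < nc; ++c) {
    long coff = (long)c * nx * ny * nz;
    for (int z = 0; z < tz; ++z)
      for (int yy = 0; yy < ty; ++yy)
        for (int xx = 0; xx < tx; ++xx, ++o) {
          const LinW &ax = wx[xx], &ay = wy[yy], &az = wz[z];
          double v = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            int zi = dz ? az.i1 : az.i0; double wzv = dz ? az.w1 : az.w0;
            if (wzv == 0) continue;
            long zoff = coff + (long)zi * nx * ny;
            for (int dy = 0; dy < 2; ++dy) {
              int yi = dy ? ay.i1 : ay.i0; double wyv = dy ? ay.w1 : ay.w0;
              if (wyv == 0) continue;
              long yoff = zoff + (long)yi * nx;
              for (int dxk = 0; dxk < 2; ++dxk) {
                int xi = dxk ? ax.i1 : ax.i0; double wxv = dxk ? ax.w1 : ax.w0;
                if (wxv == 0) continue;
                v += wzv * wyv * wxv * xv[yoff + xi];
              }
            }
          }
          y[o] = v;
        }
  }
  y.attr("dim") = IntegerVector::create(tx, ty, tz, nc);
  return y;
}

// Transpose of cpp_resize3_fwd (scatter the same weights).
// [[Rcpp::export]]
NumericVector cpp_resize3_bwd(NumericVector gy, IntegerVector sdim) {
  IntegerVector dm = gy.attr("dim");
  int tx = dm[0], ty = dm[1], tz = dm[2], nc = dm[3];
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  auto wx = axis_weights(nx, tx), wy = axis_weights(ny, ty), wz = axis_weights(nz, tz);
  NumericVector dx((long)nx * ny * nz * nc);
  double* dv = dx.begin();
  long o = 0;
  for (int c = 0; c < nc; ++c) {
    long coff = (long)c * nx * ny * nz;
    for (int z = 0; z < tz; ++z)
      for (int yy = 0; yy < ty; ++yy)
        for (int xx = 0; xx < tx; ++xx, ++o) {
          const LinW &ax = wx[xx], &ay = wy[yy], &az = wz[z];
          double g = gy[o];
          if (g == 0) continue;
          for (int dz = 0; dz < 2; ++dz) {
            int zi = dz ? az.i1 : az.i0; double wzv = dz ? az.w1 : az.w0;
            if (wzv == 0) continue;
            long zoff = coff + (long)zi * nx * ny;
            for (int dy = 0; dy < 2; ++dy) {
              int yi = dy ? ay.i1 : ay.i0; double wyv = dy ? ay.w1 : ay.w0;
              if (wyv == 0) continue;
              long yoff = zoff + (long)yi * nx;
              for (int dxk = 0; dxk < 2; ++dxk) {
                int xi = dxk ? ax.i1 : ax.i0; double wxv = dxk ? ax.w1 : ax.w0;
                if (wxv == 0) continue;
                dv[yoff + xi] += g * wzv * wyv * wxv;
              }
            }
          }
        }
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return dx;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform with sample spacing h.
static void dt1d(std::vector<double>& f, double h) {
  int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q * h * h) - (f[v[k]] + v[k] * (double)v[k] * h * h)) /
          (2.0 * h * h * (q - v[k]));
      if (s > zb[k]) break;
      --k;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
  f = d;
}

// Squared Euclidean distance (mm^2) from each voxel to the nearest voxel with site != 0.
// Non-site voxels start at a large finite sentinel (1e30) rather than Inf so the
// parabola-intersection arithmetic stays NaN-free; with no sites at all the result
// stays at ~1e30.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector site, NumericVector spacing) {
  IntegerVector dm = site.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericVector d((long)nx * ny * nz);
  for (long i = 0; i < d.size(); ++i) d[i] = site[i] != 0 ? 0.0 : 1e30;
  std::vector<double> line;
  // x axis
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      long off = (long)z * nx * ny + (long)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = d[off + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) d[off + x] = line[x];
    }
  // y axis
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      long off = (long)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = d[off + (long)y * nx];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) d[off + (long)y * nx] = line[y];
    }
  // z axis
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      long off = (long)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = d[off + (long)z * nx * ny];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) d[off + (long)z * nx * ny] = line[z];
    }
  d.attr("dim") = IntegerVector::create(nx, ny, nz);
  return d;
}
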