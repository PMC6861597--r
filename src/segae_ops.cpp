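// Low-level kernels: im2col/col2vol for 3D convolution, separable Gaussian
// smoothing, 3D connected-component labelling, and directed point-set
// distances. Volumes are column-major R arrays with dims (X, Y, Z[, C]).
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Unfold a (X,Y,Z,C) volume into a matrix with one row per output voxel and
// one column per (kx,ky,kz,channel) tap, zero padding outside the volume.
// Column order q = kx + k1*(ky + k2*(kz + k3*c)) matches the column-major
// flattening of a weight array with dims (k1,k2,k3,Cin,Cout).
// [[Rcpp::export]]
NumericMatrix cpp_vol2col(NumericVector x, IntegerVector dims,
                          IntegerVector ksize, int stride, IntegerVector pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int k1 = ksize[0], k2 = ksize[1], k3 = ksize[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int Xo = (X + 2 * p1 - k1) / stride + 1;
  const int Yo = (Y + 2 * p2 - k2) / stride + 1;
  const int Zo = (Z + 2 * p3 - k3) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  NumericMatrix col(N, (R_xlen_t)k1 * k2 * k3 * C);
  double *pc = col.begin();
  const double *px = x.begin();
  for (int c = 0; c < C; ++c)
    for (int kz = 0; kz < k3; ++kz)
      for (int ky = 0; ky < k2; ++ky)
        for (int kx = 0; kx < k1; ++kx) {
          double *dst = pc + N * (kx + (R_xlen_t)k1 * (ky + (R_xlen_t)k2 * (kz + (R_xlen_t)k3 * c)));
          // valid xo range: 0 <= xo*stride - p1 + kx < X
          int xo_lo = 0, xo_hi = Xo - 1;
          while (xo_lo < Xo && xo_lo * stride - p1 + kx < 0) ++xo_lo;
          while (xo_hi >= 0 && xo_hi * stride - p1 + kx >= X) --xo_hi;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - p3 + kz;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - p2 + ky;
              double *d2 = dst + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo);
              if (zi < 0 || zi >= Z || yi < 0 || yi >= Y) {
                std::fill(d2, d2 + Xo, 0.0);
                continue;
              }
              const double *src = px + (R_xlen_t)X * (yi + (R_xlen_t)Y * (zi + (R_xlen_t)Z * c));
              for (int xo = 0; xo < xo_lo; ++xo) d2[xo] = 0.0;
              if (stride == 1) {
                const double *s0 = src - p1 + kx;
                for (int xo = xo_lo; xo <= xo_hi; ++xo) d2[xo] = s0[xo];
              } else {
                for (int xo = xo_lo; xo <= xo_hi; ++xo)
                  d2[xo] = src[xo * stride - p1 + kx];
              }
              for (int xo = xo_hi + 1; xo < Xo; ++xo) d2[xo] = 0.0;
            }
          }
        }
  return col;
}

// Adjoint of cpp_vol2col: scatter-add a column matrix back onto the input
// grid. Used for the gradient with respect to the convolution input.
// [[Rcpp::export]]
NumericVector cpp_col2vol(NumericMatrix dcol, IntegerVector dims,
                          IntegerVector ksize, int stride, IntegerVector pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int k1 = ksize[0], k2 = ksize[1], k3 = ksize[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int Xo = (X + 2 * p1 - k1) / stride + 1;
  const int Yo = (Y + 2 * p2 - k2) / stride + 1;
  const int Zo = (Z + 2 * p3 - k3) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  double *pdx = dx.begin();
  const double *pc = dcol.begin();
  for (int c = 0; c < C; ++c)
    for (int kz = 0; kz < k3; ++kz)
      for (int ky = 0; ky < k2; ++ky)
        for (int kx = 0; kx < k1; ++kx) {
          const double *src = pc + N * (kx + (R_xlen_t)k1 * (ky + (R_xlen_t)k2 * (kz + (R_xlen_t)k3 * c)));
          int xo_lo = 0, xo_hi = Xo - 1;
          while (xo_lo < Xo && xo_lo * stride - p1 + kx < 0) ++xo_lo;
          while (xo_hi >= 0 && xo_hi * stride - p1 + kx >= X) --xo_hi;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - p3 + kz;
            if (zi < 0 || zi >= Z) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - p2 + ky;
              if (yi < 0 || yi >= Y) continue;
              const double *s2 = src + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo);
              double *dst = pdx + (R_xlen_t)X * (yi + (R_xlen_t)Y * (zi + (R_xlen_t)Z * c));
              if (stride == 1) {
                double *d0 = dst - p1 + kx;
                for (int xo = xo_lo; xo <= xo_hi; ++xo) d0[xo] += s2[xo];
              } else {
                for (int xo = xo_lo; xo <= xo_hi; ++xo)
                  dst[xo * stride - p1 + kx] += s2[xo];
              }
            }
          }
        }
  return dx;
}

static void smooth_axis(const std::vector<double> &in, std::vector<double> &out,
                        int n_along, R_xlen_t stride_along, R_xlen_t n_lines,
                        R_xlen_t line_stride_outer, int inner_per_outer,
                        R_xlen_t stride_inner,
                        const std::vector<double> &kern) {
  // Generic 1D convolution along one axis of a 3D array, zero boundary.
  const int r = ((int)kern.size() - 1) / 2;
  for (R_xlen_t line = 0; line < n_lines; ++line) {
    const R_xlen_t outer = line / inner_per_outer;
    const R_xlen_t inner = line % inner_per_outer;
    const R_xlen_t base = outer * line_stride_outer + inner * stride_inner;
    for (int i = 0; i < n_along; ++i) {
      double acc = 0.0;
      const int j0 = std::max(0, i - r), j1 = std::min(n_along - 1, i + r);
      for (int j = j0; j <= j1; ++j)
        acc += in[base + (R_xlen_t)j * stride_along] * kern[(size_t)(j - i + r)];
      out[base + (R_xlen_t)i * stride_along] = acc;
    }
  }
}

// Separable Gaussian smoothing of a 3D volume (zero boundary condition).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3d(NumericVector x, IntegerVector dims, double sigma) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  if (sigma <= 0) return clone(x);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[(size_t)(i + r)] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += kern[(size_t)(i + r)];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= s;
  std::vector<double> a(x.begin(), x.end()), b(n);
  // x-axis: lines indexed by (y,z)
  smooth_axis(a, b, X, 1, (R_xlen_t)Y * Z, (R_xlen_t)X * Y, Y, X, kern);
  // y-axis: lines indexed by (z,x): outer = z, inner = x
  smooth_axis(b, a, Y, X, (R_xlen_t)X * Z, (R_xlen_t)X * Y, X, 1, kern);
  // z-axis: lines indexed by (y,x)
  smooth_axis(a, b, Z, (R_xlen_t)X * Y, (R_xlen_t)X * Y, (R_xlen_t)X * Y, X * Y, 1, kern);
  return NumericVector(b.begin(), b.end());
}

// Label 3D connected components of a binary mask (6 or 26 connectivity).
// Returns integer labels 1..n_components, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  IntegerVector lab(n);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int cx = (int)(cur % X);
      const int cy = (int)((cur / X) % Y);
      const int cz = (int)(cur / ((R_xlen_t)X * Y));
      for (size_t o = 0; o < offs.size(); o += 3) {
        const int nx = cx + offs[o], ny = cy + offs[o + 1], nz = cz + offs[o + 2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        const R_xlen_t ni = nx + (R_xlen_t)X * (ny + (R_xlen_t)Y * nz);
        if (mask[ni] != 0 && lab[ni] == 0) { lab[ni] = next; q.push(ni); }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Direct 3D convolution (no im2col): y[n, co] = sum_tap,ci w[q(tap,ci), co]
// * x[shifted voxel, ci] + b[co]. Line-buffered accumulation; much faster
// than im2col+GEMM for the small channel counts used here.
// A leaky-ReLU slope >= 0 is applied at write time (slope < 0 disables
// the activation, for the Softmax head).
// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fw(NumericVector x, IntegerVector dims,
                            NumericMatrix W, NumericVector b,
                            int k, int stride, int pad, double slope) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = (X + 2 * pad - k) / stride + 1;
  const int Yo = (Y + 2 * pad - k) / stride + 1;
  const int Zo = (Z + 2 * pad - k) / stride + 1;
  const int Co = W.ncol();
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  NumericMatrix y(N, Co);
  const double *px = x.begin();
  const double *pw = W.begin();
  const R_xlen_t wld = W.nrow();
  std::vector<double> acc((size_t)Co * Xo);
  for (int zo = 0; zo < Zo; ++zo) {
    for (int yo = 0; yo < Yo; ++yo) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int kz = 0; kz < k; ++kz) {
        const int zi = zo * stride - pad + kz;
        if (zi < 0 || zi >= Z) continue;
        for (int ky = 0; ky < k; ++ky) {
          const int yi = yo * stride - pad + ky;
          if (yi < 0 || yi >= Y) continue;
          for (int kx = 0; kx < k; ++kx) {
            int xo_lo = 0, xo_hi = Xo - 1;
            while (xo_lo < Xo && xo_lo * stride - pad + kx < 0) ++xo_lo;
            while (xo_hi >= 0 && xo_hi * stride - pad + kx >= X) --xo_hi;
            if (xo_lo > xo_hi) continue;
            for (int ci = 0; ci < C; ++ci) {
              const double *src = px + (R_xlen_t)X * (yi + (R_xlen_t)Y * (zi + (R_xlen_t)Z * ci));
              const R_xlen_t q = kx + (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * ci));
              int co = 0;
              if (stride == 1) {
                const double *s0 = src - pad + kx;
                for (; co + 1 < Co; co += 2) {  // two channels per sweep
                  const double w1 = pw[q + wld * co];
                  const double w2 = pw[q + wld * (co + 1)];
                  double *a1 = &acc[(size_t)co * Xo];
                  double *a2 = &acc[(size_t)(co + 1) * Xo];
                  for (int xo = xo_lo; xo <= xo_hi; ++xo) {
                    const double s = s0[xo];
                    a1[xo] += w1 * s;
                    a2[xo] += w2 * s;
                  }
                }
                for (; co < Co; ++co) {
                  const double wv = pw[q + wld * co];
                  double *a = &acc[(size_t)co * Xo];
                  for (int xo = xo_lo; xo <= xo_hi; ++xo) a[xo] += wv * s0[xo];
                }
              } else {
                for (; co < Co; ++co) {
                  const double wv = pw[q + wld * co];
                  double *a = &acc[(size_t)co * Xo];
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    a[xo] += wv * src[xo * stride - pad + kx];
                }
              }
            }
          }
        }
      }
      const R_xlen_t base = (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo);
      for (int co = 0; co < Co; ++co) {
        double *dst = y.begin() + (R_xlen_t)N * co + base;
        const double *a = &acc[(size_t)co * Xo];
        const double bc = b[co];
        if (slope < 0) {
          for (int xo = 0; xo < Xo; ++xo) dst[xo] = a[xo] + bc;
        } else {
          for (int xo = 0; xo < Xo; ++xo) {
            const double v = a[xo] + bc;
            dst[xo] = v > 0 ? v : slope * v;
          }
        }
      }
    }
  }
  return y;
}

// Gradients of the direct convolution: dx (input gradient, scatter of the
// transposed kernel) and dW (weight gradient, line dot products).
// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector dims, NumericMatrix dy,
                   NumericMatrix W, int k, int stride, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = (X + 2 * pad - k) / stride + 1;
  const int Yo = (Y + 2 * pad - k) / stride + 1;
  const int Zo = (Z + 2 * pad - k) / stride + 1;
  const int Co = W.ncol();
  const R_xlen_t N = (R_xlen_t)Xo * Yo * Zo;
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  NumericMatrix dW(W.nrow(), Co);
  const double *px = x.begin();
  const double *pdy = dy.begin();
  const double *pw = W.begin();
  double *pdx = dx.begin();
  double *pdw = dW.begin();
  const R_xlen_t wld = W.nrow();
  std::vector<double> tmpv((size_t)Xo);
  double *tmp = tmpv.data();
  for (int zo = 0; zo < Zo; ++zo) {
    for (int yo = 0; yo < Yo; ++yo) {
      const R_xlen_t base = (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo);
      for (int kz = 0; kz < k; ++kz) {
        const int zi = zo * stride - pad + kz;
        if (zi < 0 || zi >= Z) continue;
        for (int ky = 0; ky < k; ++ky) {
          const int yi = yo * stride - pad + ky;
          if (yi < 0 || yi >= Y) continue;
          for (int kx = 0; kx < k; ++kx) {
            int xo_lo = 0, xo_hi = Xo - 1;
            while (xo_lo < Xo && xo_lo * stride - pad + kx < 0) ++xo_lo;
            while (xo_hi >= 0 && xo_hi * stride - pad + kx >= X) --xo_hi;
            if (xo_lo > xo_hi) continue;
            for (int ci = 0; ci < C; ++ci) {
              const double *src = px + (R_xlen_t)X * (yi + (R_xlen_t)Y * (zi + (R_xlen_t)Z * ci));
              double *dst = pdx + (R_xlen_t)X * (yi + (R_xlen_t)Y * (zi + (R_xlen_t)Z * ci));
              const R_xlen_t q = kx + (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * ci));
              if (stride == 1) {
                const double *s0 = src - pad + kx;
                double *d0 = dst - pad + kx;
                // accumulate sum_co wv * dy into one temporary line so the
                // dx array is touched once per (tap, ci), not per channel
                for (int xo = xo_lo; xo <= xo_hi; ++xo) tmp[xo - xo_lo] = 0.0;
                int co = 0;
                for (; co + 1 < Co; co += 2) {  // two channels per sweep
                  const double w1 = pw[q + wld * co];
                  const double w2 = pw[q + wld * (co + 1)];
                  const double *d1 = pdy + N * co + base;
                  const double *d2 = pdy + N * (co + 1) + base;
                  double acc1 = 0.0, acc2 = 0.0;
                  for (int xo = xo_lo; xo <= xo_hi; ++xo) {
                    const double s = s0[xo];
                    acc1 += s * d1[xo];
                    acc2 += s * d2[xo];
                    // two separate additions keep the same rounding order
                    // as the unpaired loop (bit-reproducible training)
                    tmp[xo - xo_lo] += w1 * d1[xo];
                    tmp[xo - xo_lo] += w2 * d2[xo];
                  }
                  pdw[q + wld * co] += acc1;
                  pdw[q + wld * (co + 1)] += acc2;
                }
                for (; co < Co; ++co) {
                  const double wv = pw[q + wld * co];
                  const double *dyl = pdy + N * co + base;
                  double acc = 0.0;
                  for (int xo = xo_lo; xo <= xo_hi; ++xo) {
                    acc += s0[xo] * dyl[xo];
                    tmp[xo - xo_lo] += wv * dyl[xo];
                  }
                  pdw[q + wld * co] += acc;
                }
                for (int xo = xo_lo; xo <= xo_hi; ++xo) d0[xo] += tmp[xo - xo_lo];
              } else {
                for (int co = 0; co < Co; ++co) {
                  const double wv = pw[q + wld * co];
                  const double *dyl = pdy + N * co + base;
                  double acc = 0.0;
                  for (int xo = xo_lo; xo <= xo_hi; ++xo) {
                    const int xi = xo * stride - pad + kx;
                    acc += src[xi] * dyl[xo];
                    dst[xi] += wv * dyl[xo];
                  }
                  pdw[q + wld * co] += acc;
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dW") = dW);
}

// Batch-norm forward on an N x C activation matrix (biased variance).
// training: per-batch statistics; otherwise the supplied running stats.
// [[Rcpp::export]]
List cpp_bn_fw(NumericMatrix a, NumericVector gamma, NumericVector beta,
               double eps, bool training,
               NumericVector rmean, NumericVector rvar) {
  const R_xlen_t n = a.nrow();
  const int C = a.ncol();
  NumericMatrix out(n, C);
  NumericVector mu(C), vv(C);
  for (int c = 0; c < C; ++c) {
    const double *ac = a.begin() + n * c;
    double m, v;
    if (training) {
      long double s = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) s += ac[i];
      m = (double)(s / n);
      long double s2 = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) {
        const double d = ac[i] - m;
        s2 += (long double)d * d;
      }
      v = (double)(s2 / n);
      mu[c] = m; vv[c] = v;
    } else {
      m = rmean[c]; v = rvar[c];
    }
    const double inv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c] * inv;
    const double off = beta[c] - m * g;
    double *oc = out.begin() + n * c;
    for (R_xlen_t i = 0; i < n; ++i) oc[i] = ac[i] * g + off;
  }
  return List::create(Named("out") = out, Named("mu") = mu, Named("var") = vv);
}

// Batch-norm backward fused with the leaky-ReLU derivative of the
// activation that produced `a` (slope < 0 skips the LReLU factor).
// [[Rcpp::export]]
List cpp_bn_bw(NumericMatrix dout, NumericMatrix a, NumericVector mu,
               NumericVector vv, NumericVector gamma, double eps,
               double slope) {
  const R_xlen_t n = dout.nrow();
  const int C = dout.ncol();
  NumericMatrix da(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *dc = dout.begin() + n * c;
    const double *ac = a.begin() + n * c;
    double *dac = da.begin() + n * c;
    const double inv = 1.0 / std::sqrt(vv[c] + eps);
    const double m = mu[c];
    double sd_ = 0.0, sdx = 0.0, sg = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xh = (ac[i] - m) * inv;
      sg += dc[i] * xh;
      sd_ += dc[i];
    }
    dgamma[c] = sg; dbeta[c] = sd_;
    const double md = sd_ / n, mdx = sg / n;
    const double g = gamma[c] * inv;
    sdx = mdx;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xh = (ac[i] - m) * inv;
      double v = g * (dc[i] - md - xh * sdx);
      if (slope >= 0 && ac[i] <= 0) v *= slope;
      dac[i] = v;
    }
  }
  return List::create(Named("da") = da, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// Nearest-neighbour 2x upsampling of a (X,Y,Z,C) volume.
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  NumericVector out((R_xlen_t)8 * X * Y * Z * C);
  const double *px = x.begin();
  double *po = out.begin();
  const int X2 = 2 * X, Y2 = 2 * Y;
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < 2 * Z; ++z)
      for (int y = 0; y < Y2; ++y) {
        const double *src = px + (R_xlen_t)X * ((y >> 1) + (R_xlen_t)Y * ((z >> 1) + (R_xlen_t)Z * c));
        double *dst = po + (R_xlen_t)X2 * (y + (R_xlen_t)Y2 * (z + (R_xlen_t)2 * Z * c));
        for (int xx = 0; xx < X; ++xx) {
          dst[2 * xx] = src[xx];
          dst[2 * xx + 1] = src[xx];
        }
      }
  return out;
}

// Adjoint of cpp_upsample2: sum each 2x2x2 block.
// [[Rcpp::export]]
NumericVector cpp_downsum2(NumericVector x, IntegerVector dims) {
  const int X2 = dims[0], Y2 = dims[1], Z2 = dims[2], C = dims[3];
  const int X = X2 / 2, Y = Y2 / 2, Z = Z2 / 2;
  NumericVector out((R_xlen_t)X * Y * Z * C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z2; ++z)
      for (int y = 0; y < Y2; ++y) {
        const double *src = px + (R_xlen_t)X2 * (y + (R_xlen_t)Y2 * (z + (R_xlen_t)Z2 * c));
        double *dst = po + (R_xlen_t)X * ((y >> 1) + (R_xlen_t)Y * ((z >> 1) + (R_xlen_t)Z * c));
        for (int xx = 0; xx < X; ++xx)
          dst[xx] += src[2 * xx] + src[2 * xx + 1];
      }
  return out;
}

// For each row of A (points, physical coordinates), the Euclidean distance
// to the nearest row of B. Brute force; mask point sets are small.
// [[Rcpp::export]]
NumericVector cpp_directed_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
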