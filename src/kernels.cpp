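#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// Dense 5D tensors are R arrays with dim (L, W, H, C, N), column-major.
// Convolutions use odd kernels with "same" zero padding; weights have
// dim (K, K, K, Cin, Cout).

static inline R_xlen_t idx5(R_xlen_t i, R_xlen_t j, R_xlen_t k, R_xlen_t c,
                            R_xlen_t n, R_xlen_t L, R_xlen_t W, R_xlen_t H,
                            R_xlen_t C) {
  return i + L * (j + W * (k + H * (c + C * n)));
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, IntegerVector xdim, NumericVector w,
                        int K, int Cin, int Cout, NumericVector b, int pad) {
  const R_xlen_t L = xdim[0], W = xdim[1], H = xdim[2], N = xdim[4];
  const R_xlen_t HWL = L * W * H;
  NumericVector y(HWL * Cout * N);
  const double *xp = x.begin(), *wp = w.begin(), *bp = b.begin();
  double *yp = y.begin();
  const R_xlen_t K3 = (R_xlen_t)K * K * K;
  for (R_xlen_t n = 0; n < N; ++n) {
    for (R_xlen_t co = 0; co < Cout; ++co) {
      double *yb = yp + HWL * (co + (R_xlen_t)Cout * n);
      const double bias = bp[co];
      for (R_xlen_t v = 0; v < HWL; ++v) yb[v] = bias;
      for (R_xlen_t ci = 0; ci < Cin; ++ci) {
        const double *xb = xp + HWL * (ci + (R_xlen_t)Cin * n);
        const double *wb = wp + K3 * (ci + (R_xlen_t)Cin * co);
        for (int kz = 0; kz < K; ++kz) {
          const int oz = kz - pad;
          for (int ky = 0; ky < K; ++ky) {
            const int oy = ky - pad;
            for (int kx = 0; kx < K; ++kx) {
              const int ox = kx - pad;
              const double wv = wb[kx + K * (ky + K * kz)];
              if (wv == 0.0) continue;
              const R_xlen_t k0 = std::max((R_xlen_t)0, (R_xlen_t)-oz);
              const R_xlen_t k1 = std::min(H, H - oz);
              const R_xlen_t j0 = std::max((R_xlen_t)0, (R_xlen_t)-oy);
              const R_xlen_t j1 = std::min(W, W - oy);
              const R_xlen_t i0 = std::max((R_xlen_t)0, (R_xlen_t)-ox);
              const R_xlen_t i1 = std::min(L, L - ox);
              for (R_xlen_t k = k0; k < k1; ++k) {
                for (R_xlen_t j = j0; j < j1; ++j) {
                  double *yr = yb + L * (j + W * k);
                  const double *xr = xb + ox + L * ((j + oy) + W * (k + oz));
                  for (R_xlen_t i = i0; i < i1; ++i) yr[i] += wv * xr[i];
                }
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// gradient wrt input: dx[u] = sum_o w[o] * dy[u - o]
// [[Rcpp::export(name = ".conv3d_bw_x")]]
NumericVector conv3d_bw_x(NumericVector dy, IntegerVector xdim, NumericVector w,
                          int K, int Cin, int Cout, int pad) {
  const R_xlen_t L = xdim[0], W = xdim[1], H = xdim[2], N = xdim[4];
  const R_xlen_t HWL = L * W * H;
  NumericVector dx(HWL * Cin * N);
  const double *dyp = dy.begin(), *wp = w.begin();
  double *dxp = dx.begin();
  const R_xlen_t K3 = (R_xlen_t)K * K * K;
  for (R_xlen_t n = 0; n < N; ++n) {
    for (R_xlen_t ci = 0; ci < Cin; ++ci) {
      double *dxb = dxp + HWL * (ci + (R_xlen_t)Cin * n);
      for (R_xlen_t co = 0; co < Cout; ++co) {
        const double *dyb = dyp + HWL * (co + (R_xlen_t)Cout * n);
        const double *wb = wp + K3 * (ci + (R_xlen_t)Cin * co);
        for (int kz = 0; kz < K; ++kz) {
          const int oz = kz - pad;
          for (int ky = 0; ky < K; ++ky) {
            const int oy = ky - pad;
            for (int kx = 0; kx < K; ++kx) {
              const int ox = kx - pad;
              const double wv = wb[kx + K * (ky + K * kz)];
              if (wv == 0.0) continue;
              // dx[i,j,k] += wv * dy[i - ox, j - oy, k - oz]
              const R_xlen_t k0 = std::max((R_xlen_t)0, (R_xlen_t)oz);
              const R_xlen_t k1 = std::min(H, H + oz);
              const R_xlen_t j0 = std::max((R_xlen_t)0, (R_xlen_t)oy);
              const R_xlen_t j1 = std::min(W, W + oy);
              const R_xlen_t i0 = std::max((R_xlen_t)0, (R_xlen_t)ox);
              const R_xlen_t i1 = std::min(L, L + ox);
              for (R_xlen_t k = k0; k < k1; ++k) {
                for (R_xlen_t j = j0; j < j1; ++j) {
                  double *dxr = dxb + L * (j + W * k);
                  const double *dyr = dyb - ox + L * ((j - oy) + W * (k - oz));
                  for (R_xlen_t i = i0; i < i1; ++i) dxr[i] += wv * dyr[i];
                }
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// gradients wrt weights and bias
// [[Rcpp::export(name = ".conv3d_bw_w")]]
List conv3d_bw_w(NumericVector x, IntegerVector xdim, NumericVector dy, int K,
                 int Cin, int Cout, int pad) {
  const R_xlen_t L = xdim[0], W = xdim[1], H = xdim[2], N = xdim[4];
  const R_xlen_t HWL = L * W * H;
  const R_xlen_t K3 = (R_xlen_t)K * K * K;
  NumericVector dw(K3 * Cin * Cout), db(Cout);
  const double *xp = x.begin(), *dyp = dy.begin();
  double *dwp = dw.begin(), *dbp = db.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    for (R_xlen_t co = 0; co < Cout; ++co) {
      const double *dyb = dyp + HWL * (co + (R_xlen_t)Cout * n);
      double acc_b = 0.0;
      for (R_xlen_t v = 0; v < HWL; ++v) acc_b += dyb[v];
      dbp[co] += acc_b;
      for (R_xlen_t ci = 0; ci < Cin; ++ci) {
        const double *xb = xp + HWL * (ci + (R_xlen_t)Cin * n);
        double *dwb = dwp + K3 * (ci + (R_xlen_t)Cin * co);
        for (int kz = 0; kz < K; ++kz) {
          const int oz = kz - pad;
          for (int ky = 0; ky < K; ++ky) {
            const int oy = ky - pad;
            for (int kx = 0; kx < K; ++kx) {
              const int ox = kx - pad;
              const R_xlen_t k0 = std::max((R_xlen_t)0, (R_xlen_t)-oz);
              const R_xlen_t k1 = std::min(H, H - oz);
              const R_xlen_t j0 = std::max((R_xlen_t)0, (R_xlen_t)-oy);
              const R_xlen_t j1 = std::min(W, W - oy);
              const R_xlen_t i0 = std::max((R_xlen_t)0, (R_xlen_t)-ox);
              const R_xlen_t i1 = std::min(L, L - ox);
              double acc = 0.0;
              for (R_xlen_t k = k0; k < k1; ++k) {
                for (R_xlen_t j = j0; j < j1; ++j) {
                  const double *dyr = dyb + L * (j + W * k);
                  const double *xr = xb + ox + L * ((j + oy) + W * (k + oz));
                  for (R_xlen_t i = i0; i < i1; ++i) acc += dyr[i] * xr[i];
                }
              }
              dwb[kx + K * (ky + K * kz)] += acc;
            }
          }
        }
      }
    }
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// transpose convolution, kernel 2, stride 2: (l,w,h) -> (2l,2w,2h)
// weights dim (2,2,2,Cin,Cout)
// [[Rcpp::export(name = ".convtr2_fw")]]
NumericVector convtr2_fw(NumericVector x, IntegerVector xdim, NumericVector w,
                         int Cin, int Cout, NumericVector b) {
  const R_xlen_t l = xdim[0], wd = xdim[1], h = xdim[2], N = xdim[4];
  const R_xlen_t L = 2 * l, W = 2 * wd, H = 2 * h;
  const R_xlen_t hwl = l * wd * h, HWL = L * W * H;
  NumericVector y(HWL * Cout * N);
  const double *xp = x.begin(), *wp = w.begin(), *bp = b.begin();
  double *yp = y.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    for (R_xlen_t co = 0; co < Cout; ++co) {
      double *yb = yp + HWL * (co + (R_xlen_t)Cout * n);
      const double bias = bp[co];
      for (R_xlen_t v = 0; v < HWL; ++v) yb[v] = bias;
      for (R_xlen_t ci = 0; ci < Cin; ++ci) {
        const double *xb = xp + hwl * (ci + (R_xlen_t)Cin * n);
        const double *wb = wp + 8 * (ci + (R_xlen_t)Cin * co);
        for (int dz = 0; dz < 2; ++dz)
          for (int dyj = 0; dyj < 2; ++dyj)
            for (int dxi = 0; dxi < 2; ++dxi) {
              const double wv = wb[dxi + 2 * (dyj + 2 * dz)];
              for (R_xlen_t k = 0; k < h; ++k)
                for (R_xlen_t j = 0; j < wd; ++j) {
                  const double *xr = xb + l * (j + wd * k);
                  double *yr =
                      yb + L * ((2 * j + dyj) + W * (2 * k + dz)) + dxi;
                  for (R_xlen_t i = 0; i < l; ++i) yr[2 * i] += wv * xr[i];
                }
            }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convtr2_bw")]]
List convtr2_bw(NumericVector x, IntegerVector xdim, NumericVector dy,
                NumericVector w, int Cin, int Cout) {
  const R_xlen_t l = xdim[0], wd = xdim[1], h = xdim[2], N = xdim[4];
  const R_xlen_t L = 2 * l, W = 2 * wd, H = 2 * h;
  const R_xlen_t hwl = l * wd * h, HWL = L * W * H;
  NumericVector dx(hwl * Cin * N), dw(8 * Cin * Cout), db(Cout);
  const double *xp = x.begin(), *dyp = dy.begin(), *wp = w.begin();
  double *dxp = dx.begin(), *dwp = dw.begin(), *dbp = db.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    for (R_xlen_t co = 0; co < Cout; ++co) {
      const double *dyb = dyp + HWL * (co + (R_xlen_t)Cout * n);
      double acc_b = 0.0;
      for (R_xlen_t v = 0; v < HWL; ++v) acc_b += dyb[v];
      dbp[co] += acc_b;
      for (R_xlen_t ci = 0; ci < Cin; ++ci) {
        const double *xb = xp + hwl * (ci + (R_xlen_t)Cin * n);
        double *dxb = dxp + hwl * (ci + (R_xlen_t)Cin * n);
        const double *wb = wp + 8 * (ci + (R_xlen_t)Cin * co);
        double *dwb = dwp + 8 * (ci + (R_xlen_t)Cin * co);
        for (int dz = 0; dz < 2; ++dz)
          for (int dyj = 0; dyj < 2; ++dyj)
            for (int dxi = 0; dxi < 2; ++dxi) {
              const double wv = wb[dxi + 2 * (dyj + 2 * dz)];
              double acc_w = 0.0;
              for (R_xlen_t k = 0; k < h; ++k)
                for (R_xlen_t j = 0; j < wd; ++j) {
                  const double *xr = xb + l * (j + wd * k);
                  double *dxr = dxb + l * (j + wd * k);
                  const double *dyr =
                      dyb + L * ((2 * j + dyj) + W * (2 * k + dz)) + dxi;
                  for (R_xlen_t i = 0; i < l; ++i) {
                    const double g = dyr[2 * i];
                    dxr[i] += wv * g;
                    acc_w += xr[i] * g;
                  }
                }
              dwb[dxi + 2 * (dyj + 2 * dz)] += acc_w;
            }
      }
    }
  }
  return dx.size() ? List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db)
                   : List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// max pooling 2x2x2, stride 2; returns pooled values and 1-based argmax
// linear indices into x (per channel/sample plane included)
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x, IntegerVector xdim) {
  const R_xlen_t L = xdim[0], W = xdim[1], H = xdim[2], C = xdim[3],
                 N = xdim[4];
  const R_xlen_t l = L / 2, wd = W / 2, h = H / 2;
  NumericVector y(l * wd * h * C * N);
  NumericVector idx(y.size());
  const double *xp = x.begin();
  double *yp = y.begin(), *ip = idx.begin();
  R_xlen_t o = 0;
  for (R_xlen_t cn = 0; cn < C * N; ++cn) {
    const double *xb = xp + L * W * H * cn;
    const R_xlen_t base = L * W * H * cn;
    for (R_xlen_t k = 0; k < h; ++k)
      for (R_xlen_t j = 0; j < wd; ++j)
        for (R_xlen_t i = 0; i < l; ++i) {
          double best = -1e300;
          R_xlen_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dyj = 0; dyj < 2; ++dyj)
              for (int dxi = 0; dxi < 2; ++dxi) {
                const R_xlen_t u =
                    (2 * i + dxi) + L * ((2 * j + dyj) + W * (2 * k + dz));
                if (xb[u] > best) {
                  best = xb[u];
                  bi = u;
                }
              }
          yp[o] = best;
          ip[o] = (double)(base + bi + 1);
          ++o;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// connected-component labeling on a binary 3D mask, BFS, 6/18/26-connectivity.
// Labels are assigned in increasing order of each component's smallest linear
// (column-major) voxel index, so label ids are a deterministic scan order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int L = dim[0], W = dim[1], H = dim[2];
  const R_xlen_t nvox = (R_xlen_t)L * W * H;
  IntegerVector lab(nvox);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && l1 > 1) continue;
        if (connectivity == 18 && l1 > 2) continue;
        offs.push_back(dx);
        offs.push_back(dy);
        offs.push_back(dz);
      }
  const int noff = (int)offs.size() / 3;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t u = stack.back();
      stack.pop_back();
      const int i = (int)(u % L);
      const int j = (int)((u / L) % W);
      const int k = (int)(u / ((R_xlen_t)L * W));
      for (int t = 0; t < noff; ++t) {
        const int ii = i + offs[3 * t], jj = j + offs[3 * t + 1],
                  kk = k + offs[3 * t + 2];
        if (ii < 0 || ii >= L || jj < 0 || jj >= W || kk < 0 || kk >= H)
          continue;
        const R_xlen_t v = ii + (R_xlen_t)L * (jj + (R_xlen_t)W * kk);
        if (mask[v] != 0 && lab[v] == 0) {
          lab[v] = next;
          stack.push_back(v);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// binary dilation by `steps` applications of the 6-connected unit ball
// [[Rcpp::export(name = ".dilate6")]]
IntegerVector dilate6(IntegerVector mask, IntegerVector dim, int steps) {
  const int L = dim[0], W = dim[1], H = dim[2];
  const R_xlen_t nvox = (R_xlen_t)L * W * H;
  std::vector<int> cur(mask.begin(), mask.end()), nxt(nvox);
  for (int s = 0; s < steps; ++s) {
    for (int k = 0; k < H; ++k)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < L; ++i) {
          const R_xlen_t u = i + (R_xlen_t)L * (j + (R_xlen_t)W * k);
          int v = cur[u];
          if (!v) {
            if (i > 0 && cur[u - 1]) v = 1;
            else if (i < L - 1 && cur[u + 1]) v = 1;
            else if (j > 0 && cur[u - L]) v = 1;
            else if (j < W - 1 && cur[u + L]) v = 1;
            else if (k > 0 && cur[u - (R_xlen_t)L * W]) v = 1;
            else if (k < H - 1 && cur[u + (R_xlen_t)L * W]) v = 1;
          }
          nxt[u] = v;
        }
    cur.swap(nxt);
  }
  IntegerVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// trilinear affine resampling of a 3D array: for each destination voxel d,
// source coordinate = A %*% (d - c) + c + t (0-based), outside -> fill.
// [[Rcpp::export(name = ".affine_resample")]]
NumericVector affine_resample(NumericVector x, IntegerVector dim,
                              NumericVector A, NumericVector centre,
                              NumericVector shift, double fill, bool nearest) {
  const int L = dim[0], W = dim[1], H = dim[2];
  NumericVector y((R_xlen_t)L * W * H);
  const double *xp = x.begin();
  double *yp = y.begin();
  const double cx = centre[0], cy = centre[1], cz = centre[2];
  R_xlen_t o = 0;
  for (int k = 0; k < H; ++k)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < L; ++i) {
        const double di = i - cx, dj = j - cy, dk = k - cz;
        const double sx = A[0] * di + A[3] * dj + A[6] * dk + cx + shift[0];
        const double sy = A[1] * di + A[4] * dj + A[7] * dk + cy + shift[1];
        const double sz = A[2] * di + A[5] * dj + A[8] * dk + cz + shift[2];
        double val = fill;
        if (nearest) {
          const int ri = (int)std::lround(sx), rj = (int)std::lround(sy),
                    rk = (int)std::lround(sz);
          if (ri >= 0 && ri < L && rj >= 0 && rj < W && rk >= 0 && rk < H)
            val = xp[ri + (R_xlen_t)L * (rj + (R_xlen_t)W * rk)];
        } else {
          const int fx = (int)std::floor(sx), fy = (int)std::floor(sy),
                    fz = (int)std::floor(sz);
          if (sx >= 0 && sx <= L - 1 && sy >= 0 && sy <= W - 1 && sz >= 0 &&
              sz <= H - 1) {
            const double ax = sx - fx, ay = sy - fy, az = sz - fz;
            const int x1 = std::min(fx + 1, L - 1), y1 = std::min(fy + 1, W - 1),
                      z1 = std::min(fz + 1, H - 1);
            double acc = 0.0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy2 = 0; dy2 < 2; ++dy2)
                for (int dx2 = 0; dx2 < 2; ++dx2) {
                  const double wgt = (dx2 ? ax : 1 - ax) * (dy2 ? ay : 1 - ay) *
                                     (dz ? az : 1 - az);
                  if (wgt == 0.0) continue;
                  acc += wgt * xp[(dx2 ? x1 : fx) +
                                  (R_xlen_t)L * ((dy2 ? y1 : fy) +
                                                 (R_xlen_t)W * (dz ? z1 : fz))];
                }
            val = acc;
          }
        }
        yp[o++] = val;
      }
  return y;
}
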