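// Low-level image and network kernels.
//
// Conventions shared with the R side:
//  * image batches are column-major arrays [H, W, C, N];
//  * 3x3 convolution weights are (9*Cin) x Cout matrices whose row index is
//    r = (kh+1) + 3*(kw+1) + 9*c  with kernel offsets kh, kw in {-1, 0, 1};
//  * voxel indices in affine resampling are 0-based.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fill colsT (HW x 9Cin) with the im2col expansion (zero-padded borders) of
// one slice of the batch. Each column of colsT is contiguous, so the inner
// copy is a strided shift of one image column.
static void im2col_t(const double* x, int H, int W, int C, arma::mat& colsT) {
  const int HW = H * W;
  colsT.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        const int r = (kh + 1) + 3 * (kw + 1) + 9 * c;
        double* dst = colsT.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kw;
          if (sw < 0 || sw >= W) continue;
          const double* src = xc + (size_t)sw * H;
          const int h0 = std::max(0, -kh);
          const int h1 = H - 1 - std::max(0, kh);
          std::memcpy(dst + (size_t)w * H + h0, src + h0 + kh,
                      (size_t)(h1 - h0 + 1) * sizeof(double));
        }
      }
    }
  }
}

// Scatter-add the gradient of the im2col expansion back onto the input grid.
static void col2im_t_add(const arma::mat& dcolsT, int H, int W, int C, double* dx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (size_t)c * HW;
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        const int r = (kh + 1) + 3 * (kw + 1) + 9 * c;
        const double* src = dcolsT.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kw;
          if (sw < 0 || sw >= W) continue;
          double* dst = dxc + (size_t)sw * H;
          const int h0 = std::max(0, -kh);
          const int h1 = H - 1 - std::max(0, kh);
          for (int h = h0; h <= h1; ++h) dst[h + kh] += src[(size_t)w * H + h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3x3_fwd(NumericVector x, IntegerVector xdim,
                              NumericMatrix w, NumericVector b) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int HW = H * W;
  const int Cout = w.ncol();
  if (w.nrow() != 9 * C) stop("weight rows must equal 9 * input channels");
  NumericVector y((size_t)HW * Cout * N);
  arma::mat Wm(w.begin(), w.nrow(), Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat colsT(HW, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * HW * C, H, W, C, colsT);
    arma::mat Y(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Y = colsT * Wm;
    Y.each_row() += bv;
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3x3_bwd(NumericVector x, IntegerVector xdim,
                     NumericMatrix w, NumericVector dy) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int HW = H * W;
  const int Cout = w.ncol();
  NumericVector dx((size_t)HW * C * N);
  NumericMatrix dw(w.nrow(), Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), w.nrow(), Cout, false, true);
  arma::mat dWm(dw.begin(), w.nrow(), Cout, false, true);
  arma::rowvec dbv(Cout, arma::fill::zeros);
  arma::mat colsT(HW, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * HW * C, H, W, C, colsT);
    arma::mat DY(dy.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    dWm += colsT.t() * DY;
    dbv += arma::sum(DY, 0);
    arma::mat dcolsT = DY * Wm.t();
    col2im_t_add(dcolsT, H, W, C, dx.begin() + (size_t)n * HW * C);
  }
  std::copy(dbv.begin(), dbv.end(), db.begin());
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector arg(y.size());
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t best = base + (size_t)(2 * w) * H + 2 * h;
          double bv = x[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int k = 0; k < 3; ++k)
            if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
          y[o] = bv;
          arg[o] = (int)best; // safe: grids used here stay below 2^31 elements
          ++o;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector argmax, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * H * W;
      double* ys = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        const double* col = xs + (size_t)(w / 2) * H;
        double* dst = ys + (size_t)w * Ho;
        for (int h = 0; h < Ho; ++h) dst[h] = col[h / 2];
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector ydim) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* ds = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* xs = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w) {
        double* dst = xs + (size_t)(w / 2) * H;
        const double* col = ds + (size_t)w * Ho;
        for (int h = 0; h < Ho; ++h) dst[h / 2] += col[h];
      }
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Keys cubic convolution kernel (a = -0.5), support [-2, 2].
static inline double keys3(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// Resample a 3D volume: out voxel (i,j,k) takes the source value at
// M %*% c(i,j,k,1) (0-based voxel coordinates). method 0 = nearest
// neighbour, 1 = trilinear, 2 = tricubic (Keys); samples outside the
// source grid read `cval`.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector src, IntegerVector sdim,
                             IntegerVector odim, NumericMatrix M,
                             int method, double cval) {
  const int S1 = sdim[0], S2 = sdim[1], S3 = sdim[2];
  const int O1 = odim[0], O2 = odim[1], O3 = odim[2];
  NumericVector out((size_t)O1 * O2 * O3);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  const double* s = src.begin();
  size_t o = 0;
  for (int k = 0; k < O3; ++k)
    for (int j = 0; j < O2; ++j)
      for (int i = 0; i < O1; ++i, ++o) {
        const double x = m00 * i + m01 * j + m02 * k + m03;
        const double y = m10 * i + m11 * j + m12 * k + m13;
        const double z = m20 * i + m21 * j + m22 * k + m23;
        if (method == 0) {
          const int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
          out[o] = (xi < 0 || xi >= S1 || yi < 0 || yi >= S2 || zi < 0 || zi >= S3)
                     ? cval : s[(size_t)zi * S1 * S2 + (size_t)yi * S1 + xi];
        } else if (method == 2) {
          const int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
          double acc = 0.0;
          for (int dz = -1; dz <= 2; ++dz) {
            const double wz = keys3(z - (z0 + dz));
            if (wz == 0.0) continue;
            for (int dyy = -1; dyy <= 2; ++dyy) {
              const double wy = keys3(y - (y0 + dyy));
              if (wy == 0.0) continue;
              for (int dxx = -1; dxx <= 2; ++dxx) {
                const double wx = keys3(x - (x0 + dxx));
                if (wx == 0.0) continue;
                const int xi = x0 + dxx, yi = y0 + dyy, zi = z0 + dz;
                const double v = (xi < 0 || xi >= S1 || yi < 0 || yi >= S2 || zi < 0 || zi >= S3)
                                   ? cval : s[(size_t)zi * S1 * S2 + (size_t)yi * S1 + xi];
                acc += wx * wy * wz * v;
              }
            }
          }
          out[o] = acc;
        } else {
          const int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
          const double fx = x - x0, fy = y - y0, fz = z - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dyy = 0; dyy <= 1; ++dyy)
              for (int dxx = 0; dxx <= 1; ++dxx) {
                const double wt = (dxx ? fx : 1 - fx) * (dyy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                if (wt == 0.0) continue;
                const int xi = x0 + dxx, yi = y0 + dyy, zi = z0 + dz;
                const double v = (xi < 0 || xi >= S1 || yi < 0 || yi >= S2 || zi < 0 || zi >= S3)
                                   ? cval : s[(size_t)zi * S1 * S2 + (size_t)yi * S1 + xi];
                acc += wt * v;
              }
          out[o] = acc;
        }
      }
  out.attr("dim") = odim;
  return out;
}

// Label foreground (non-zero) voxels of a 3D grid into connected components
// (connectivity 6, 18 or 26) by breadth-first search. Labels are 1..K in
// order of first (column-major) encounter; background stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector arr, IntegerVector dim3, int connectivity) {
  const int D1 = dim3[0], D2 = dim3[1], D3 = dim3[2];
  const size_t n = (size_t)D1 * D2 * D3;
  IntegerVector lab(n);
  std::vector<std::array<int,3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2)) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<size_t> stack;
  for (size_t start = 0; start < n; ++start) {
    if (arr[start] == 0.0 || lab[start] != 0) continue;
    lab[start] = ++next;
    stack.push_back(start);
    while (!stack.empty()) {
      const size_t cur = stack.back(); stack.pop_back();
      const int z = (int)(cur / ((size_t)D1 * D2));
      const int rem = (int)(cur % ((size_t)D1 * D2));
      const int y = rem / D1, x = rem % D1;
      for (const auto& d : nb) {
        const int xi = x + d[0], yi = y + d[1], zi = z + d[2];
        if (xi < 0 || xi >= D1 || yi < 0 || yi >= D2 || zi < 0 || zi >= D3) continue;
        const size_t q = (size_t)zi * D1 * D2 + (size_t)yi * D1 + xi;
        if (arr[q] != 0.0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim3;
  return lab;
}

// Directed Hausdorff term: max over rows of A of the min distance to B.
// A, B are point sets (rows) in mm.
// [[Rcpp::export]]
double cpp_directed_maxmin(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  double worst = 0.0;
  for (int i = 0; i < na; ++i) {
    const double ax = A(i,0), ay = A(i,1), az = A(i,2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; if (best <= worst) break; }
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}

// Separable Gaussian smoothing with zero padding; sigma per axis in voxels.
// Kernels are normalized to unit sum, so interior mass is conserved.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3d(NumericVector arr, IntegerVector dim3, NumericVector sigma) {
  const int D[3] = {dim3[0], dim3[1], dim3[2]};
  const size_t n = (size_t)D[0] * D[1] * D[2];
  std::vector<double> cur(arr.begin(), arr.end()), nxt(n);
  for (int ax = 0; ax < 3; ++ax) {
    const double sg = sigma[ax];
    if (sg <= 0) continue;
    const int rad = std::max(1, (int)std::ceil(3.5 * sg));
    std::vector<double> ker(2 * rad + 1);
    double ks = 0;
    for (int t = -rad; t <= rad; ++t) { ker[t + rad] = std::exp(-0.5 * t * t / (sg * sg)); ks += ker[t + rad]; }
    for (auto& v : ker) v /= ks;
    const size_t stride = (ax == 0) ? 1 : (ax == 1) ? (size_t)D[0] : (size_t)D[0] * D[1];
    const int len = D[ax];
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (size_t idx = 0; idx < n; ++idx) {
      const int pos = (ax == 0) ? (int)(idx % D[0])
                    : (ax == 1) ? (int)((idx / D[0]) % D[1])
                                : (int)(idx / ((size_t)D[0] * D[1]));
      double acc = 0;
      const int t0 = std::max(-rad, -pos), t1 = std::min(rad, len - 1 - pos);
      for (int t = t0; t <= t1; ++t) acc += ker[t + rad] * cur[idx + (size_t)t * stride];
      nxt[idx] = acc;
    }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim3;
  return out;
}
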