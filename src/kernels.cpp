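// Low-level 3D kernels: valid 3x3x3 convolution (forward/backward, im2col +
// GEMM in single precision), separable Gaussian smoothing, trilinear warping,
// connected components, modal label filtering, binary dilation, and nearest-
// neighbour mask distances. All R-facing arrays are double, column-major,
// with spatial axes first.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// im2col for a single sample: x is [X,Y,Z,Ci] (contiguous), result is
// [ov x 27*Ci] with ov = (X-2)(Y-2)(Z-2); column di+3dj+9dk+27ci matches the
// column-major reshape of a [3,3,3,Ci,Co] filter array.
static void im2col3(const double* x, int X, int Y, int Z, int Ci,
                    arma::fmat& K) {
  const int ox = X - 2, oy = Y - 2, oz = Z - 2;
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = x + (size_t)ci * X * Y * Z;
    for (int dk = 0; dk < 3; ++dk)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di) {
          float* col = K.colptr(di + 3 * dj + 9 * dk + 27 * ci);
          for (int ok = 0; ok < oz; ++ok)
            for (int oj = 0; oj < oy; ++oj) {
              const double* src =
                  xc + (size_t)(di) + X * ((size_t)(oj + dj) + (size_t)Y * (ok + dk));
              float* dst = col + ox * (oj + (size_t)oy * ok);
              for (int oi = 0; oi < ox; ++oi) dst[oi] = (float)src[oi];
            }
        }
  }
}

// Valid 3x3x3 convolution. x: [X,Y,Z,Ci,B]; w: [3,3,3,Ci,Co]; b: length Co.
// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], B = xd[4];
  const int Co = wd[4];
  const int ox = X - 2, oy = Y - 2, oz = Z - 2;
  const size_t ov = (size_t)ox * oy * oz;
  arma::fmat Wm(27 * Ci, Co);
  for (size_t i = 0; i < Wm.n_elem; ++i) Wm[i] = (float)w[i];
  arma::frowvec bias(Co);
  for (int c = 0; c < Co; ++c) bias[c] = (float)b[c];
  NumericVector out((R_xlen_t)(ov * Co * B));
  out.attr("dim") = IntegerVector::create(ox, oy, oz, Co, B);
  arma::fmat K(ov, 27 * Ci);
  for (int s = 0; s < B; ++s) {
    im2col3(REAL(x) + (size_t)s * X * Y * Z * Ci, X, Y, Z, Ci, K);
    arma::fmat Yb = K * Wm;
    Yb.each_row() += bias;
    double* dst = REAL(out) + (size_t)s * ov * Co;
    for (size_t i = 0; i < ov * (size_t)Co; ++i) dst[i] = (double)Yb[i];
  }
  return out;
}

// Backward pass of the valid 3x3x3 convolution. gy: [ox,oy,oz,Co,B].
// Returns grad wrt input, filters and biases.
// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], B = xd[4];
  const int Co = wd[4];
  const int ox = X - 2, oy = Y - 2, oz = Z - 2;
  const size_t ov = (size_t)ox * oy * oz;
  arma::fmat Wm(27 * Ci, Co);
  for (size_t i = 0; i < Wm.n_elem; ++i) Wm[i] = (float)w[i];
  arma::fmat GW(27 * Ci, Co, arma::fill::zeros);
  arma::fvec GB(Co, arma::fill::zeros);
  NumericVector gx((R_xlen_t)x.size());
  gx.attr("dim") = xd;
  arma::fmat K(ov, 27 * Ci), Gy(ov, Co);
  for (int s = 0; s < B; ++s) {
    const double* gys = REAL(gy) + (size_t)s * ov * Co;
    for (size_t i = 0; i < ov * (size_t)Co; ++i) Gy[i] = (float)gys[i];
    im2col3(REAL(x) + (size_t)s * X * Y * Z * Ci, X, Y, Z, Ci, K);
    GW += K.t() * Gy;
    GB += arma::sum(Gy, 0).t();
    arma::fmat Gx = Gy * Wm.t();  // ov x 27Ci, scatter back (col2im)
    double* gxs = REAL(gx) + (size_t)s * X * Y * Z * Ci;
    for (int ci = 0; ci < Ci; ++ci) {
      double* gxc = gxs + (size_t)ci * X * Y * Z;
      for (int dk = 0; dk < 3; ++dk)
        for (int dj = 0; dj < 3; ++dj)
          for (int di = 0; di < 3; ++di) {
            const float* col = Gx.colptr(di + 3 * dj + 9 * dk + 27 * ci);
            for (int ok = 0; ok < oz; ++ok)
              for (int oj = 0; oj < oy; ++oj) {
                double* dst =
                    gxc + (size_t)di + X * ((size_t)(oj + dj) + (size_t)Y * (ok + dk));
                const float* src = col + ox * (oj + (size_t)oy * ok);
                for (int oi = 0; oi < ox; ++oi) dst[oi] += (double)src[oi];
              }
          }
    }
  }
  NumericVector gwv((R_xlen_t)w.size());
  gwv.attr("dim") = wd;
  for (size_t i = 0; i < GW.n_elem; ++i) gwv[i] = (double)GW[i];
  NumericVector gbv(Co);
  for (int c = 0; c < Co; ++c) gbv[c] = (double)GB[c];
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// Separable Gaussian smoothing of a 3D array, reflect boundary, kernel
// truncated at `truncate` standard deviations (radius >= 1).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector x, double sigma, double truncate) {
  IntegerVector d = x.attr("dim");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  int radius = (int)std::ceil(truncate * sigma);
  if (radius < 1) radius = 1;
  std::vector<double> ker(2 * radius + 1);
  double ksum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    ker[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    ksum += ker[i + radius];
  }
  for (auto& v : ker) v /= ksum;
  std::vector<double> buf(x.begin(), x.end()), tmp(buf.size());
  const int n[3] = {n0, n1, n2};
  const size_t stride[3] = {1, (size_t)n0, (size_t)n0 * n1};
  for (int ax = 0; ax < 3; ++ax) {
    const int na = n[ax];
    const size_t sa = stride[ax];
    // iterate over all lines along axis ax
    for (int k = 0; k < n2; ++k)
      for (int j = 0; j < n1; ++j)
        for (int i = 0; i < n0; ++i) {
          int idx3[3] = {i, j, k};
          if (idx3[ax] != 0) continue;  // start of line only
          size_t base = (size_t)i + stride[1] * j + stride[2] * k;
          for (int p = 0; p < na; ++p) {
            double acc = 0.0;
            for (int q = -radius; q <= radius; ++q) {
              int pp = p + q;
              // reflect (scipy-style: mirror about edge midpoint)
              while (pp < 0 || pp >= na) {
                if (pp < 0) pp = -pp - 1;
                if (pp >= na) pp = 2 * na - pp - 1;
              }
              acc += ker[q + radius] * buf[base + sa * pp];
            }
            tmp[base + sa * p] = acc;
          }
        }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = d;
  return out;
}

// Trilinear warp: out(v) = vol(v + d(v)), displacements in voxel units,
// sample positions clamped to the grid.
// [[Rcpp::export]]
NumericVector cpp_warp_trilinear(NumericVector vol, NumericVector dx,
                                 NumericVector dy, NumericVector dz) {
  IntegerVector d = vol.attr("dim");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  NumericVector out((R_xlen_t)vol.size());
  out.attr("dim") = d;
  const double* v = REAL(vol);
  size_t idx = 0;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i, ++idx) {
        double px = i + dx[idx], py = j + dy[idx], pz = k + dz[idx];
        if (px < 0) px = 0; if (px > n0 - 1) px = n0 - 1;
        if (py < 0) py = 0; if (py > n1 - 1) py = n1 - 1;
        if (pz < 0) pz = 0; if (pz > n2 - 1) pz = n2 - 1;
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
            z0 = (int)std::floor(pz);
        int x1 = clampi(x0 + 1, 0, n0 - 1), y1 = clampi(y0 + 1, 0, n1 - 1),
            z1 = clampi(z0 + 1, 0, n2 - 1);
        x0 = clampi(x0, 0, n0 - 1); y0 = clampi(y0, 0, n1 - 1);
        z0 = clampi(z0, 0, n2 - 1);
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        #define V(a, b, c) v[(size_t)(a) + n0 * ((size_t)(b) + (size_t)n1 * (c))]
        double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
        double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
        double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
        double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
        #undef V
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[idx] = c0 * (1 - fz) + c1 * fz;
      }
  return out;
}

// Connected components of a binary mask (6 or 26 connectivity). Component ids
// are assigned in scan order of each component's first-encountered voxel.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  IntegerVector lab((R_xlen_t)mask.size());
  lab.attr("dim") = d;
  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({di, dj, dk});
      }
  int next = 0;
  std::queue<size_t> q;
  size_t idx = 0;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i, ++idx) {
        if (mask[idx] == 0 || lab[idx] != 0) continue;
        lab[idx] = ++next;
        q.push(idx);
        while (!q.empty()) {
          size_t cur = q.front(); q.pop();
          int ci = cur % n0, cj = (cur / n0) % n1, ck = cur / ((size_t)n0 * n1);
          for (auto& o : nb) {
            int ii = ci + o[0], jj = cj + o[1], kk = ck + o[2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n0 || jj >= n1 || kk >= n2)
              continue;
            size_t nidx = (size_t)ii + n0 * ((size_t)jj + (size_t)n1 * kk);
            if (mask[nidx] != 0 && lab[nidx] == 0) {
              lab[nidx] = next;
              q.push(nidx);
            }
          }
        }
      }
  return lab;
}

// Modal 3x3x3 label filter, edge-truncated neighbourhoods; any tie for the
// modal label keeps the original voxel label.
// [[Rcpp::export]]
IntegerVector cpp_mode_filter3(IntegerVector lab) {
  IntegerVector d = lab.attr("dim");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  IntegerVector out((R_xlen_t)lab.size());
  out.attr("dim") = d;
  int maxlab = 0;
  for (R_xlen_t i = 0; i < lab.size(); ++i)
    if (lab[i] > maxlab) maxlab = lab[i];
  std::vector<int> cnt(maxlab + 1);
  size_t idx = 0;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i, ++idx) {
        std::fill(cnt.begin(), cnt.end(), 0);
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= n0 || jj >= n1 || kk >= n2)
                continue;
              ++cnt[lab[(size_t)ii + n0 * ((size_t)jj + (size_t)n1 * kk)]];
            }
        int best = -1, bestc = -1; bool tie = false;
        for (int l = 0; l <= maxlab; ++l) {
          if (cnt[l] > bestc) { bestc = cnt[l]; best = l; tie = false; }
          else if (cnt[l] == bestc) tie = true;
        }
        out[idx] = tie ? lab[idx] : best;
      }
  return out;
}

// Binary dilation with the full 3x3x3 structuring element, one iteration.
// [[Rcpp::export]]
IntegerVector cpp_dilate333(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  IntegerVector out((R_xlen_t)mask.size());
  out.attr("dim") = d;
  size_t idx = 0;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i, ++idx) {
        int hit = 0;
        for (int dk = -1; dk <= 1 && !hit; ++dk)
          for (int dj = -1; dj <= 1 && !hit; ++dj)
            for (int di = -1; di <= 1 && !hit; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= n0 || jj >= n1 || kk >= n2)
                continue;
              if (mask[(size_t)ii + n0 * ((size_t)jj + (size_t)n1 * kk)] != 0)
                hit = 1;
            }
        out[idx] = hit;
      }
  return out;
}

// For each row of A (world-space mm coordinates), the Euclidean distance to
// the nearest row of R.
// [[Rcpp::export]]
NumericVector cpp_min_nn_dists(NumericMatrix A, NumericMatrix R) {
  const int n = A.nrow(), m = R.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = ax - R(j, 0), dy = ay - R(j, 1), dz = az - R(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
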