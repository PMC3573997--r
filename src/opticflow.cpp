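#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Images are R matrices indexed (row, col) = (y, x); coordinates passed in and
// out of these routines are 0-based, sub-pixel, x right / y down.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// bilinear sample with replicated border
static inline double bilin(const NumericMatrix &img, double x, double y) {
  const int W = img.ncol(), H = img.nrow();
  x = clampd(x, 0.0, W - 1.0);
  y = clampd(y, 0.0, H - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < W ? x0 + 1 : W - 1;
  int y1 = y0 + 1 < H ? y0 + 1 : H - 1;
  double ax = x - x0, ay = y - y0;
  return (1 - ax) * (1 - ay) * img(y0, x0) + ax * (1 - ay) * img(y0, x1) +
         (1 - ax) * ay * img(y1, x0) + ax * ay * img(y1, x1);
}

// [1 2 1]/4 separable smoothing followed by factor-2 decimation
static NumericMatrix pyr_down(const NumericMatrix &img) {
  const int H = img.nrow(), W = img.ncol();
  const int h = (H + 1) / 2, w = (W + 1) / 2;
  NumericMatrix tmp(H, W), out(h, w);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int xm = x > 0 ? x - 1 : 0, xp = x + 1 < W ? x + 1 : W - 1;
      tmp(y, x) = 0.25 * img(y, xm) + 0.5 * img(y, x) + 0.25 * img(y, xp);
    }
  }
  for (int y = 0; y < h; ++y) {
    int sy = 2 * y;
    int ym = sy > 0 ? sy - 1 : 0, yp = sy + 1 < H ? sy + 1 : H - 1;
    for (int x = 0; x < w; ++x) {
      int sx = 2 * x;
      out(y, x) = 0.25 * tmp(ym, sx) + 0.5 * tmp(sy, sx) + 0.25 * tmp(yp, sx);
    }
  }
  return out;
}

// Minimum eigenvalue of the structure tensor summed over a (2r+1)^2 window
// (Shi-Tomasi corner response). Border of width r+1 is zeroed.
// [[Rcpp::export]]
NumericMatrix st_response_cpp(NumericMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix ix(H, W), iy(H, W), out(H, W);
  for (int y = 1; y < H - 1; ++y)
    for (int x = 1; x < W - 1; ++x) {
      ix(y, x) = 0.5 * (img(y, x + 1) - img(y, x - 1));
      iy(y, x) = 0.5 * (img(y + 1, x) - img(y - 1, x));
    }
  // integral images of the tensor entries
  std::vector<double> sxx((H + 1) * (W + 1), 0.0), syy((H + 1) * (W + 1), 0.0),
      sxy((H + 1) * (W + 1), 0.0);
  const int stride = W + 1;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double gx = ix(y, x), gy = iy(y, x);
      size_t i = (size_t)(y + 1) * stride + (x + 1);
      sxx[i] = gx * gx + sxx[i - 1] + sxx[i - stride] - sxx[i - stride - 1];
      syy[i] = gy * gy + syy[i - 1] + syy[i - stride] - syy[i - stride - 1];
      sxy[i] = gx * gy + sxy[i - 1] + sxy[i - stride] - sxy[i - stride - 1];
    }
  const int b = radius + 1;  // gradient border is invalid too
  for (int y = b; y < H - b; ++y)
    for (int x = b; x < W - b; ++x) {
      int y0 = y - radius, y1 = y + radius + 1;
      int x0 = x - radius, x1 = x + radius + 1;
      size_t i11 = (size_t)y1 * stride + x1, i01 = (size_t)y0 * stride + x1,
             i10 = (size_t)y1 * stride + x0, i00 = (size_t)y0 * stride + x0;
      double a = sxx[i11] - sxx[i01] - sxx[i10] + sxx[i00];
      double c = syy[i11] - syy[i01] - syy[i10] + syy[i00];
      double bb = sxy[i11] - sxy[i01] - sxy[i10] + sxy[i00];
      out(y, x) = 0.5 * ((a + c) - std::sqrt((a - c) * (a - c) + 4.0 * bb * bb));
    }
  return out;
}

// Pyramidal Lucas-Kanade sparse tracking.
// pts: n x 2 matrix of 0-based (x, y); returns n x 2 next positions + status.
// [[Rcpp::export]]
List lk_track_cpp(NumericMatrix prev_img, NumericMatrix next_img, NumericMatrix pts,
                  int win_radius, int levels, int max_iter, double eps,
                  double min_eig_floor) {
  const int n = pts.nrow();
  std::vector<NumericMatrix> pyr_prev, pyr_next;
  pyr_prev.push_back(prev_img);
  pyr_next.push_back(next_img);
  for (int l = 1; l < levels; ++l) {
    const NumericMatrix &p = pyr_prev.back();
    if (p.nrow() < 2 * (win_radius + 2) || p.ncol() < 2 * (win_radius + 2)) break;
    pyr_prev.push_back(pyr_down(pyr_prev.back()));
    pyr_next.push_back(pyr_down(pyr_next.back()));
  }
  const int L = (int)pyr_prev.size();
  const int wside = 2 * win_radius + 1;
  const int npix = wside * wside;
  std::vector<double> patch(npix), gx(npix), gy(npix);

  NumericMatrix out(n, 2);
  LogicalVector status(n);
  for (int f = 0; f < n; ++f) {
    double px = pts(f, 0), py = pts(f, 1);
    double gxv = 0.0, gyv = 0.0;  // accumulated guess at current level scale
    bool ok = true;
    for (int l = L - 1; l >= 0; --l) {
      const NumericMatrix &A = pyr_prev[l];
      const NumericMatrix &B = pyr_next[l];
      const double scale = std::ldexp(1.0, -l);  // 2^-l
      const double cx = px * scale, cy = py * scale;
      // template patch and gradients from prev at this level
      double G11 = 0.0, G12 = 0.0, G22 = 0.0;
      int k = 0;
      for (int wy = -win_radius; wy <= win_radius; ++wy)
        for (int wx = -win_radius; wx <= win_radius; ++wx, ++k) {
          double sx = cx + wx, sy = cy + wy;
          patch[k] = bilin(A, sx, sy);
          gx[k] = 0.5 * (bilin(A, sx + 1, sy) - bilin(A, sx - 1, sy));
          gy[k] = 0.5 * (bilin(A, sx, sy + 1) - bilin(A, sx, sy - 1));
          G11 += gx[k] * gx[k];
          G12 += gx[k] * gy[k];
          G22 += gy[k] * gy[k];
        }
      double tr = G11 + G22;
      double min_eig =
          0.5 * (tr - std::sqrt((G11 - G22) * (G11 - G22) + 4.0 * G12 * G12));
      if (min_eig / npix < min_eig_floor) { ok = false; break; }
      double det = G11 * G22 - G12 * G12;
      double vx = 0.0, vy = 0.0;
      for (int it = 0; it < max_iter; ++it) {
        double b1 = 0.0, b2 = 0.0;
        k = 0;
        for (int wy = -win_radius; wy <= win_radius; ++wy)
          for (int wx = -win_radius; wx <= win_radius; ++wx, ++k) {
            double d = patch[k] -
                       bilin(B, cx + wx + gxv + vx, cy + wy + gyv + vy);
            b1 += d * gx[k];
            b2 += d * gy[k];
          }
        double ux = (G22 * b1 - G12 * b2) / det;
        double uy = (G11 * b2 - G12 * b1) / det;
        vx += ux;
        vy += uy;
        if (ux * ux + uy * uy < eps * eps) break;
      }
      gxv += vx;
      gyv += vy;
      if (l > 0) { gxv *= 2.0; gyv *= 2.0; }
    }
    double nx = px + gxv, ny = py + gyv;
    if (ok) {
      if (nx < 0 || ny < 0 || nx > next_img.ncol() - 1.0 || ny > next_img.nrow() - 1.0)
        ok = false;
    }
    out(f, 0) = ok ? nx : NA_REAL;
    out(f, 1) = ok ? ny : NA_REAL;
    status[f] = ok;
  }
  return List::create(_["positions"] = out, _["status"] = status);
}
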