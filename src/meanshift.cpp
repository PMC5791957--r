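#include <Rcpp.h>
using namespace Rcpp;

// Mean-shift filtering of a 3-channel raster (Comaniciu-Meer style) with a
// flat kernel in the joint spatial-range domain. Each pixel's (x, y, c)
// point iterates to the local mode: at every step the mean of the original
// samples within `hs` pixels spatially AND within `hr` in colour of the
// current point replaces it. The filtered image keeps each pixel at its
// original grid position with its converged colour.
//
// c1..c3 are H x W matrices (any colour space; the caller uses CIE-L*u*v*
// so that `hr` is a perceptual distance).
// [[Rcpp::export]]
List ms_filter_cpp(NumericMatrix c1, NumericMatrix c2, NumericMatrix c3,
                   int hs, double hr, int max_iter, double tol) {
  const int H = c1.nrow(), W = c1.ncol();
  NumericMatrix o1(H, W), o2(H, W), o3(H, W);
  const double hr2 = hr * hr, hs2 = (double)hs * hs;

  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double px = x, py = y;
      double v1 = c1(y, x), v2 = c2(y, x), v3 = c3(y, x);
      for (int it = 0; it < max_iter; ++it) {
        int xc = (int)std::lround(px), yc = (int)std::lround(py);
        int x0 = std::max(0, xc - hs), x1 = std::min(W - 1, xc + hs);
        int y0 = std::max(0, yc - hs), y1 = std::min(H - 1, yc + hs);
        double sx = 0, sy = 0, s1 = 0, s2 = 0, s3 = 0;
        int n = 0;
        for (int xx = x0; xx <= x1; ++xx) {
          double dx = xx - px;
          for (int yy = y0; yy <= y1; ++yy) {
            double dy = yy - py;
            if (dx * dx + dy * dy > hs2) continue;
            double d1 = c1(yy, xx) - v1, d2 = c2(yy, xx) - v2,
                   d3 = c3(yy, xx) - v3;
            if (d1 * d1 + d2 * d2 + d3 * d3 > hr2) continue;
            sx += xx; sy += yy;
            s1 += c1(yy, xx); s2 += c2(yy, xx); s3 += c3(yy, xx);
            ++n;
          }
        }
        if (n == 0) break;
        double nx = sx / n, ny = sy / n;
        double n1 = s1 / n, n2 = s2 / n, n3 = s3 / n;
        double shift = (nx - px) * (nx - px) + (ny - py) * (ny - py) +
                       (n1 - v1) * (n1 - v1) + (n2 - v2) * (n2 - v2) +
                       (n3 - v3) * (n3 - v3);
        px = nx; py = ny; v1 = n1; v2 = n2; v3 = n3;
        if (shift < tol) break;
      }
      o1(y, x) = v1; o2(y, x) = v2; o3(y, x) = v3;
    }
  }
  return List::create(o1, o2, o3);
}
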