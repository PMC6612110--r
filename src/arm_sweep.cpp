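#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rotating three-rectangle Haar-like response around a point.
//
// gray: H x W intensity matrix on [0,1], row = image y (down), col = image x.
// cx, cy: centre of rotation in 0-based pixel coordinates.
// rect_width: full width of the centre rectangle in pixels.
// step_deg: angular step (360 must be divisible by it).
//
// Angle convention: 0 deg points image-left (west), angles increase clockwise
// on screen, so 90 = up, 180 = right, 270 = down.  For each angle the centre
// rectangle runs from the centre to the image border along the ray; the two
// side rectangles of equal width are adjacent on either side.  The response is
// the mean of (CV_side - CV_centre) over the two sides, where CV is the
// population coefficient of variation of intensities; a rectangle with fewer
// than 4 pixels or near-zero mean contributes CV = 0.
// [[Rcpp::export(name = ".arm_sweep_cpp")]]
NumericVector arm_sweep_cpp(NumericMatrix gray, double cx, double cy,
                            double rect_width, int step_deg) {
  const int H = gray.nrow(), W = gray.ncol();
  const int n_ang = 360 / step_deg;
  const double hw = rect_width / 2.0;   // centre rect half-width
  const double ow = 3.0 * hw;           // outer edge of side rects
  const double eps = 1e-6;
  NumericVector out(n_ang);

  for (int a = 0; a < n_ang; ++a) {
    const double th = (a * step_deg) * M_PI / 180.0;
    const double ux = -std::cos(th), uy = -std::sin(th); // along-ray
    const double px = -uy, py = ux;                      // perpendicular
    double s0 = 0, q0 = 0, s1 = 0, q1 = 0, s2 = 0, q2 = 0;
    long   n0 = 0, n1 = 0, n2 = 0;
    for (int x = 0; x < W; ++x) {
      const double dx = x - cx;
      for (int y = 0; y < H; ++y) {
        const double dy = y - cy;
        const double t = dx * ux + dy * uy;
        if (t < 0) continue;
        const double s = dx * px + dy * py;
        if (s < -ow || s > ow) continue;
        const double v = gray(y, x);
        if (s >= -hw && s <= hw)      { s0 += v; q0 += v * v; ++n0; }
        else if (s > hw)              { s1 += v; q1 += v * v; ++n1; }
        else                          { s2 += v; q2 += v * v; ++n2; }
      }
    }
    auto cv = [eps](double s, double q, long n) -> double {
      if (n < 4) return 0.0;
      const double m = s / n;
      if (m < eps) return 0.0;
      double var = q / n - m * m;
      if (var < 0) var = 0;
      return std::sqrt(var) / m;
    };
    const double cvc = cv(s0, q0, n0);
    out[a] = ((cv(s1, q1, n1) - cvc) + (cv(s2, q2, n2) - cvc)) / 2.0;
  }
  return out;
}
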