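#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dense pyramidal Lucas-Kanade optical flow.
//
// Coarse-to-fine estimation: at each pyramid level the second image is warped
// by the current flow, the residual is solved per pixel from the locally
// (Gaussian-window) averaged normal equations, and the increment is added.
// Regularized with lambda on the diagonal so textureless pixels return ~0.
//
// Images are stored column-major (matching R) in flat buffers.

namespace {

struct Img {
  int H = 0, W = 0;
  std::vector<double> v;
  Img() = default;
  Img(int h, int w) : H(h), W(w), v((size_t)h * w, 0.0) {}
  double *data() { return v.data(); }
  const double *data() const { return v.data(); }
  double &at(int i, int j) { return v[(size_t)j * H + i]; }
  double at(int i, int j) const { return v[(size_t)j * H + i]; }
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// bilinear sample with border clamp
inline double sample(const Img &m, double y, double x) {
  x = clampd(x, 0.0, m.W - 1.0);
  y = clampd(y, 0.0, m.H - 1.0);
  const int x0 = (int)x, y0 = (int)y;
  const int x1 = x0 + 1 < m.W ? x0 + 1 : x0;
  const int y1 = y0 + 1 < m.H ? y0 + 1 : y0;
  const double fx = x - x0, fy = y - y0;
  const double *d = m.data();
  const double a = d[(size_t)x0 * m.H + y0], b = d[(size_t)x1 * m.H + y0];
  const double c = d[(size_t)x0 * m.H + y1], e = d[(size_t)x1 * m.H + y1];
  return (1 - fy) * ((1 - fx) * a + fx * b) + fy * ((1 - fx) * c + fx * e);
}

// separable Gaussian blur with reflected borders
void blur_into(const Img &src, Img &tmp, Img &dst, double sigma) {
  const int H = src.H, W = src.W;
  const int r = (int)std::ceil(2.5 * sigma);
  std::vector<double> k(2 * r + 1);
  double ks = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += k[i + r];
  }
  for (double &x : k) x /= ks;
  // vertical pass (within a column, contiguous)
  for (int j = 0; j < W; ++j) {
    const double *s = src.data() + (size_t)j * H;
    double *t = tmp.data() + (size_t)j * H;
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii;
        if (ii >= H) ii = 2 * H - 2 - ii;
        acc += k[d + r] * s[ii];
      }
      t[i] = acc;
    }
  }
  // horizontal pass
  for (int j = 0; j < W; ++j) {
    double *o = dst.data() + (size_t)j * H;
    for (int i = 0; i < H; ++i) o[i] = 0.0;
    for (int d = -r; d <= r; ++d) {
      int jj = j + d;
      if (jj < 0) jj = -jj;
      if (jj >= W) jj = 2 * W - 2 - jj;
      const double *t = tmp.data() + (size_t)jj * H;
      const double kv = k[d + r];
      for (int i = 0; i < H; ++i) o[i] += kv * t[i];
    }
  }
}

Img blur(const Img &src, double sigma) {
  Img tmp(src.H, src.W), dst(src.H, src.W);
  blur_into(src, tmp, dst, sigma);
  return dst;
}

Img downsample2(const Img &m) {
  Img out(m.H / 2, m.W / 2);
  for (int j = 0; j < out.W; ++j)
    for (int i = 0; i < out.H; ++i)
      out.at(i, j) = 0.25 * (m.at(2 * i, 2 * j) + m.at(2 * i + 1, 2 * j) +
                             m.at(2 * i, 2 * j + 1) + m.at(2 * i + 1, 2 * j + 1));
  return out;
}

Img resize_scale(const Img &m, int H, int W, double gain) {
  Img out(H, W);
  const double sy = (double)m.H / H, sx = (double)m.W / W;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out.at(i, j) = gain * sample(m, (i + 0.5) * sy - 0.5, (j + 0.5) * sx - 0.5);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".lk_flow_cpp")]]
List lk_flow_cpp(NumericMatrix im1, NumericMatrix im2, int levels = 3,
                 int iters = 3, double sigma = 2.0, double lambda = 1e-4) {
  std::vector<Img> p1, p2;
  {
    Img a(im1.nrow(), im1.ncol()), b(im2.nrow(), im2.ncol());
    std::copy(im1.begin(), im1.end(), a.v.begin());
    std::copy(im2.begin(), im2.end(), b.v.begin());
    p1.push_back(std::move(a));
    p2.push_back(std::move(b));
  }
  for (int l = 1; l < levels; ++l) {
    if (p1.back().H < 24 || p1.back().W < 24) break;
    p1.push_back(downsample2(blur(p1.back(), 1.0)));
    p2.push_back(downsample2(blur(p2.back(), 1.0)));
  }
  const int L = (int)p1.size();
  Img u(p1[L - 1].H, p1[L - 1].W), v(p1[L - 1].H, p1[L - 1].W);

  for (int l = L - 1; l >= 0; --l) {
    const Img &I1 = p1[l], &I2 = p2[l];
    const int H = I1.H, W = I1.W;
    if (u.H != H || u.W != W) {
      Img u2 = resize_scale(u, H, W, (double)W / u.W);
      Img v2 = resize_scale(v, H, W, (double)H / v.H);
      u = std::move(u2);
      v = std::move(v2);
    }
    Img Ixx(H, W), Ixy(H, W), Iyy(H, W), Ixt(H, W), Iyt(H, W), tmp(H, W);
    for (int it = 0; it < iters; ++it) {
      for (int j = 0; j < W; ++j) {
        const int jp = j + 1 < W ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        for (int i = 0; i < H; ++i) {
          const int ip = i + 1 < H ? i + 1 : i, im = i > 0 ? i - 1 : i;
          const double uu = u.at(i, j), vv = v.at(i, j);
          const double w0 = sample(I2, i + vv, j + uu);
          const double wxp = sample(I2, i + vv, j + 1 + uu);
          const double wxm = sample(I2, i + vv, j - 1 + uu);
          const double wyp = sample(I2, i + 1 + vv, j + uu);
          const double wym = sample(I2, i - 1 + vv, j + uu);
          const double ix = 0.25 * (I1.at(i, jp) - I1.at(i, jm)) + 0.25 * (wxp - wxm);
          const double iy = 0.25 * (I1.at(ip, j) - I1.at(im, j)) + 0.25 * (wyp - wym);
          const double itv = w0 - I1.at(i, j);
          Ixx.at(i, j) = ix * ix;
          Ixy.at(i, j) = ix * iy;
          Iyy.at(i, j) = iy * iy;
          Ixt.at(i, j) = ix * itv;
          Iyt.at(i, j) = iy * itv;
        }
      }
      blur_into(Ixx, tmp, Ixx, sigma);
      blur_into(Ixy, tmp, Ixy, sigma);
      blur_into(Iyy, tmp, Iyy, sigma);
      blur_into(Ixt, tmp, Ixt, sigma);
      blur_into(Iyt, tmp, Iyt, sigma);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double a = Ixx.at(i, j) + lambda, b = Ixy.at(i, j);
          const double c = Iyy.at(i, j) + lambda;
          const double det = a * c - b * b;
          const double du = -(c * Ixt.at(i, j) - b * Iyt.at(i, j)) / det;
          const double dv = -(-b * Ixt.at(i, j) + a * Iyt.at(i, j)) / det;
          u.at(i, j) += clampd(du, -4.0, 4.0);
          v.at(i, j) += clampd(dv, -4.0, 4.0);
        }
    }
  }
  NumericMatrix dx(im1.nrow(), im1.ncol()), dy(im1.nrow(), im1.ncol());
  std::copy(u.v.begin(), u.v.end(), dx.begin());
  std::copy(v.v.begin(), v.v.end(), dy.begin());
  return List::create(_["dx"] = dx, _["dy"] = dy);
}
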