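#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete Radon transform by direct line summation.
//
// The image is sampled along rays parameterised as
//   x(tau) = cx + tau*sin(theta) + r*cos(theta)
//   t(tau) = cy + tau*cos(theta) - r*sin(theta)
// with theta measured in degrees from the time (row) axis, so a streak that
// advances sin(theta) columns per cos(theta) rows integrates coherently at
// projection angle theta.  tau steps in whole pixels; the ray offset r steps
// in units of r_step pixels (the variance search oversamples offsets at half
// a pixel to keep the peak of the variance profile from aliasing to the bin
// grid).  Samples are read with bilinear interpolation, zero outside the
// raster.  `weight` records the summed in-image bilinear weight of each ray
// (its effective length through the raster): the R side uses it to drop rays
// that barely graze the image and to normalize ray sums to ray means.
// [[Rcpp::export]]
List radon_sinogram_cpp(const NumericMatrix& px, const NumericVector& theta_deg,
                        const double r_step) {
  const int h = px.nrow(), w = px.ncol();
  const double cx = (w + 1) / 2.0, cy = (h + 1) / 2.0;
  const double R = std::ceil(std::sqrt((double)w * w + (double)h * h) / 2.0) + 1.0;
  const int nr = 2 * (int)std::ceil(R / r_step) + 1;
  const int nt = 2 * (int)R + 1;
  const int rhalf = (nr - 1) / 2, thalf = (nt - 1) / 2;
  const int na = theta_deg.size();
  NumericMatrix proj(nr, na);
  NumericMatrix weight(nr, na);

  for (int a = 0; a < na; ++a) {
    const double th = theta_deg[a] * M_PI / 180.0;
    const double st = std::sin(th), ct = std::cos(th);
    for (int ri = 0; ri < nr; ++ri) {
      const double r = (ri - rhalf) * r_step;
      const double bx = cx + r * ct;
      const double by = cy - r * st;
      double acc = 0.0, wacc = 0.0;
      for (int ti = 0; ti < nt; ++ti) {
        const double tau = (double)(ti - thalf);
        const double x = bx + tau * st;
        const double y = by + tau * ct;
        if (x < 0.0 || x > (double)w + 1.0 || y < 0.0 || y > (double)h + 1.0)
          continue;
        const int x0 = (int)std::floor(x);
        const int y0 = (int)std::floor(y);
        const double fx = x - x0, fy = y - y0;
        double v = 0.0, wt = 0.0;
        if (y0 >= 1 && y0 <= h) {
          if (x0 >= 1 && x0 <= w) {
            v += (1.0 - fx) * (1.0 - fy) * px(y0 - 1, x0 - 1);
            wt += (1.0 - fx) * (1.0 - fy);
          }
          if (x0 + 1 >= 1 && x0 + 1 <= w) {
            v += fx * (1.0 - fy) * px(y0 - 1, x0);
            wt += fx * (1.0 - fy);
          }
        }
        if (y0 + 1 >= 1 && y0 + 1 <= h) {
          if (x0 >= 1 && x0 <= w) {
            v += (1.0 - fx) * fy * px(y0, x0 - 1);
            wt += (1.0 - fx) * fy;
          }
          if (x0 + 1 >= 1 && x0 + 1 <= w) {
            v += fx * fy * px(y0, x0);
            wt += fx * fy;
          }
        }
        acc += v;
        wacc += wt;
      }
      proj(ri, a) = acc;
      weight(ri, a) = wacc;
    }
  }
  return List::create(_["proj"] = proj, _["weight"] = weight,
                      _["r_half"] = rhalf, _["r_step"] = r_step);
}
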