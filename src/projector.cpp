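#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Siddon-style exact chord traversal of a 2-D pixel grid.
//
// Grid: nx * ny pixels of size px (mm), lower-left corner at (xmin, ymin),
// column-major storage (index = ix + iy * nx), matching an R matrix with
// the x index running over rows.
//
// For each ray (x0,y0) -> (x1,y1) the visitor receives (pixel, length_mm)
// for every pixel the chord crosses. Forward projection and backprojection
// share this traversal, so the pair is an exact adjoint up to floating
// point rounding.

template <typename Visitor>
static inline void traverse_ray(double x0, double y0, double x1, double y1,
                                int nx, int ny, double px,
                                double xmin, double ymin,
                                Visitor visit) {
  const double dx = x1 - x0, dy = y1 - y0;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0.0) return;

  const double xmax = xmin + nx * px, ymax = ymin + ny * px;
  const double inf = std::numeric_limits<double>::infinity();

  // slab clipping in ray parameter t in [0,1]
  double tmin = 0.0, tmax = 1.0;
  if (dx != 0.0) {
    double t1 = (xmin - x0) / dx, t2 = (xmax - x0) / dx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  } else if (x0 <= xmin || x0 >= xmax) {
    return;
  }
  if (dy != 0.0) {
    double t1 = (ymin - y0) / dy, t2 = (ymax - y0) / dy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  } else if (y0 <= ymin || y0 >= ymax) {
    return;
  }
  if (tmin >= tmax) return;

  // entry pixel (nudge inward to dodge exact-boundary ambiguity)
  double t = tmin;
  const double eps = 1e-12;
  double xe = x0 + (t + eps * (tmax - tmin)) * dx;
  double ye = y0 + (t + eps * (tmax - tmin)) * dy;
  int ix = (int)std::floor((xe - xmin) / px);
  int iy = (int)std::floor((ye - ymin) / px);
  if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
  if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;

  const int sx = (dx > 0.0) ? 1 : -1;
  const int sy = (dy > 0.0) ? 1 : -1;
  const double dtx = (dx != 0.0) ? px / std::fabs(dx) : inf;
  const double dty = (dy != 0.0) ? px / std::fabs(dy) : inf;

  // parameter of next x / y grid-line crossing
  double txn, tyn;
  if (dx != 0.0) {
    double xb = xmin + (ix + (sx > 0 ? 1 : 0)) * px;
    txn = (xb - x0) / dx;
  } else txn = inf;
  if (dy != 0.0) {
    double yb = ymin + (iy + (sy > 0 ? 1 : 0)) * px;
    tyn = (yb - y0) / dy;
  } else tyn = inf;

  while (t < tmax) {
    double tn = std::min(std::min(txn, tyn), tmax);
    double w = (tn - t) * L;
    if (w > 0.0 && ix >= 0 && ix < nx && iy >= 0 && iy < ny)
      visit(ix + iy * nx, w);
    t = tn;
    if (t >= tmax) break;
    if (txn <= tyn) { ix += sx; txn += dtx; }
    else            { iy += sy; tyn += dty; }
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
  }
}

// [[Rcpp::export(name = ".siddon_forward")]]
NumericVector siddon_forward(NumericVector image, int nx, int ny,
                             double px, double xmin, double ymin,
                             NumericVector x0, NumericVector y0,
                             NumericVector x1, NumericVector y1) {
  const int n = x0.size();
  NumericVector out(n);
  const double* img = REAL(image);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    traverse_ray(x0[i], y0[i], x1[i], y1[i], nx, ny, px, xmin, ymin,
                 [&](int pix, double w) { acc += img[pix] * w; });
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export(name = ".siddon_back")]]
NumericVector siddon_back(NumericVector values, int nx, int ny,
                          double px, double xmin, double ymin,
                          NumericVector x0, NumericVector y0,
                          NumericVector x1, NumericVector y1) {
  const int n = x0.size();
  NumericVector img(nx * ny);
  double* out = REAL(img);
  for (int i = 0; i < n; ++i) {
    const double v = values[i];
    if (v == 0.0) continue;
    traverse_ray(x0[i], y0[i], x1[i], y1[i], nx, ny, px, xmin, ymin,
                 [&](int pix, double w) { out[pix] += v * w; });
  }
  return img;
}

// chord length of each ray through the grid (forward projection of ones)
// [[Rcpp::export(name = ".siddon_chord")]]
NumericVector siddon_chord(int nx, int ny, double px,
                           double xmin, double ymin,
                           NumericVector x0, NumericVector y0,
                           NumericVector x1, NumericVector y1) {
  const int n = x0.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    traverse_ray(x0[i], y0[i], x1[i], y1[i], nx, ny, px, xmin, ymin,
                 [&](int, double w) { acc += w; });
    out[i] = acc;
  }
  return out;
}
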