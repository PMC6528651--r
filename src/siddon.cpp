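#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Incremental Siddon traversal of one parallel-beam ray through a 2-D pixel
// grid. The ray for angle phi and signed radial offset s is
//   p(t) = (s cos(phi) - t sin(phi), s sin(phi) + t cos(phi)),
// i.e. s is measured along the detector axis (cos, sin) and t runs along the
// line of response. Emits (pixel index, intersection length in mm) pairs.
// Both projection directions use this single traversal, so the
// backprojector is the exact adjoint of the projector by construction.

struct RayHit { int idx; double len; };

static int trace_ray(double s, double cphi, double sphi,
                     int nx, int ny, double dx, double dy,
                     double xmin, double ymin,
                     RayHit *hits, int maxHits) {
  const double px0 = s * cphi, py0 = s * sphi;
  const double dirx = -sphi, diry = cphi;
  const double xmax = xmin + nx * dx, ymax = ymin + ny * dy;
  const double eps = 1e-12;

  double tmin = -1e30, tmax = 1e30;
  if (std::fabs(dirx) > eps) {
    double t1 = (xmin - px0) / dirx, t2 = (xmax - px0) / dirx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  } else if (px0 <= xmin || px0 >= xmax) {
    return 0;
  }
  if (std::fabs(diry) > eps) {
    double t1 = (ymin - py0) / diry, t2 = (ymax - py0) / diry;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  } else if (py0 <= ymin || py0 >= ymax) {
    return 0;
  }
  if (tmax - tmin <= eps) return 0;

  double t = tmin;
  double x = px0 + t * dirx, y = py0 + t * diry;

  int ix, iy, sx = 0, sy = 0;
  double txNext = 1e30, tyNext = 1e30, dtx = 1e30, dty = 1e30;

  ix = (int)std::floor((x - xmin) / dx);
  if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
  iy = (int)std::floor((y - ymin) / dy);
  if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;

  if (std::fabs(dirx) > eps) {
    sx = dirx > 0 ? 1 : -1;
    dtx = dx / std::fabs(dirx);
    double xb = xmin + (dirx > 0 ? (ix + 1) : ix) * dx;
    txNext = t + (xb - x) / dirx;
    if (txNext < t) txNext = t;
  }
  if (std::fabs(diry) > eps) {
    sy = diry > 0 ? 1 : -1;
    dty = dy / std::fabs(diry);
    double yb = ymin + (diry > 0 ? (iy + 1) : iy) * dy;
    tyNext = t + (yb - y) / diry;
    if (tyNext < t) tyNext = t;
  }

  int n = 0;
  while (t < tmax - eps) {
    double tn = std::min(std::min(txNext, tyNext), tmax);
    double len = tn - t;
    if (len > eps && ix >= 0 && ix < nx && iy >= 0 && iy < ny) {
      if (n >= maxHits) break;  // cannot happen for maxHits >= nx+ny+2
      hits[n].idx = ix + nx * iy;
      hits[n].len = len;
      ++n;
    }
    t = tn;
    if (txNext - tn < eps) { ix += sx; txNext += dtx; }
    if (tyNext - tn < eps) { iy += sy; tyNext += dty; }
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
  }
  return n;
}

// data: image (nx*ny*nPlanes) when forward, sinogram (nr*na*nPlanes) when not.
// Returns sinogram values when forward, image values when not. Planes are
// independent axial slices sharing the in-plane geometry.
// [[Rcpp::export]]
NumericVector cpp_siddon(NumericVector data, IntegerVector imgDim,
                         NumericVector voxSize, NumericVector origin,
                         NumericVector radial, NumericVector angles,
                         int nPlanes, bool forward) {
  const int nx = imgDim[0], ny = imgDim[1];
  const double dx = voxSize[0], dy = voxSize[1];
  const double xmin = origin[0] - dx / 2.0, ymin = origin[1] - dy / 2.0;
  const int nr = radial.size(), na = angles.size();
  const int nvox = nx * ny, nbin = nr * na;

  NumericVector out(forward ? (R_xlen_t)nbin * nPlanes
                            : (R_xlen_t)nvox * nPlanes);
  std::vector<RayHit> hits(nx + ny + 4);

  for (int a = 0; a < na; ++a) {
    const double cphi = std::cos(angles[a]), sphi = std::sin(angles[a]);
    for (int r = 0; r < nr; ++r) {
      int nh = trace_ray(radial[r], cphi, sphi, nx, ny, dx, dy, xmin, ymin,
                         hits.data(), (int)hits.size());
      if (nh == 0) continue;
      for (int p = 0; p < nPlanes; ++p) {
        const R_xlen_t imgOff = (R_xlen_t)nvox * p;
        const R_xlen_t bin = r + (R_xlen_t)nr * a + (R_xlen_t)nbin * p;
        if (forward) {
          double acc = 0.0;
          for (int h = 0; h < nh; ++h)
            acc += hits[h].len * data[imgOff + hits[h].idx];
          out[bin] = acc;
        } else {
          const double v = data[bin];
          if (v != 0.0)
            for (int h = 0; h < nh; ++h)
              out[imgOff + hits[h].idx] += hits[h].len * v;
        }
      }
    }
  }
  return out;
}
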