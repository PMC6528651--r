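#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Helpers shared by the Bowsher selection and the smoothed Lange penalty.
// Voxels are addressed in R's column-major order; offsets are rows of an
// integer matrix (noffset x ndim). Out-of-bounds neighbours are skipped and
// the proximity weights are renormalized over the in-bounds (truncated)
// neighbourhood so that their per-voxel sum is exactly 1.

static inline bool neighbour_index(int i, int j, int k,
                                   int nx, int ny, int nz,
                                   int oi, int oj, int ok, R_xlen_t &out) {
  const int ni = i + oi, nj = j + oj, nk = k + ok;
  if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz)
    return false;
  out = ni + (R_xlen_t)nx * (nj + (R_xlen_t)ny * nk);
  return true;
}

// Modified (asymmetric) Bowsher selection: for every voxel, the B neighbours
// most similar in the anatomical image get weight 1, the rest 0. Ties are
// broken by smaller physical distance, then by offset (row) order, which is
// lexicographic when offsets are generated lexicographically. At boundary
// voxels all min(B, available) in-bounds neighbours compete.
// [[Rcpp::export]]
IntegerMatrix cpp_bowsher(NumericVector anat, IntegerVector dim,
                          IntegerMatrix offsets, NumericVector dists, int B) {
  const int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const int ndim = offsets.ncol(), K = offsets.nrow();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerMatrix w(nvox, K);

  struct Cand { double diff; double dist; int o; };
  std::vector<Cand> cand(K);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        int nc = 0;
        for (int o = 0; o < K; ++o) {
          R_xlen_t u;
          const int ok = ndim > 2 ? offsets(o, 2) : 0;
          if (!neighbour_index(i, j, k, nx, ny, nz,
                               offsets(o, 0), offsets(o, 1), ok, u))
            continue;
          cand[nc].diff = std::fabs(anat[v] - anat[u]);
          cand[nc].dist = dists[o];
          cand[nc].o = o;
          ++nc;
        }
        const int nb = std::min(B, nc);
        if (nb <= 0) continue;
        std::partial_sort(cand.begin(), cand.begin() + nb, cand.begin() + nc,
          [](const Cand &a, const Cand &b) {
            if (a.diff != b.diff) return a.diff < b.diff;
            if (a.dist != b.dist) return a.dist < b.dist;
            return a.o < b.o;
          });
        for (int s = 0; s < nb; ++s) w(v, cand[s].o) = 1;
      }
  return w;
}

// Smoothed Lange penalty: U = sum_j psi(t_j) with
//   t_j = sqrt( sum_k xi_jk w_jk (theta_j - theta_k)^2 ),
//   psi(t) = delta * ( t/delta - log(1 + t/delta) ).
// gradMode 0: the one-sided derivative as used in the one-step-late update,
//   dU/dtheta_j = sum_k xi_jk w_jk (theta_j - theta_k) / (delta + t_j).
// gradMode 1: the full (symmetrized) derivative of U, which additionally
//   propagates -xi_jk w_jk (theta_j - theta_k)/(delta + t_j) to neighbour k;
//   this is the exact gradient of the energy and is used for numeric
//   gradient checks.
// [[Rcpp::export]]
List cpp_smoothed_lange(NumericVector theta, IntegerVector dim,
                        IntegerMatrix offsets, NumericVector xiRaw,
                        IntegerMatrix w, double delta, int gradMode) {
  const int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const int ndim = offsets.ncol(), K = offsets.nrow();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector grad(nvox);
  double energy = 0.0;

  std::vector<R_xlen_t> nidx(K);
  std::vector<bool> valid(K);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double xiSum = 0.0;
        for (int o = 0; o < K; ++o) {
          const int ok = ndim > 2 ? offsets(o, 2) : 0;
          valid[o] = neighbour_index(i, j, k, nx, ny, nz,
                                     offsets(o, 0), offsets(o, 1), ok, nidx[o]);
          if (valid[o]) xiSum += xiRaw[o];
        }
        if (xiSum <= 0.0) continue;
        double num = 0.0, ss = 0.0;
        for (int o = 0; o < K; ++o) {
          if (!valid[o] || w(v, o) == 0) continue;
          const double xi = xiRaw[o] / xiSum;
          const double d = theta[v] - theta[nidx[o]];
          num += xi * d;
          ss += xi * d * d;
        }
        const double t = std::sqrt(ss);
        energy += delta * (t / delta - std::log1p(t / delta));
        const double den = delta + t;
        grad[v] += num / den;
        if (gradMode == 1) {
          for (int o = 0; o < K; ++o) {
            if (!valid[o] || w(v, o) == 0) continue;
            const double xi = xiRaw[o] / xiSum;
            grad[nidx[o]] -= xi * (theta[v] - theta[nidx[o]]) / den;
          }
        }
      }
  return List::create(_["energy"] = energy, _["grad"] = grad);
}
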