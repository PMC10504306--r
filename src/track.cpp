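// FACT deterministic streamline integration.
//
// Direction at a point is the principal eigenvector of the voxel containing
// the point (nearest-voxel lookup, no interpolation), sign-aligned with the
// previous step. A half-track terminates when the next point would leave the
// grid, when the containing voxel's FA falls below the threshold (the
// sub-threshold point is kept as the terminal point), when the turning angle
// between successive steps exceeds the angle threshold, or after max_steps.
// The two half-tracks launched along +e1 and -e1 of the seed voxel are
// concatenated. Coordinates are world mm; voxel ownership is half-open with
// centers at integer indices.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Grid {
  const double *inv;  // 3x4 world-to-voxel (column-major, 3 rows)
  int nx, ny, nz;
  bool voxel_of(const double *p, int *v) const {
    for (int r = 0; r < 3; ++r) {
      double c = inv[r] * p[0] + inv[3 + r] * p[1] + inv[6 + r] * p[2] + inv[9 + r];
      v[r] = (int)std::floor(c + 0.5);
    }
    return v[0] >= 0 && v[0] < nx && v[1] >= 0 && v[1] < ny && v[2] >= 0 && v[2] < nz;
  }
  int lin(const int *v) const { return v[0] + nx * (v[1] + ny * v[2]); }
};

// One half-track; appends world points (excluding the seed) to out.
void half_track(const double *seed, const double *d0, const Grid &g,
                const double *e1, const double *fa, double fa_thr,
                double cos_thr, double step, int max_steps,
                std::vector<double> &out) {
  double p[3] = {seed[0], seed[1], seed[2]};
  double prev[3] = {d0[0], d0[1], d0[2]};
  int v[3];
  for (int s = 0; s < max_steps; ++s) {
    if (!g.voxel_of(p, v)) break;  // safety; entry points are checked below
    const int li = g.lin(v);
    double d[3] = {e1[li], e1[li + g.nx * g.ny * g.nz],
                   e1[li + 2 * g.nx * g.ny * g.nz]};
    double dot = d[0] * prev[0] + d[1] * prev[1] + d[2] * prev[2];
    if (dot < 0) { d[0] = -d[0]; d[1] = -d[1]; d[2] = -d[2]; dot = -dot; }
    if (s > 0 && dot < cos_thr) break;  // turning angle exceeded
    double pn[3] = {p[0] + step * d[0], p[1] + step * d[1], p[2] + step * d[2]};
    int vn[3];
    if (!g.voxel_of(pn, vn)) break;  // would exit the grid
    out.push_back(pn[0]); out.push_back(pn[1]); out.push_back(pn[2]);
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
    prev[0] = d[0]; prev[1] = d[1]; prev[2] = d[2];
    if (fa[g.lin(vn)] < fa_thr) break;  // terminal sub-threshold point kept
  }
}

}  // namespace

// seeds: n x 3 world mm; e1: flat array length nx*ny*nz*3 (component-major
// blocks, i.e. an R array c(nx, ny, nz, 3)); fa: flat nx*ny*nz;
// inv_affine: 3 x 4. Returns a list of numeric matrices (k x 3), one per
// seed; a 0 x 3 matrix marks a seed whose voxel FA is sub-threshold.
// [[Rcpp::export]]
List track_streamlines_cpp(const NumericMatrix &seeds, const NumericVector &e1,
                           const NumericVector &fa, const IntegerVector &dims,
                           const NumericMatrix &inv_affine, double fa_thresh,
                           double angle_thresh_deg, double step,
                           int max_steps) {
  Grid g;
  g.inv = REAL(inv_affine);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  const double cos_thr = std::cos(angle_thresh_deg * M_PI / 180.0);
  const double *e1p = REAL(e1);
  const double *fap = REAL(fa);
  const int n_vox = g.nx * g.ny * g.nz;
  const int n = seeds.nrow();
  List out(n);
  std::vector<double> fwd, bwd;
  for (int i = 0; i < n; ++i) {
    double seed[3] = {seeds(i, 0), seeds(i, 1), seeds(i, 2)};
    int v[3];
    if (!g.voxel_of(seed, v)) {
      out[i] = NumericMatrix(0, 3);
      continue;
    }
    const int li = g.lin(v);
    if (fap[li] < fa_thresh) {
      out[i] = NumericMatrix(0, 3);
      continue;
    }
    double d0[3] = {e1p[li], e1p[li + n_vox], e1p[li + 2 * n_vox]};
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    fwd.clear(); bwd.clear();
    half_track(seed, d0, g, e1p, fap, fa_thresh, cos_thr, step, max_steps, fwd);
    half_track(seed, d0n, g, e1p, fap, fa_thresh, cos_thr, step, max_steps, bwd);
    const int nb = (int)bwd.size() / 3, nf = (int)fwd.size() / 3;
    NumericMatrix pts(nb + 1 + nf, 3);
    for (int j = 0; j < nb; ++j) {          // backward half, reversed
      const int src = nb - 1 - j;
      pts(j, 0) = bwd[3 * src]; pts(j, 1) = bwd[3 * src + 1]; pts(j, 2) = bwd[3 * src + 2];
    }
    pts(nb, 0) = seed[0]; pts(nb, 1) = seed[1]; pts(nb, 2) = seed[2];
    for (int j = 0; j < nf; ++j) {
      pts(nb + 1 + j, 0) = fwd[3 * j]; pts(nb + 1 + j, 1) = fwd[3 * j + 1];
      pts(nb + 1 + j, 2) = fwd[3 * j + 2];
    }
    out[i] = pts;
  }
  return out;
}
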