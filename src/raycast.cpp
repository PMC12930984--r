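#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Orthographic first-hit ray casting over a masked voxel grid.
//
// Rays run parallel to the view direction; each pixel takes the intensity
// of the first mask-true voxel its ray meets (nearest-voxel lookup at
// sub-voxel marching steps), 0 if none. All vectors are given in voxel
// coordinate space, pre-scaled per unit of world length, so anisotropic
// voxels are handled by the caller.
//
// dims: grid dimensions; vol: intensities (column-major); mask: 0/1.
// dirVox/uVox/vVox: ray direction and image-plane right/up vectors.
// centerVox: volume center. halfExtent: half image width in world units.
// stepWorld: marching step in world units. tMax: ray length budget.
// [[Rcpp::export]]
NumericMatrix raycast_view_cpp(NumericVector vol, IntegerVector mask,
                               IntegerVector dims, NumericVector dirVox,
                               NumericVector uVox, NumericVector vVox,
                               NumericVector centerVox, double halfExtent,
                               int res, double stepWorld, double tMax) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(res, res);
  const double px = 2.0 * halfExtent / res;
  const int nsteps = (int)std::ceil(tMax / stepWorld);
  const double dx = dirVox[0] * stepWorld;
  const double dy = dirVox[1] * stepWorld;
  const double dz = dirVox[2] * stepWorld;

  for (int r = 0; r < res; ++r) {
    const double b = halfExtent - (r + 0.5) * px;
    for (int c = 0; c < res; ++c) {
      const double a = -halfExtent + (c + 0.5) * px;
      // start half a ray-length behind the volume center
      double x = centerVox[0] + a * uVox[0] + b * vVox[0] - 0.5 * tMax * dirVox[0];
      double y = centerVox[1] + a * uVox[1] + b * vVox[1] - 0.5 * tMax * dirVox[1];
      double z = centerVox[2] + a * uVox[2] + b * vVox[2] - 0.5 * tMax * dirVox[2];
      double val = 0.0;
      for (int s = 0; s <= nsteps; ++s, x += dx, y += dy, z += dz) {
        const int i = (int)std::floor(x + 0.5);
        if (i < 0 || i >= nx) continue;
        const int j = (int)std::floor(y + 0.5);
        if (j < 0 || j >= ny) continue;
        const int k = (int)std::floor(z + 0.5);
        if (k < 0 || k >= nz) continue;
        const R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (mask[idx]) { val = vol[idx]; break; }
      }
      out(r, c) = val;
    }
  }
  return out;
}
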