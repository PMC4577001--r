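#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a grid defined on voxel centers with zero padding.
// (x,y,z) are continuous 0-based voxel-center coordinates: voxel (i,j,k)
// holds the value at (i,j,k); beyond the outermost centers the field
// interpolates continuously to 0 (air), reaching it one voxel out.
static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x <= -1 || y <= -1 || z <= -1 || x >= nx || y >= ny || z >= nz)
    return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const size_t sxy = (size_t)nx * ny;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    int k = k0 + dk;
    if (k < 0 || k > nz - 1) continue;
    double wz = dk ? fz : 1 - fz;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j > ny - 1) continue;
      double wy = dj ? fy : 1 - fy;
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di;
        if (i < 0 || i > nx - 1) continue;
        double wx = di ? fx : 1 - fx;
        acc += wx * wy * wz * v[(size_t)i + (size_t)nx * j + sxy * k];
      }
    }
  }
  return acc;
}

// Divergent-beam DRR: line integral of attenuation along source->pixel rays,
// restricted to the body-mask bounding box, midpoint quadrature with a
// uniform parametric step and trilinear interpolation.
//
// mu        : attenuation grid (mm^-1), column-major dims[0] x dims[1] x dims[2]
// spacing   : voxel size (mm); origin: grid-corner world position (mm), so the
//             center of voxel (i,j,k) sits at origin + (i+0.5)*spacing etc.
// blo, bhi  : world-mm bounds (volume frame) of the integration box
// tinv      : 4x4 mapping room coordinates -> volume world coordinates
//             (inverse of the rigid pose placing the volume in the room)
// src       : room-frame source position (mm)
// det0,uax,vax : detector corner and unit in-plane axes (room frame, mm)
// roi       : half-open pixel rectangle (u0, v0, u1, v1), 0-based
// step      : quadrature step along the ray (mm)
// [[Rcpp::export]]
NumericMatrix cast_drr_cpp(NumericVector mu, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericVector blo, NumericVector bhi,
                           NumericMatrix tinv,
                           NumericVector src, NumericVector det0,
                           NumericVector uax, NumericVector vax,
                           double pitch, int nu, int nv,
                           IntegerVector roi, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(mu);
  NumericMatrix out(nu, nv);

  // source in volume world coordinates
  double s[3], M[3][4];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) M[r][c] = tinv(r, c);
  for (int r = 0; r < 3; ++r)
    s[r] = M[r][0]*src[0] + M[r][1]*src[1] + M[r][2]*src[2] + M[r][3];

  const int u0 = roi[0], v0 = roi[1], u1 = roi[2], v1 = roi[3];
  for (int vv = v0; vv < v1; ++vv) {
    for (int uu = u0; uu < u1; ++uu) {
      // pixel center in room frame, then ray direction in volume frame
      double p[3], d[3];
      for (int r = 0; r < 3; ++r)
        p[r] = det0[r] + (uu + 0.5) * pitch * uax[r] + (vv + 0.5) * pitch * vax[r];
      double dr[3] = { p[0]-src[0], p[1]-src[1], p[2]-src[2] };
      for (int r = 0; r < 3; ++r)
        d[r] = M[r][0]*dr[0] + M[r][1]*dr[1] + M[r][2]*dr[2];
      double dlen = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      if (dlen <= 0) continue;
      for (int r = 0; r < 3; ++r) d[r] /= dlen;

      // slab intersection with the integration box, t in mm from source
      double t0 = 0.0, t1 = dlen, acc = 0.0;
      bool miss = false;
      for (int r = 0; r < 3; ++r) {
        if (std::fabs(d[r]) < 1e-12) {
          if (s[r] < blo[r] || s[r] > bhi[r]) { miss = true; break; }
        } else {
          double ta = (blo[r] - s[r]) / d[r];
          double tb = (bhi[r] - s[r]) / d[r];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
        }
      }
      if (miss || t1 <= t0) { out(uu, vv) = 0.0; continue; }

      // composite midpoint rule on a global quadrature grid (intervals
      // [k*h, (k+1)*h] along the ray), clipping the boundary intervals to
      // [t0, t1].  Anchoring the grid globally makes the interior sample
      // positions independent of the bounding box, so skipping air-clamped
      // regions changes nothing.
      double h = step;
      long k0 = (long)std::floor(t0 / h);
      long k1 = (long)std::floor((t1 - 1e-12) / h);
      for (long k = k0; k <= k1; ++k) {
        double a = std::max((double)k * h, t0);
        double b = std::min((double)(k + 1) * h, t1);
        double w = b - a;
        if (w <= 0) continue;
        double t = 0.5 * (a + b);
        double x = (s[0] + t * d[0] - origin[0]) / spacing[0] - 0.5;
        double y = (s[1] + t * d[1] - origin[1]) / spacing[1] - 0.5;
        double z = (s[2] + t * d[2] - origin[2]) / spacing[2] - 0.5;
        acc += w * trilinear(v, nx, ny, nz, x, y, z);
      }
      out(uu, vv) = acc;
    }
  }
  return out;
}

// 6-connected flood labelling helpers for body segmentation -----------------

static void flood(const std::vector<char> &in, std::vector<int> &lab,
                  int nx, int ny, int nz, size_t seed, int id,
                  size_t &size) {
  std::vector<size_t> stack;
  stack.push_back(seed);
  lab[seed] = id;
  size = 0;
  const size_t sxy = (size_t)nx * ny;
  while (!stack.empty()) {
    size_t q = stack.back(); stack.pop_back();
    ++size;
    int k = (int)(q / sxy);
    size_t rem = q - (size_t)k * sxy;
    int j = (int)(rem / nx), i = (int)(rem % nx);
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int m = 0; m < 6; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      size_t qq = (size_t)ii + (size_t)nx * jj + sxy * kk;
      if (in[qq] && lab[qq] == 0) { lab[qq] = id; stack.push_back(qq); }
    }
  }
}

// Largest 6-connected component of (hu >= threshold), with internal cavities
// (background components not reaching the grid border) filled in.
// [[Rcpp::export]]
LogicalVector body_mask_cpp(NumericVector hu, IntegerVector dims,
                            double threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz, sxy = (size_t)nx * ny;
  std::vector<char> fg(n);
  size_t nfg = 0;
  for (size_t q = 0; q < n; ++q) {
    fg[q] = REAL(hu)[q] >= threshold;
    nfg += fg[q];
  }
  if (nfg == 0) stop("empty body: no voxel at or above the threshold");

  std::vector<int> lab(n, 0);
  int id = 0, best = 0;
  size_t best_size = 0;
  for (size_t q = 0; q < n; ++q) {
    if (fg[q] && lab[q] == 0) {
      size_t sz;
      flood(fg, lab, nx, ny, nz, q, ++id, sz);
      if (sz > best_size) { best_size = sz; best = id; }
    }
  }
  std::vector<char> body(n);
  for (size_t q = 0; q < n; ++q) body[q] = (lab[q] == best);

  // background components: mark those touching the border as exterior
  std::vector<char> bg(n);
  for (size_t q = 0; q < n; ++q) bg[q] = !body[q];
  std::fill(lab.begin(), lab.end(), 0);
  id = 0;
  std::vector<char> exterior_id(1, 0);
  for (size_t q = 0; q < n; ++q) {
    if (bg[q] && lab[q] == 0) {
      size_t sz;
      flood(bg, lab, nx, ny, nz, q, ++id, sz);
      exterior_id.push_back(0);
    }
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i == 0 || j == 0 || k == 0 || i == nx-1 || j == ny-1 || k == nz-1) {
          size_t q = (size_t)i + (size_t)nx * j + sxy * k;
          if (lab[q] > 0) exterior_id[lab[q]] = 1;
        }
      }
  LogicalVector out(n);
  for (size_t q = 0; q < n; ++q)
    out[q] = body[q] || (lab[q] > 0 && !exterior_id[lab[q]]);
  return out;
}
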