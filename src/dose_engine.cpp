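#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Divergent-beam dose kernel.
//
// For one plan phase (a list of control points whose beam frames have
// already been moved by the inverse patient transform on the R side),
// accumulates dose into every voxel inside the body mask:
//
//   dose = fluence(projection) * exp(-mu * radiological depth)
//          * (sad / source-voxel distance)^2 * output
//
// Radiological depth is obtained by fixed-step ray marching through the
// body mask from the ray's entry into the grid bounding box to the voxel
// (the phantom is water-equivalent everywhere). Fluence is looked up
// bilinearly on the per-control-point map at the isocenter plane; outside
// the map extent the closed-leaf transmission level `fallback` applies.

// [[Rcpp::export]]
NumericVector cpp_phase_dose(IntegerVector dims, NumericVector origin,
                             NumericVector spacing, LogicalVector body,
                             List cps, double mu_water, double sad,
                             double output, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dose(nvox);

  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double inv_dx = 1.0 / dx, inv_dy = 1.0 / dy, inv_dz = 1.0 / dz;

  // outer bounding box of the lattice (voxel edges)
  const double lo[3] = {ox - 0.5 * dx, oy - 0.5 * dy, oz - 0.5 * dz};
  const double hi[3] = {ox + (nx - 0.5) * dx, oy + (ny - 0.5) * dy,
                        oz + (nz - 0.5) * dz};

  // collect body voxels once
  std::vector<R_xlen_t> bidx;
  std::vector<double> bx, by, bz;
  bidx.reserve(nvox / 4);
  {
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx)
          if (body[idx]) {
            bidx.push_back(idx);
            bx.push_back(ox + i * dx);
            by.push_back(oy + j * dy);
            bz.push_back(oz + k * dz);
          }
  }
  const size_t nb = bidx.size();
  const int ncp = cps.size();
  const int* bodyp = LOGICAL(body);

  for (int c = 0; c < ncp; ++c) {
    List cp = cps[c];
    NumericMatrix F = cp["F"];
    const double a0 = cp["a0"], b0 = cp["b0"];
    const double da = cp["da"], db = cp["db"];
    const double fallback = cp["fallback"];
    NumericVector src = cp["src"], u = cp["u"], v = cp["v"], w = cp["w"],
                  iso = cp["iso"];
    const int na = F.nrow(), nbm = F.ncol();
    const double sx = src[0], sy = src[1], sz = src[2];
    const double ux = u[0], uy = u[1], uz = u[2];
    const double vx = v[0], vy = v[1], vz = v[2];
    const double wx = w[0], wy = w[1], wz = w[2];
    const double ix = iso[0], iy = iso[1], iz = iso[2];
    const double* Fp = REAL(F);

    for (size_t m = 0; m < nb; ++m) {
      const double px = bx[m], py = by[m], pz = bz[m];
      double rdx = px - sx, rdy = py - sy, rdz = pz - sz;
      const double dist2 = rdx * rdx + rdy * rdy + rdz * rdz;
      const double dist = std::sqrt(dist2);
      const double denom = rdx * wx + rdy * wy + rdz * wz;
      if (denom <= 1e-9) continue;  // behind or beside the source

      // divergent projection onto the isocenter plane
      const double lam = sad / denom;
      const double qx = sx + lam * rdx - ix;
      const double qy = sy + lam * rdy - iy;
      const double qz = sz + lam * rdz - iz;
      const double a = qx * ux + qy * uy + qz * uz;
      const double b = qx * vx + qy * vy + qz * vz;

      double flu;
      const double fa = (a - a0) / da, fb = (b - b0) / db;
      if (fa < 0 || fb < 0 || fa > na - 1 || fb > nbm - 1) {
        flu = fallback;
      } else {
        int ia = (int)fa, ib = (int)fb;
        if (ia >= na - 1) ia = na - 2;
        if (ib >= nbm - 1) ib = nbm - 2;
        const double ta = fa - ia, tb = fb - ib;
        const double f00 = Fp[ia + (R_xlen_t)na * ib];
        const double f10 = Fp[ia + 1 + (R_xlen_t)na * ib];
        const double f01 = Fp[ia + (R_xlen_t)na * (ib + 1)];
        const double f11 = Fp[ia + 1 + (R_xlen_t)na * (ib + 1)];
        flu = f00 * (1 - ta) * (1 - tb) + f10 * ta * (1 - tb) +
              f01 * (1 - ta) * tb + f11 * ta * tb;
      }
      if (flu <= 0) continue;

      // unit ray direction and entry into the grid bounding box
      const double inv_dist = 1.0 / dist;
      const double ex = rdx * inv_dist, ey = rdy * inv_dist,
                   ez = rdz * inv_dist;
      double t0 = 0.0, t1 = dist;
      const double e3[3] = {ex, ey, ez}, s3[3] = {sx, sy, sz};
      bool miss = false;
      for (int ax = 0; ax < 3; ++ax) {
        if (std::fabs(e3[ax]) < 1e-12) {
          if (s3[ax] < lo[ax] || s3[ax] > hi[ax]) { miss = true; break; }
        } else {
          double ta = (lo[ax] - s3[ax]) / e3[ax];
          double tb = (hi[ax] - s3[ax]) / e3[ax];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
        }
      }
      double depth = 0.0;
      if (!miss && t0 < dist) {
        // incremental stepping in fractional grid coordinates; the +0.5
        // turns truncation into round-to-nearest (entry point is inside
        // the bounding box, so coordinates stay non-negative up to
        // rounding epsilon at the padded, body-free grid edge)
        const double t = t0 + 0.5 * step;
        double gx = (sx + t * ex - ox) * inv_dx + 0.5;
        double gy = (sy + t * ey - oy) * inv_dy + 0.5;
        double gz = (sz + t * ez - oz) * inv_dz + 0.5;
        const double hx = step * ex * inv_dx;
        const double hy = step * ey * inv_dy;
        const double hz = step * ez * inv_dz;
        int nsteps = (dist > t) ? (int)((dist - t) / step) + 1 : 0;
        int inside = 0;
        for (; nsteps > 0; --nsteps) {
          const int ii = (int)gx, jj = (int)gy, kk = (int)gz;
          if ((unsigned)ii < (unsigned)nx && (unsigned)jj < (unsigned)ny &&
              (unsigned)kk < (unsigned)nz &&
              bodyp[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)])
            ++inside;
          gx += hx; gy += hy; gz += hz;
        }
        depth = inside * step;
      }

      dose[bidx[m]] +=
          flu * std::exp(-mu_water * depth) * (sad * sad / dist2) * output;
    }
  }
  return dose;
}

// Radiological depths for probe points along a beam (used by tests to
// cross-check the marcher against closed forms on slabs).
// [[Rcpp::export]]
NumericVector cpp_ray_depth(IntegerVector dims, NumericVector origin,
                            NumericVector spacing, LogicalVector body,
                            NumericVector src, NumericMatrix pts,
                            double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double lo[3] = {ox - 0.5 * dx, oy - 0.5 * dy, oz - 0.5 * dz};
  const double hi[3] = {ox + (nx - 0.5) * dx, oy + (ny - 0.5) * dy,
                        oz + (nz - 0.5) * dz};
  const int* bodyp = LOGICAL(body);
  const int n = pts.nrow();
  NumericVector out(n);
  for (int m = 0; m < n; ++m) {
    double rdx = pts(m, 0) - src[0], rdy = pts(m, 1) - src[1],
           rdz = pts(m, 2) - src[2];
    const double dist = std::sqrt(rdx * rdx + rdy * rdy + rdz * rdz);
    const double ex = rdx / dist, ey = rdy / dist, ez = rdz / dist;
    double t0 = 0.0;
    const double e3[3] = {ex, ey, ez};
    const double s3[3] = {src[0], src[1], src[2]};
    for (int ax = 0; ax < 3; ++ax) {
      if (std::fabs(e3[ax]) > 1e-12) {
        double ta = (lo[ax] - s3[ax]) / e3[ax];
        double tb = (hi[ax] - s3[ax]) / e3[ax];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
      }
    }
    double depth = 0.0, t = t0 + 0.5 * step;
    while (t < dist) {
      const double cx = s3[0] + t * ex, cy = s3[1] + t * ey,
                   cz = s3[2] + t * ez;
      const int ii = (int)std::lround((cx - ox) / dx);
      const int jj = (int)std::lround((cy - oy) / dy);
      const int kk = (int)std::lround((cz - oz) / dz);
      if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz &&
          bodyp[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)])
        depth += step;
      t += step;
    }
    out[m] = depth;
  }
  return out;
}
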