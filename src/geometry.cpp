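// Trilinear projection and batched bilinear image rotation. Both are inner
// loops of the library build (one projection per model and direction; one
// rotation per alignment search variant) and dominate runtime if written
// with R-level vectorized gathers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double trilinear(const cube& g, double x, double y, double z) {
  // x, y, z are 0-based continuous voxel indices
  const int nx = g.n_rows, ny = g.n_cols, nz = g.n_slices;
  const int x0 = static_cast<int>(std::floor(x));
  const int y0 = static_cast<int>(std::floor(y));
  const int z0 = static_cast<int>(std::floor(z));
  if (x0 < -1 || y0 < -1 || z0 < -1 || x0 > nx - 1 || y0 > ny - 1 ||
      z0 > nz - 1) {
    return 0.0;
  }
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    const int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    const double wz = dz ? fz : 1 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      const int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      const double wy = dy ? fy : 1 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        const int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        const double wx = dx ? fx : 1 - fx;
        out += wx * wy * wz * g(xi, yi, zi);
      }
    }
  }
  return out;
}

// line-integral projection of a map along basis column 3, sampled on the
// (xs x xs) image raster with z steps zs; spacing is per-axis angstrom
// [[Rcpp::export(name = ".project_cpp")]]
arma::mat project_cpp(const arma::cube& grid, const arma::vec& spacing,
                      const arma::mat& basis, const arma::vec& xs,
                      const arma::vec& zs) {
  const int n = xs.n_elem;
  const vec ctr = {grid.n_rows * spacing[0] / 2.0,
                   grid.n_cols * spacing[1] / 2.0,
                   grid.n_slices * spacing[2] / 2.0};
  mat img(n, n, fill::zeros);
  for (int iy = 0; iy < n; ++iy) {
    for (int ix = 0; ix < n; ++ix) {
      double acc = 0.0;
      for (uword iz = 0; iz < zs.n_elem; ++iz) {
        const double px = ctr[0] + xs[ix] * basis(0, 0) +
          xs[iy] * basis(0, 1) + zs[iz] * basis(0, 2);
        const double py = ctr[1] + xs[ix] * basis(1, 0) +
          xs[iy] * basis(1, 1) + zs[iz] * basis(1, 2);
        const double pz = ctr[2] + xs[ix] * basis(2, 0) +
          xs[iy] * basis(2, 1) + zs[iz] * basis(2, 2);
        acc += trilinear(grid, px / spacing[0] - 0.5, py / spacing[1] - 0.5,
                         pz / spacing[2] - 0.5);
      }
      img(ix, iy) = acc;
    }
  }
  return img;
}

// counterclockwise rotations of one image about its center (bilinear,
// zero padding); one output slice per angle
// [[Rcpp::export(name = ".rotate_images_cpp")]]
arma::cube rotate_images_cpp(const arma::mat& img,
                             const arma::vec& psis_deg) {
  const int n = img.n_rows;
  const double ctr = (n - 1) / 2.0;
  cube out(n, n, psis_deg.n_elem, fill::zeros);
  for (uword v = 0; v < psis_deg.n_elem; ++v) {
    const double th = psis_deg[v] * M_PI / 180.0;
    const double cs = std::cos(th), sn = std::sin(th);
    for (int j = 0; j < n; ++j) {
      const double dy = j - ctr;
      for (int i = 0; i < n; ++i) {
        const double dx = i - ctr;
        const double sx = ctr + cs * dx + sn * dy;
        const double sy = ctr - sn * dx + cs * dy;
        const int x0 = static_cast<int>(std::floor(sx));
        const int y0 = static_cast<int>(std::floor(sy));
        if (x0 < -1 || y0 < -1 || x0 > n - 1 || y0 > n - 1) continue;
        const double fx = sx - x0, fy = sy - y0;
        double val = 0.0;
        for (int dyy = 0; dyy <= 1; ++dyy) {
          const int yi = y0 + dyy;
          if (yi < 0 || yi >= n) continue;
          const double wy = dyy ? fy : 1 - fy;
          for (int dxx = 0; dxx <= 1; ++dxx) {
            const int xi = x0 + dxx;
            if (xi < 0 || xi >= n) continue;
            const double wx = dxx ? fx : 1 - fx;
            val += wx * wy * img(xi, yi);
          }
        }
        out(i, j, v) = val;
      }
    }
  }
  return out;
}
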