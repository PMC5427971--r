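#include <Rcpp.h>
using namespace Rcpp;

// Coarse 9-6 Lennard-Jones energy summed over unique inter-copy atom pairs
// within the cutoff.  `copy` labels which symmetry copy each row belongs to;
// intra-copy pairs are excluded.
// [[Rcpp::export]]
double lj_energy_cpp(const NumericMatrix& xyz, const IntegerVector& copy,
                     double sigma, double eps, double cutoff) {
  const int n = xyz.nrow();
  const double cut2 = cutoff * cutoff;
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const int ci = copy[i];
    for (int j = i + 1; j < n; ++j) {
      if (copy[j] == ci) continue;
      const double dx = xyz(j, 0) - xi;
      const double dy = xyz(j, 1) - yi;
      const double dz = xyz(j, 2) - zi;
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2 || r2 <= 0.0) continue;
      const double s2 = (sigma * sigma) / r2;
      const double s6 = s2 * s2 * s2;
      const double s9 = s6 * std::sqrt(s6);
      e += 4.0 * eps * (s9 - s6);
    }
  }
  return e;
}

// Minimum distance between atoms belonging to different copies.
// [[Rcpp::export]]
double min_intercopy_dist_cpp(const NumericMatrix& xyz,
                              const IntegerVector& copy) {
  const int n = xyz.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i) {
    const int ci = copy[i];
    for (int j = i + 1; j < n; ++j) {
      if (copy[j] == ci) continue;
      const double dx = xyz(j, 0) - xyz(i, 0);
      const double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  }
  return std::sqrt(best);
}

// Sum of unit-weight isotropic Gaussians on a regular grid.  The kernel is
// truncated spherically at trunc_sd * sigma.  Grid values are returned in
// R array order (x fastest), origin is the centre of voxel [1,1,1].
// [[Rcpp::export]]
NumericVector splat_gaussian_cpp(const NumericMatrix& xyz,
                                 const IntegerVector& dims,
                                 const NumericVector& origin, double voxel,
                                 double sigma, double trunc_sd) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector grid(static_cast<R_xlen_t>(nx) * ny * nz);
  const double rcut = trunc_sd * sigma;
  const double rcut2 = rcut * rcut;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int natom = xyz.nrow();
  for (int a = 0; a < natom; ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    int ix0 = (int)std::ceil((ax - rcut - origin[0]) / voxel);
    int ix1 = (int)std::floor((ax + rcut - origin[0]) / voxel);
    int iy0 = (int)std::ceil((ay - rcut - origin[1]) / voxel);
    int iy1 = (int)std::floor((ay + rcut - origin[1]) / voxel);
    int iz0 = (int)std::ceil((az - rcut - origin[2]) / voxel);
    int iz1 = (int)std::floor((az + rcut - origin[2]) / voxel);
    if (ix0 < 0) ix0 = 0;
    if (iy0 < 0) iy0 = 0;
    if (iz0 < 0) iz0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * voxel - az;
      const double dz2 = dz * dz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * voxel - ay;
        const double dyz2 = dy * dy + dz2;
        if (dyz2 > rcut2) continue;
        const R_xlen_t base = (static_cast<R_xlen_t>(iz) * ny + iy) * nx;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * voxel - ax;
          const double r2 = dx * dx + dyz2;
          if (r2 > rcut2) continue;
          grid[base + ix] += std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return grid;
}

// Pearson correlation over voxels where a > thr_a or b > thr_b.
// Returns NA if fewer than 2 voxels selected or either side has zero variance.
// [[Rcpp::export]]
double masked_cor_cpp(const NumericVector& a, const NumericVector& b,
                      double thr_a, double thr_b) {
  const R_xlen_t n = a.size();
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  R_xlen_t m = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double va = a[i], vb = b[i];
    if (va > thr_a || vb > thr_b) {
      sa += va; sb += vb;
      saa += va * va; sbb += vb * vb; sab += va * vb;
      ++m;
    }
  }
  if (m < 2) return NA_REAL;
  const double ca = saa - sa * sa / m;
  const double cb = sbb - sb * sb / m;
  if (ca <= 0 || cb <= 0) return NA_REAL;
  return (sab - sa * sb / m) / std::sqrt(ca * cb);
}

// All pairwise fixed-frame RMSDs between flattened coordinate sets
// (rows = models, columns = x1,y1,z1,x2,...).
// [[Rcpp::export]]
NumericMatrix rmsd_matrix_cpp(const NumericMatrix& flat) {
  const int n = flat.nrow();
  const int k = flat.ncol();
  const int natom = k / 3;
  NumericMatrix d(n, n);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < k; ++c) {
        const double dv = flat(i, c) - flat(j, c);
        s += dv * dv;
      }
      const double r = std::sqrt(s / natom);
      d(i, j) = r;
      d(j, i) = r;
    }
  }
  return d;
}
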