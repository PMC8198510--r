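// Low-level voxel kernels: connected components, anisotropic exact Euclidean
// distance transform, per-slice bilateral filter, capsule renderer for the
// phantom, point-set and segment-set minimum distances, and the Hungarian
// algorithm for the karyotype assignment.
//
// Volumes are flat vectors in R's column-major (x, y, z) order:
//   flat = x + nx * (y + ny * z), 0-based here, 1-based on the R side.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline long long flat_index(int x, int y, int z, int nx, int ny) {
  return (long long)x + (long long)nx * ((long long)y + (long long)ny * z);
}

struct Offset { int dx, dy, dz; };

static std::vector<Offset> neighbor_offsets(int connectivity) {
  std::vector<Offset> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        int touching = (dx != 0) + (dy != 0) + (dz != 0);
        if (connectivity == 6 && touching > 1) continue;
        if (connectivity == 18 && touching > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// ---------------------------------------------------------------------------
// Connected components (BFS), arbitrary 6/18/26 connectivity.
// Returns labels in scan order of discovery; size filtering / renumbering by
// descending voxel count happens on the R side.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  if ((long long)mask.size() != n) stop("mask size does not match dims");
  std::vector<Offset> off = neighbor_offsets(connectivity);
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<long long> queue;
  for (long long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      long long cur = queue.back();
      queue.pop_back();
      int cz = (int)(cur / ((long long)nx * ny));
      long long rem = cur % ((long long)nx * ny);
      int cy = (int)(rem / nx);
      int cx = (int)(rem % nx);
      for (const Offset &o : off) {
        int x = cx + o.dx, y = cy + o.dy, z = cz + o.dz;
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
        long long j = flat_index(x, y, z, nx, ny);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          queue.push_back(j);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic sample spacing. Foreground voxels receive the squared distance
// in nm^2 to the nearest background voxel center; background voxels get 0.

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double step) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = q * step;
    double s = 0.0;
    while (true) {
      double vv = v[k] * step;
      if (f[q] == INF && f[v[k]] == INF) { s = INF; }
      else s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * step;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
  static const double INF = std::numeric_limits<double>::infinity();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  if ((long long)fg.size() != n) stop("mask size does not match dims");
  NumericVector out(fg.size());
  for (long long i = 0; i < n; ++i) out[i] = fg[i] ? INF : 0.0;

  std::vector<double> f, d;
  // along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      long long base = flat_index(0, y, z, nx, ny);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[flat_index(x, y, z, nx, ny)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[flat_index(x, y, z, nx, ny)] = d[y];
    }
  // along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[flat_index(x, y, z, nx, ny)];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[flat_index(x, y, z, nx, ny)] = d[z];
    }
  // infinities remain only if there is no background voxel at all
  for (long long i = 0; i < n; ++i)
    if (out[i] == INF) out[i] = NA_REAL;
  return out;
}

// ---------------------------------------------------------------------------
// Per-slice (x-y) bilateral filter: edge-preserving denoising applied
// independently to every z-slice, Gaussian in both space and intensity.
// [[Rcpp::export]]
NumericVector bilateral_xy_cpp(NumericVector img, IntegerVector dims,
                               int radius, double sigma_s, double sigma_r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(img.size());
  if (radius <= 0) {
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  const double inv2ss = 1.0 / (2.0 * sigma_s * sigma_s);
  const double inv2sr = 1.0 / (2.0 * sigma_r * sigma_r);
  std::vector<double> sw((2 * radius + 1) * (2 * radius + 1));
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      sw[(dy + radius) * (2 * radius + 1) + (dx + radius)] =
          std::exp(-(dx * dx + dy * dy) * inv2ss);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long long ci = flat_index(x, y, z, nx, ny);
        double c = img[ci], acc = 0.0, wacc = 0.0;
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -radius; dx <= radius; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            double v = img[flat_index(xx, yy, z, nx, ny)];
            double dv = v - c;
            double w = sw[(dy + radius) * (2 * radius + 1) + (dx + radius)] *
                       std::exp(-dv * dv * inv2sr);
            acc += w * v;
            wacc += w;
          }
        }
        out[ci] = acc / wacc;
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Capsule-chain renderer for the phantom generator.
//
// Segments (p1->p2, radii r1->r2 linearly interpolated along the segment)
// describe both chromatids of one chromosome in physical nm; voxel (i,j,k)
// 1-based on the R side sits at ((i-0.5)sx, (j-0.5)sy, (k-0.5)sz). For every
// voxel in the padded bounding box the minimum normalized distance
// dn = d / rho over all segments decides membership (dn <= 1) and intensity
//   I(dn) = axis - (axis - edge) * dn^2
// clipped at background. Intensities blend by maximum; labels are written
// where dn <= 1. Modifies img/lab in place; returns the voxel count labeled.
// [[Rcpp::export]]
int render_capsule_chain_cpp(NumericVector img, IntegerVector lab,
                             IntegerVector dims, NumericVector spacing,
                             NumericMatrix p1, NumericMatrix p2,
                             NumericVector r1, NumericVector r2, int label,
                             double axis_level, double edge_level,
                             double background_level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ns = p1.nrow();
  if (ns == 0) return 0;
  const double drop = axis_level - edge_level;
  if (drop <= 0) stop("axis_level must exceed edge_level");
  const double dn_max = std::sqrt((axis_level - background_level) / drop);

  double rmax = 0.0;
  for (int s = 0; s < ns; ++s)
    rmax = std::max(rmax, std::max((double)r1[s], (double)r2[s]));
  double pad = dn_max * rmax + 1e-9;

  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int s = 0; s < ns; ++s)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], std::min(p1(s, a), p2(s, a)));
      hi[a] = std::max(hi[a], std::max(p1(s, a), p2(s, a)));
    }
  int i0[3], i1[3];
  int nmax[3] = {nx, ny, nz};
  for (int a = 0; a < 3; ++a) {
    i0[a] = std::max(0, (int)std::floor((lo[a] - pad) / spacing[a] - 0.5));
    i1[a] = std::min(nmax[a] - 1,
                     (int)std::ceil((hi[a] + pad) / spacing[a] - 0.5));
  }

  int count = 0;
  for (int k = i0[2]; k <= i1[2]; ++k) {
    double pz = (k + 0.5) * spacing[2];
    for (int j = i0[1]; j <= i1[1]; ++j) {
      double py = (j + 0.5) * spacing[1];
      for (int i = i0[0]; i <= i1[0]; ++i) {
        double px = (i + 0.5) * spacing[0];
        double best = 1e300;
        for (int s = 0; s < ns; ++s) {
          double ax = p1(s, 0), ay = p1(s, 1), az = p1(s, 2);
          double bx = p2(s, 0) - ax, by = p2(s, 1) - ay, bz = p2(s, 2) - az;
          double wx = px - ax, wy = py - ay, wz = pz - az;
          double bb = bx * bx + by * by + bz * bz;
          double t = bb > 0 ? (wx * bx + wy * by + wz * bz) / bb : 0.0;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double dx = wx - t * bx, dy = wy - t * by, dz = wz - t * bz;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          double rho = r1[s] + (r2[s] - r1[s]) * t;
          if (rho <= 0) continue;
          double dn = d / rho;
          if (dn < best) best = dn;
        }
        if (best > dn_max) continue;
        long long fi = flat_index(i, j, k, nx, ny);
        double I = axis_level - drop * best * best;
        if (I > img[fi]) img[fi] = I;
        if (best <= 1.0) {
          if (lab[fi] == 0) {
            lab[fi] = label;
            ++count;
          }
        }
      }
    }
  }
  return count;
}

// ---------------------------------------------------------------------------
// Minimum squared distance between two point sets (rows = points, nm).
// If cutoff_sq >= 0, returns early with any value <= cutoff_sq once found
// (enough for thresholded neighbor queries); with cutoff_sq < 0 the exact
// minimum is computed.
// [[Rcpp::export]]
double min_pairdist_sq_cpp(NumericMatrix a, NumericMatrix b,
                           double cutoff_sq) {
  const int na = a.nrow(), nb = b.nrow();
  double best = std::numeric_limits<double>::infinity();
  for (int i = 0; i < na; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) {
        best = d;
        if (cutoff_sq >= 0 && best <= cutoff_sq) return best;
      }
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Closest points between two 3D segments (Ericson, Real-Time Collision
// Detection, 5.1.9). Returns squared distance; writes the closest points.
static double closest_segseg(const double *p1, const double *q1,
                             const double *p2, const double *q2, double *ca,
                             double *cb) {
  double d1[3], d2[3], rr[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = q1[k] - p1[k];
    d2[k] = q2[k] - p2[k];
    rr[k] = p1[k] - p2[k];
  }
  double a = d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2];
  double e = d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2];
  double f = d2[0] * rr[0] + d2[1] * rr[1] + d2[2] * rr[2];
  double s = 0.0, t = 0.0;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) {
    // both segments degenerate
  } else if (a <= EPS) {
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    double c = d1[0] * rr[0] + d1[1] * rr[1] + d1[2] * rr[2];
    if (e <= EPS) {
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2];
      double denom = a * e - b * b;
      if (denom > EPS) s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(1.0, std::max(0.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - c) / a));
      }
    }
  }
  double dd = 0.0;
  for (int k = 0; k < 3; ++k) {
    ca[k] = p1[k] + s * d1[k];
    cb[k] = p2[k] + t * d2[k];
    double diff = ca[k] - cb[k];
    dd += diff * diff;
  }
  return dd;
}

// Minimum squared distance between two segment sets (rows of a1/a2 and
// b1/b2 are segment endpoints), with the realizing closest points.
// [[Rcpp::export]]
NumericVector min_segdist_arg_cpp(NumericMatrix a1, NumericMatrix a2,
                                  NumericMatrix b1, NumericMatrix b2) {
  const int na = a1.nrow(), nb = b1.nrow();
  double best = std::numeric_limits<double>::infinity();
  double bca[3] = {0, 0, 0}, bcb[3] = {0, 0, 0};
  double pa[3], qa[3], pb[3], qb[3], ca[3], cb[3];
  for (int i = 0; i < na; ++i) {
    for (int k = 0; k < 3; ++k) {
      pa[k] = a1(i, k);
      qa[k] = a2(i, k);
    }
    for (int j = 0; j < nb; ++j) {
      for (int k = 0; k < 3; ++k) {
        pb[k] = b1(j, k);
        qb[k] = b2(j, k);
      }
      double d = closest_segseg(pa, qa, pb, qb, ca, cb);
      if (d < best) {
        best = d;
        for (int k = 0; k < 3; ++k) {
          bca[k] = ca[k];
          bcb[k] = cb[k];
        }
      }
    }
  }
  return NumericVector::create(best, bca[0], bca[1], bca[2], bcb[0], bcb[1],
                               bcb[2]);
}

// ---------------------------------------------------------------------------
// Exact minimum squared distance between two point sets together with the
// arg-min pair (1-based row indices), for the repulsive placement relaxation.
// [[Rcpp::export]]
NumericVector min_pairdist_arg_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  double best = std::numeric_limits<double>::infinity();
  int bi = 0, bj = 0;
  for (int i = 0; i < na; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) {
        best = d;
        bi = i;
        bj = j;
      }
    }
  }
  return NumericVector::create(best, bi + 1, bj + 1);
}

// ---------------------------------------------------------------------------
// Hungarian algorithm (shortest augmenting path, O(n^3)) for square cost
// matrices. Returns, for each row, the assigned column (1-based).
// [[Rcpp::export]]
IntegerVector hungarian_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) {
          minv[j] = cur;
          way[j] = j0;
        }
        if (minv[j] < delta) {
          delta = minv[j];
          j1 = j;
        }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) {
          u[p[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector row_to_col(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) row_to_col[p[j] - 1] = j;
  return row_to_col;
}
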