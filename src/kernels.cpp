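#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx), column-major:
// linear index i = z + nz * (y + ny * x), all 0-based here.

// ---------------------------------------------------------------------------
// Separable convolution with replicate (edge-clamp) boundary handling.
// Kernels must have odd length; the centre tap sits at (len-1)/2.
// ---------------------------------------------------------------------------
static void conv_axis(std::vector<double> &a, int nz, int ny, int nx,
                      int axis, const NumericVector &k) {
  const int kl = k.size();
  if (kl <= 1) return;
  const int c = (kl - 1) / 2;
  int n;
  long stride;
  if (axis == 0) { n = nz; stride = 1; }
  else if (axis == 1) { n = ny; stride = nz; }
  else { n = nx; stride = (long)nz * ny; }

  std::vector<double> line(n), out(n);
  // iterate over all 1D lines along `axis`
  long total = (long)nz * ny * nx;
  long nlines = total / n;
  for (long l = 0; l < nlines; ++l) {
    long base;
    if (axis == 0) {
      base = l * nz;                                    // (y, x) flattened
    } else if (axis == 1) {
      long z = l % nz, x = l / nz;
      base = z + (long)nz * ny * x;
    } else {
      base = l;                                         // (z, y) flattened
    }
    for (int i = 0; i < n; ++i) line[i] = a[base + (long)i * stride];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < kl; ++j) {
        int p = i + j - c;
        if (p < 0) p = 0; else if (p >= n) p = n - 1;
        acc += k[j] * line[p];
      }
      out[i] = acc;
    }
    for (int i = 0; i < n; ++i) a[base + (long)i * stride] = out[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_sep(NumericVector a, IntegerVector dim,
                            NumericVector kz, NumericVector ky,
                            NumericVector kx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> buf(a.begin(), a.end());
  conv_axis(buf, nz, ny, nx, 0, kz);
  conv_axis(buf, nz, ny, nx, 1, ky);
  conv_axis(buf, nz, ny, nx, 2, kx);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Per-slice (y, x) local box mean with replicate padding.
// Window spans lo = floor((w-1)/2) before and hi = w-1-lo after the centre,
// so even window sizes are allowed.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_local_mean_slices(NumericVector a, IntegerVector dim, int w) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const int lo = (w - 1) / 2;
  const int py = ny + w - 1, px = nx + w - 1;
  NumericVector out(a.size());
  std::vector<double> S((py + 1) * (size_t)(px + 1));
  const double inv = 1.0 / ((double)w * w);

  for (int z = 0; z < nz; ++z) {
    // padded integral image, S[(i, j)] = sum over padded rows < i, cols < j
    for (int j = 0; j <= px; ++j) S[(size_t)j] = 0.0;
    for (int i = 1; i <= py; ++i) {
      S[(size_t)i * (px + 1)] = 0.0;
      int yy = i - 1 - lo; if (yy < 0) yy = 0; else if (yy >= ny) yy = ny - 1;
      double rowsum = 0.0;
      for (int j = 1; j <= px; ++j) {
        int xx = j - 1 - lo; if (xx < 0) xx = 0; else if (xx >= nx) xx = nx - 1;
        rowsum += a[z + (long)nz * (yy + (long)ny * xx)];
        S[(size_t)i * (px + 1) + j] = S[(size_t)(i - 1) * (px + 1) + j] + rowsum;
      }
    }
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        // window over padded coords [y, y+w) x [x, x+w)
        double s = S[(size_t)(y + w) * (px + 1) + (x + w)]
                 - S[(size_t)y * (px + 1) + (x + w)]
                 - S[(size_t)(y + w) * (px + 1) + x]
                 + S[(size_t)y * (px + 1) + x];
        out[z + (long)nz * (y + (long)ny * x)] = s * inv;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 3D connected-component labelling (union-find), connectivity 6 / 18 / 26.
// Labels are assigned in order of each component's first voxel in linear scan
// order, so output is deterministic.
// ---------------------------------------------------------------------------
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim,
                         int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long total = (long)nz * ny * nx;

  // predecessor neighbour offsets for the chosen connectivity
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        bool before = (dx < 0) || (dx == 0 && (dy < 0 || (dy == 0 && dz < 0)));
        if (before) offs.push_back({dz, dy, dx});
      }

  std::vector<int> parent(total);
  for (long i = 0; i < total; ++i) parent[i] = (int)i;

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long i = z + (long)nz * (y + (long)ny * x);
        if (!mask[i]) continue;
        for (const auto &o : offs) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          long j = zz + (long)nz * (yy + (long)ny * xx);
          if (!mask[j]) continue;
          int ri = uf_find(parent, (int)i), rj = uf_find(parent, (int)j);
          if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
        }
      }

  IntegerVector lab(total);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (long i = 0; i < total; ++i) {
    if (!mask[i]) { lab[i] = 0; continue; }
    int r = uf_find(parent, (int)i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope method, one pass per axis).
// Returns squared distance (um^2) from every voxel centre to the nearest
// TRUE voxel centre; Inf if the mask is empty.
// ---------------------------------------------------------------------------
static void edt_axis(std::vector<double> &f, int nz, int ny, int nx,
                     int axis, double s) {
  int n;
  long stride;
  if (axis == 0) { n = nz; stride = 1; }
  else if (axis == 1) { n = ny; stride = nz; }
  else { n = nx; stride = (long)nz * ny; }
  const double s2 = s * s;
  long total = (long)nz * ny * nx;
  long nlines = total / n;
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> g(n), d(n), zb(n + 1);
  std::vector<int> v(n);
  for (long l = 0; l < nlines; ++l) {
    long base;
    if (axis == 0) base = l * nz;
    else if (axis == 1) { long z = l % nz, x = l / nz; base = z + (long)nz * ny * x; }
    else base = l;

    for (int i = 0; i < n; ++i) g[i] = f[base + (long)i * stride];
    int k = 0;
    v[0] = 0;
    zb[0] = -INF;
    zb[1] = INF;
    for (int q = 1; q < n; ++q) {
      if (g[q] == INF) continue;
      if (g[v[0]] == INF && k == 0) { v[0] = q; continue; }
      double sint;
      while (true) {
        int p = v[k];
        sint = ((g[q] + s2 * q * q) - (g[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
        if (sint <= zb[k]) { --k; } else break;
      }
      ++k;
      v[k] = q;
      zb[k] = sint;
      zb[k + 1] = INF;
    }
    if (g[v[0]] == INF) {
      // whole line infinite
      for (int i = 0; i < n; ++i) f[base + (long)i * stride] = INF;
      continue;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
      while (zb[k + 1] < q) ++k;
      double dq = (double)(q - v[k]);
      d[q] = s2 * dq * dq + g[v[k]];
    }
    for (int i = 0; i < n; ++i) f[base + (long)i * stride] = d[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3_sq(LogicalVector mask, IntegerVector dim,
                          NumericVector spacing_zyx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long total = (long)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> f(total);
  for (long i = 0; i < total; ++i) f[i] = mask[i] ? 0.0 : INF;
  edt_axis(f, nz, ny, nx, 0, spacing_zyx[0]);
  edt_axis(f, nz, ny, nx, 1, spacing_zyx[1]);
  edt_axis(f, nz, ny, nx, 2, spacing_zyx[2]);
  NumericVector out(f.begin(), f.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Additive Gaussian spots, truncated at `trunc` sigma (ellipsoidal support).
// centers: n x 3 matrix of 0-based voxel coordinates (z, y, x), fractional
// positions allowed. sigma in voxels per axis.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_add_spots(NumericVector a, IntegerVector dim,
                            NumericMatrix centers, NumericVector sigma_zyx,
                            NumericVector amp, double trunc) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(a);
  const double sz = sigma_zyx[0], sy = sigma_zyx[1], sx = sigma_zyx[2];
  const double t2 = trunc * trunc;
  for (int p = 0; p < centers.nrow(); ++p) {
    double cz = centers(p, 0), cy = centers(p, 1), cx = centers(p, 2);
    double A = amp[p];
    int z0 = std::max(0, (int)std::ceil(cz - trunc * sz));
    int z1 = std::min(nz - 1, (int)std::floor(cz + trunc * sz));
    int y0 = std::max(0, (int)std::ceil(cy - trunc * sy));
    int y1 = std::min(ny - 1, (int)std::floor(cy + trunc * sy));
    int x0 = std::max(0, (int)std::ceil(cx - trunc * sx));
    int x1 = std::min(nx - 1, (int)std::floor(cx + trunc * sx));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double dz = (z - cz) / sz, dy = (y - cy) / sy, dx = (x - cx) / sx;
          double r2 = dz * dz + dy * dy + dx * dx;
          if (r2 > t2) continue;
          out[z + (long)nz * (y + (long)ny * x)] += A * std::exp(-0.5 * r2);
        }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Fill capsules (cylinders with spherical caps) into a logical mask.
// Endpoints p0, p1 and radius are in physical um; spacing_zyx converts voxel
// indices to physical coordinates. Voxels flagged in `exclude` are skipped.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_fill_capsules(LogicalVector mask, IntegerVector dim,
                                NumericVector spacing_zyx,
                                NumericMatrix p0, NumericMatrix p1,
                                NumericVector radius,
                                Nullable<LogicalVector> exclude) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out = clone(mask);
  LogicalVector ex;
  bool has_ex = exclude.isNotNull();
  if (has_ex) ex = exclude.get();
  const double vz = spacing_zyx[0], vy = spacing_zyx[1], vx = spacing_zyx[2];

  for (int c = 0; c < p0.nrow(); ++c) {
    double az = p0(c, 0), ay = p0(c, 1), ax = p0(c, 2);
    double bz = p1(c, 0), by = p1(c, 1), bx = p1(c, 2);
    double r = radius[c], r2 = r * r;
    double lz = bz - az, ly = by - ay, lx = bx - ax;
    double L2 = lz * lz + ly * ly + lx * lx;
    int z0 = std::max(0, (int)std::floor((std::min(az, bz) - r) / vz));
    int z1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + r) / vz));
    int y0 = std::max(0, (int)std::floor((std::min(ay, by) - r) / vy));
    int y1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + r) / vy));
    int x0 = std::max(0, (int)std::floor((std::min(ax, bx) - r) / vx));
    int x1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + r) / vx));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double pz = z * vz, py = y * vy, px = x * vx;
          double t = 0.0;
          if (L2 > 0.0) {
            t = ((pz - az) * lz + (py - ay) * ly + (px - ax) * lx) / L2;
            t = std::min(1.0, std::max(0.0, t));
          }
          double dz = pz - (az + t * lz), dy = py - (ay + t * ly),
                 dx = px - (ax + t * lx);
          if (dz * dz + dy * dy + dx * dx > r2) continue;
          long i = z + (long)nz * (y + (long)ny * x);
          if (has_ex && ex[i]) continue;
          out[i] = true;
        }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Fill axis-aligned ellipsoids (semi-axes in um) into a logical mask.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_fill_ellipsoids(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing_zyx,
                                  NumericMatrix centers,
                                  NumericMatrix semiaxes) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out = clone(mask);
  const double vz = spacing_zyx[0], vy = spacing_zyx[1], vx = spacing_zyx[2];
  for (int c = 0; c < centers.nrow(); ++c) {
    double cz = centers(c, 0), cy = centers(c, 1), cx = centers(c, 2);
    double az = semiaxes(c, 0), ay = semiaxes(c, 1), ax = semiaxes(c, 2);
    int z0 = std::max(0, (int)std::floor((cz - az) / vz));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + az) / vz));
    int y0 = std::max(0, (int)std::floor((cy - ay) / vy));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + ay) / vy));
    int x0 = std::max(0, (int)std::floor((cx - ax) / vx));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + ax) / vx));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double dz = (z * vz - cz) / az, dy = (y * vy - cy) / ay,
                 dx = (x * vx - cx) / ax;
          if (dz * dz + dy * dy + dx * dx > 1.0) continue;
          out[z + (long)nz * (y + (long)ny * x)] = true;
        }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Tabulate overlaps between two label volumes: one row per (label_a, label_b)
// pair with both labels > 0, with the shared voxel count. Rows are sorted by
// (label_a, label_b) so output is deterministic.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_pair_overlaps(IntegerVector la, IntegerVector lb) {
  std::unordered_map<long long, int> tab;
  long n = la.size();
  for (long i = 0; i < n; ++i) {
    int a = la[i], b = lb[i];
    if (a > 0 && b > 0) tab[((long long)a << 32) | (unsigned int)b]++;
  }
  std::vector<long long> keys;
  keys.reserve(tab.size());
  for (auto &kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerMatrix out(keys.size(), 3);
  for (size_t i = 0; i < keys.size(); ++i) {
    out(i, 0) = (int)(keys[i] >> 32);
    out(i, 1) = (int)(keys[i] & 0xffffffffLL);
    out(i, 2) = tab[keys[i]];
  }
  colnames(out) = CharacterVector::create("a", "b", "n");
  return out;
}
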