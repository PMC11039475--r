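// 3D image-analysis kernels: distance transform, connected components,
// region growing, separable convolution, marching-tetrahedra surface area,
// greyscale reconstruction / h-maxima, seeded watershed, Dijkstra geodesics,
// and parallel-beam forward/back-projection.
//
// All volumes are R arrays in native column-major order: linear index
// i + nx*(j + ny*k) addresses voxel (x=i, y=j, z=k), 0-based here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// neighbour offsets for 6/18/26 connectivity
static void neighbour_offsets(int conn, std::vector<int>& dx,
                              std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (conn == 6 && m > 1) continue;
        if (conn == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance measured in voxels from every voxel to the nearest TRUE voxel.

static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = 0;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = 1e18;
  for (R_xlen_t t = 0; t < n; ++t) out[t] = mask[t] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = out[idx3(i, j, k, nx, ny)];
      edt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) out[idx3(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[idx3(i, j, k, nx, ny)];
      edt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) out[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[idx3(i, j, k, nx, ny)];
      edt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) out[idx3(i, j, k, nx, ny)] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (BFS), labels in first-encounter order.

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  int no = dx.size();
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int k = cur / (nx * ny);
      int r = cur - k * nx * ny;
      int j = r / nx;
      int i = r - j * nx;
      for (int o = 0; o < no; ++o) {
        int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int q = idx3(ii, jj, kk, nx, ny);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Seeded region growing: breadth-first from each seed in order, accepting
// 26-neighbours within `tol` of the running mean of the region grown so far.
// First claim wins across labels; conflicts (a later growth reaching an
// already-claimed voxel of another label) are counted.

// [[Rcpp::export]]
List cpp_region_grow(NumericVector vol, IntegerVector dims,
                     IntegerMatrix seeds, IntegerVector seed_labels,
                     double tol) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(26, dx, dy, dz);
  int no = dx.size();
  int conflicts = 0;

  for (int s = 0; s < seeds.nrow(); ++s) {
    int i0 = seeds(s, 0), j0 = seeds(s, 1), k0 = seeds(s, 2);
    int label = seed_labels[s];
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= nx || j0 >= ny || k0 >= nz)
      stop("seed %d outside volume", s + 1);
    int start = idx3(i0, j0, k0, nx, ny);
    if (lab[start]) { if (lab[start] != label) ++conflicts; continue; }
    std::queue<int> q;
    lab[start] = label;
    q.push(start);
    double sum = vol[start];
    double cnt = 1.0;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int k = cur / (nx * ny);
      int r = cur - k * nx * ny;
      int j = r / nx;
      int i = r - j * nx;
      double mean = sum / cnt;
      for (int o = 0; o < no; ++o) {
        int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int p = idx3(ii, jj, kk, nx, ny);
        if (lab[p]) { if (lab[p] != label) ++conflicts; continue; }
        if (std::fabs(vol[p] - mean) <= tol) {
          lab[p] = label;
          sum += vol[p];
          cnt += 1.0;
          q.push(p);
        }
      }
    }
  }
  return List::create(_["labels"] = lab, _["conflicts"] = conflicts);
}

// ---------------------------------------------------------------------------
// Separable 3D convolution with a symmetric 1D kernel (zero padding).

// [[Rcpp::export]]
NumericVector cpp_sep_conv3(NumericVector vol, IntegerVector dims,
                            NumericVector kernel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int kr = (kernel.size() - 1) / 2;
  NumericVector a = clone(vol), b((R_xlen_t)nx * ny * nz);
  // x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -kr; t <= kr; ++t) {
          int ii = i + t;
          if (ii >= 0 && ii < nx) s += kernel[t + kr] * a[idx3(ii, j, k, nx, ny)];
        }
        b[idx3(i, j, k, nx, ny)] = s;
      }
  // y
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -kr; t <= kr; ++t) {
          int jj = j + t;
          if (jj >= 0 && jj < ny) s += kernel[t + kr] * b[idx3(i, jj, k, nx, ny)];
        }
        a[idx3(i, j, k, nx, ny)] = s;
      }
  // z
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -kr; t <= kr; ++t) {
          int kk = k + t;
          if (kk >= 0 && kk < nz) s += kernel[t + kr] * a[idx3(i, j, kk, nx, ny)];
        }
        b[idx3(i, j, k, nx, ny)] = s;
      }
  return b;
}

// ---------------------------------------------------------------------------
// Marching-tetrahedra isosurface area. Each cube cell is split into six
// tetrahedra sharing the main diagonal; iso-crossing edges are interpolated
// linearly. Returns total triangle area in voxel^2 units.

static const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double v[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_march_tet_area(NumericVector field, IntegerVector dims,
                          double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double area = 0.0;
  double cpos[8][3], cval[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          cval[c] = field[idx3(ci, cj, ck, nx, ny)];
          cpos[c][0] = ci; cpos[c][1] = cj; cpos[c][2] = ck;
          if (cval[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vin[4], vout[4], nin = 0, nout = 0;
          for (int m = 0; m < 4; ++m) {
            int c = TETS[t][m];
            if (cval[c] > iso) vin[nin++] = c; else vout[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          double p[4][3];
          int np = 0;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? vin[0] : vout[0];
            int *others = (nin == 1) ? vout : vin;
            for (int m = 0; m < 3; ++m) {
              int o = others[m];
              double tt = (iso - cval[apex]) / (cval[o] - cval[apex]);
              for (int d = 0; d < 3; ++d)
                p[np][d] = cpos[apex][d] + tt * (cpos[o][d] - cpos[apex][d]);
              ++np;
            }
            area += tri_area(p[0], p[1], p[2]);
          } else { // 2-2 case: quad ordered a0b0, a0b1, a1b1, a1b0
            int pairs[4][2] = {
              {vin[0], vout[0]}, {vin[0], vout[1]},
              {vin[1], vout[1]}, {vin[1], vout[0]}
            };
            for (int m = 0; m < 4; ++m) {
              int a = pairs[m][0], b = pairs[m][1];
              double tt = (iso - cval[a]) / (cval[b] - cval[a]);
              for (int d = 0; d < 3; ++d)
                p[m][d] = cpos[a][d] + tt * (cpos[b][d] - cpos[a][d]);
            }
            area += tri_area(p[0], p[1], p[2]) + tri_area(p[0], p[2], p[3]);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Greyscale reconstruction by dilation (hybrid raster algorithm, 26-conn),
// marker <= mask assumed. Used for h-maxima.

// [[Rcpp::export]]
NumericVector cpp_grey_reconstruct(NumericVector marker, NumericVector mask,
                                   IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector f = clone(marker);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(26, dx, dy, dz);
  int no = dx.size();
  bool changed = true;
  int guard = 0;
  while (changed && guard < 10000) {
    changed = false;
    ++guard;
    // forward raster
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int p = idx3(i, j, k, nx, ny);
          double m = f[p];
          for (int o = 0; o < no; ++o) {
            int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            double v = f[idx3(ii, jj, kk, nx, ny)];
            if (v > m) m = v;
          }
          m = std::min(m, mask[p]);
          if (m > f[p]) { f[p] = m; changed = true; }
        }
    // backward raster
    for (int k = nz - 1; k >= 0; --k)
      for (int j = ny - 1; j >= 0; --j)
        for (int i = nx - 1; i >= 0; --i) {
          int p = idx3(i, j, k, nx, ny);
          double m = f[p];
          for (int o = 0; o < no; ++o) {
            int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            double v = f[idx3(ii, jj, kk, nx, ny)];
            if (v > m) m = v;
          }
          m = std::min(m, mask[p]);
          if (m > f[p]) { f[p] = m; changed = true; }
        }
  }
  (void)n;
  return f;
}

// Regional maxima of f restricted to mask (26-conn): plateaus with no
// strictly greater neighbour inside mask.

// [[Rcpp::export]]
LogicalVector cpp_regional_maxima(NumericVector f, LogicalVector mask,
                                  IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<char> suppressed(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(26, dx, dy, dz);
  int no = dx.size();
  std::queue<int> q;
  // seed suppression from voxels having a strictly greater masked neighbour
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = idx3(i, j, k, nx, ny);
        if (!mask[p]) continue;
        for (int o = 0; o < no; ++o) {
          int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          int pq = idx3(ii, jj, kk, nx, ny);
          if (mask[pq] && f[pq] > f[p]) { suppressed[p] = 1; q.push(p); break; }
        }
      }
  // spread through equal-valued plateaus
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int k = cur / (nx * ny);
    int r = cur - k * nx * ny;
    int j = r / nx;
    int i = r - j * nx;
    for (int o = 0; o < no; ++o) {
      int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int p = idx3(ii, jj, kk, nx, ny);
      if (mask[p] && !suppressed[p] && f[p] == f[cur]) {
        suppressed[p] = 1;
        q.push(p);
      }
    }
  }
  for (R_xlen_t p = 0; p < n; ++p) out[p] = mask[p] && !suppressed[p];
  return out;
}

// ---------------------------------------------------------------------------
// Seeded watershed on a height map (flood from seeds in decreasing height).

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector height, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(26, dx, dy, dz);
  int no = dx.size();
  typedef std::tuple<double, long long, int> Node; // (height, -order, index)
  std::priority_queue<Node> pq;
  long long counter = 0;
  for (R_xlen_t p = 0; p < n; ++p)
    if (seeds[p] > 0 && mask[p]) {
      lab[p] = seeds[p];
      pq.push(Node(height[p], -(counter++), (int)p));
    }
  while (!pq.empty()) {
    int cur = std::get<2>(pq.top()); pq.pop();
    int k = cur / (nx * ny);
    int r = cur - k * nx * ny;
    int j = r / nx;
    int i = r - j * nx;
    for (int o = 0; o < no; ++o) {
      int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int p = idx3(ii, jj, kk, nx, ny);
      if (mask[p] && !lab[p]) {
        lab[p] = lab[cur];
        pq.push(Node(height[p], -(counter++), p));
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Multi-source Dijkstra within a mask, 26-neighbour moves, edge weight =
// Euclidean step length * 0.5*(cost[u] + cost[v]). Returns distances and
// predecessors (-1 where unreached).

// [[Rcpp::export]]
List cpp_dijkstra(LogicalVector mask, IntegerVector dims,
                  IntegerVector sources, NumericVector cost) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector dist(n, R_PosInf);
  IntegerVector pred(n, -1);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(26, dx, dy, dz);
  int no = dx.size();
  std::vector<double> step(no);
  for (int o = 0; o < no; ++o)
    step[o] = std::sqrt((double)(dx[o]*dx[o] + dy[o]*dy[o] + dz[o]*dz[o]));
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    int p = sources[s];
    if (p < 0 || p >= n) stop("source index out of range");
    dist[p] = 0.0;
    pq.push(Node(0.0, p));
  }
  while (!pq.empty()) {
    double d = pq.top().first;
    int cur = pq.top().second;
    pq.pop();
    if (d > dist[cur]) continue;
    int k = cur / (nx * ny);
    int r = cur - k * nx * ny;
    int j = r / nx;
    int i = r - j * nx;
    for (int o = 0; o < no; ++o) {
      int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int p = idx3(ii, jj, kk, nx, ny);
      if (!mask[p]) continue;
      double w = d + step[o] * 0.5 * (cost[cur] + cost[p]);
      if (w < dist[p]) {
        dist[p] = w;
        pred[p] = cur;
        pq.push(Node(w, p));
      }
    }
  }
  return List::create(_["dist"] = dist, _["pred"] = pred);
}

// ---------------------------------------------------------------------------
// Parallel-beam forward projection: per z-slice line integrals over angles.
// Output array (n_det = nx, n_angles, nz) in voxel-length units.

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector angles, double step,
                                  int n_det = -1,
                                  double det_spacing = 1.0) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx != ny) stop("forward projection requires square slices");
  if (n_det < 0) n_det = nx;
  int na = angles.size();
  NumericVector out((R_xlen_t)n_det * na * nz);
  double c0 = (nx - 1) / 2.0;
  double cd = (n_det - 1) / 2.0;
  double L = std::sqrt(2.0) * nx;
  int ns = (int)std::ceil(L / step);
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int k = 0; k < nz; ++k) {
      const double *slice = REAL(vol) + (R_xlen_t)k * nx * ny;
      for (int t = 0; t < n_det; ++t) {
        double tv = (t - cd) * det_spacing;
        double sum = 0.0;
        for (int s = 0; s <= ns; ++s) {
          double sv = -L / 2.0 + s * step;
          double x = c0 + tv * ct - sv * st;
          double y = c0 + tv * st + sv * ct;
          int ix = (int)std::floor(x), iy = (int)std::floor(y);
          if (ix < 0 || iy < 0 || ix >= nx - 1 || iy >= ny - 1) continue;
          double fx = x - ix, fy = y - iy;
          double v00 = slice[ix + nx * iy];
          double v10 = slice[ix + 1 + nx * iy];
          double v01 = slice[ix + nx * (iy + 1)];
          double v11 = slice[ix + 1 + nx * (iy + 1)];
          sum += (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
                 (1 - fx) * fy * v01 + fx * fy * v11;
        }
        out[t + (R_xlen_t)n_det * (a + (R_xlen_t)na * k)] = sum * step;
      }
    }
  }
  return out;
}

// Filtered back-projection accumulation. sino: (n_det, n_angles, nz)
// already ramp-filtered; returns (n_det, n_det, nz), scaled by pi/n_angles.

// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector sino, IntegerVector dims,
                              NumericVector angles) {
  int nd = dims[0], na = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nd * nd * nz);
  double c0 = (nd - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int k = 0; k < nz; ++k) {
      const double *proj = REAL(sino) + (R_xlen_t)nd * (a + (R_xlen_t)na * k);
      double *slice = REAL(out) + (R_xlen_t)k * nd * nd;
      for (int j = 0; j < nd; ++j) {
        double yv = j - c0;
        for (int i = 0; i < nd; ++i) {
          double xv = i - c0;
          double t = xv * ct + yv * st + c0;
          int it = (int)std::floor(t);
          if (it < 0 || it >= nd - 1) continue;
          double ft = t - it;
          slice[i + nd * j] += (1 - ft) * proj[it] + ft * proj[it + 1];
        }
      }
    }
  }
  double scale = M_PI / na;
  for (R_xlen_t p = 0; p < out.size(); ++p) out[p] *= scale;
  return out;
}

// Majority (modal) filter over 3x3x3 neighbourhoods for small integer
// class maps; ties keep the centre value.

// [[Rcpp::export]]
IntegerVector cpp_mode_filter(IntegerVector lab, IntegerVector dims,
                              int nclass) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(lab.size());
  std::vector<int> cnt(nclass + 1);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        std::fill(cnt.begin(), cnt.end(), 0);
        for (int c = -1; c <= 1; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              int ii = i + a, jj = j + b, kk = k + c;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                  kk >= nz)
                continue;
              int v = lab[idx3(ii, jj, kk, nx, ny)];
              if (v >= 0 && v <= nclass) ++cnt[v];
            }
        int p = idx3(i, j, k, nx, ny);
        int best = lab[p], bestc = cnt[lab[p]];
        for (int v = 0; v <= nclass; ++v)
          if (cnt[v] > bestc) { bestc = cnt[v]; best = v; }
        out[p] = best;
      }
  return out;
}
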