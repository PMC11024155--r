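#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Arrays are indexed [z, y, x] with z fastest (R dim = c(nz, ny, nx)).
// Linear index (0-based): iz + nz * (iy + ny * ix).

static inline void get_dims(const RObject& a, int& nz, int& ny, int& nx) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  nz = d[0]; ny = d[1]; nx = d[2];
}

// ---- connected components ------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, int connectivity) {
  int nz, ny, nx;
  get_dims(mask, nz, ny, nx);
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;

  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int noff = (int)dz.size();

  IntegerVector labels(n);
  labels.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int iz = (int)(v % nz);
      int iy = (int)((v / nz) % ny);
      int ix = (int)(v / ((R_xlen_t)nz * ny));
      for (int o = 0; o < noff; ++o) {
        int jz = iz + dz[o], jy = iy + dy[o], jx = ix + dx[o];
        if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
        R_xlen_t w = jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx);
        if (mask[w] != 0 && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n_labels") = next;
  return labels;
}

// does each label touch (6-connectivity) a voxel where `mask` is nonzero?
// [[Rcpp::export]]
LogicalVector cpp_label_adjacent(IntegerVector labels, IntegerVector mask, int n_labels) {
  int nz, ny, nx;
  get_dims(labels, nz, ny, nx);
  LogicalVector out(n_labels);
  const int dz[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0}, dx[6] = {0,0,0,0,1,-1};
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        R_xlen_t v = iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
        int lab = labels[v];
        if (lab == 0 || out[lab - 1]) continue;
        for (int o = 0; o < 6; ++o) {
          int jz = iz + dz[o], jy = iy + dy[o], jx = ix + dx[o];
          if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
          R_xlen_t w = jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx);
          if (mask[w] != 0) { out[lab - 1] = true; break; }
        }
      }
  return out;
}

// ---- separable Gaussian --------------------------------------------------

static void blur_axis(std::vector<double>& img, int nz, int ny, int nx,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> w(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    w[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += w[i + radius];
  }
  for (double& x : w) x /= s;

  int n[3] = {nz, ny, nx};
  int len = n[axis];
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
  for (int i1 = 0; i1 < n[o1]; ++i1)
    for (int i2 = 0; i2 < n[o2]; ++i2) {
      R_xlen_t base = (R_xlen_t)i1 * stride[o1] + (R_xlen_t)i2 * stride[o2];
      for (int i = 0; i < len; ++i) line[i] = img[base + (R_xlen_t)i * stride[axis]];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int k = -radius; k <= radius; ++k) {
          int j = i + k;                       // reflect at borders
          if (j < 0) j = -j - 1;
          if (j >= len) j = 2 * len - j - 1;
          if (j < 0) j = 0; if (j >= len) j = len - 1;  // tiny arrays
          acc += w[k + radius] * line[j];
        }
        img[base + (R_xlen_t)i * stride[axis]] = acc;
      }
    }
}

// sigma_vox ordered (z, y, x), in voxels
// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector img, NumericVector sigma_vox) {
  int nz, ny, nx;
  get_dims(img, nz, ny, nx);
  std::vector<double> buf(img.begin(), img.end());
  blur_axis(buf, nz, ny, nx, 0, sigma_vox[0]);
  blur_axis(buf, nz, ny, nx, 1, sigma_vox[1]);
  blur_axis(buf, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = img.attr("dim");
  return out;
}

// ---- grey-scale morphology (flat structuring element) --------------------

// offsets: matrix with columns (dz, dy, dx); out-of-bounds neighbours are
// ignored (border treated as +inf for erosion, -inf for dilation)
// [[Rcpp::export]]
NumericVector cpp_morph3d(NumericVector img, IntegerMatrix offsets, bool dilate) {
  int nz, ny, nx;
  get_dims(img, nz, ny, nx);
  const int noff = offsets.nrow();
  NumericVector out((R_xlen_t)nz * ny * nx);
  out.attr("dim") = img.attr("dim");
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        double best = img[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)];
        for (int o = 0; o < noff; ++o) {
          int jz = iz + offsets(o, 0), jy = iy + offsets(o, 1), jx = ix + offsets(o, 2);
          if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
          double v = img[jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx)];
          if (dilate ? (v > best) : (v < best)) best = v;
        }
        out[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)] = best;
      }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) ------

// 1D squared distance transform with sample spacing s (lower envelope of
// parabolas); f holds squared distances, positions are i * s
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -R_PosInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sep <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = sep;
      z[k + 1] = R_PosInf;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// squared physical distance from every voxel to the nearest mask!=0 voxel
// [[Rcpp::export]]
NumericVector cpp_edt2(IntegerVector mask, NumericVector spacing_zyx) {
  int nz, ny, nx;
  get_dims(mask, nz, ny, nx);
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  NumericVector D(ntot);
  D.attr("dim") = mask.attr("dim");
  const double BIG = 1e30;
  for (R_xlen_t i = 0; i < ntot; ++i) D[i] = mask[i] != 0 ? 0.0 : BIG;

  int n[3] = {nz, ny, nx};
  R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  int maxn = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxn), d(maxn), z(maxn + 1);
  std::vector<int> v(maxn);
  for (int axis = 0; axis < 3; ++axis) {
    int len = n[axis];
    double s = spacing_zyx[axis];
    int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
    for (int i1 = 0; i1 < n[o1]; ++i1)
      for (int i2 = 0; i2 < n[o2]; ++i2) {
        R_xlen_t base = (R_xlen_t)i1 * stride[o1] + (R_xlen_t)i2 * stride[o2];
        for (int i = 0; i < len; ++i) f[i] = D[base + (R_xlen_t)i * stride[axis]];
        dt1d(f, d, v, z, len, s);
        for (int i = 0; i < len; ++i) D[base + (R_xlen_t)i * stride[axis]] = d[i];
      }
  }
  return D;
}

// ---- per-label statistics ------------------------------------------------

// returns voxel counts, index sums and bounding boxes (0-based indices)
// [[Rcpp::export]]
List cpp_region_stats(IntegerVector labels, int n_labels) {
  int nz, ny, nx;
  get_dims(labels, nz, ny, nx);
  NumericVector count(n_labels), sz(n_labels), sy(n_labels), sx(n_labels);
  IntegerVector z0(n_labels, nz), z1(n_labels, -1),
                y0(n_labels, ny), y1(n_labels, -1),
                x0(n_labels, nx), x1(n_labels, -1);
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        int lab = labels[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)];
        if (lab == 0) continue;
        int i = lab - 1;
        count[i] += 1; sz[i] += iz; sy[i] += iy; sx[i] += ix;
        if (iz < z0[i]) z0[i] = iz; if (iz > z1[i]) z1[i] = iz;
        if (iy < y0[i]) y0[i] = iy; if (iy > y1[i]) y1[i] = iy;
        if (ix < x0[i]) x0[i] = ix; if (ix > x1[i]) x1[i] = ix;
      }
  return List::create(_["count"] = count,
                      _["sum_z"] = sz, _["sum_y"] = sy, _["sum_x"] = sx,
                      _["z0"] = z0, _["z1"] = z1, _["y0"] = y0, _["y1"] = y1,
                      _["x0"] = x0, _["x1"] = x1);
}

// ---- iso-surface area by marching tetrahedra -----------------------------

struct P3 { double x, y, z; };

static inline P3 interp(const P3& a, const P3& b, double fa, double fb, double level) {
  double t = (level - fa) / (fb - fa);
  P3 p; p.x = a.x + t * (b.x - a.x); p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

static double g_mesh_volume;  // accumulated signed volume of current mesh

static inline void add_tri(double& area, const P3& a, const P3& b, const P3& c,
                           const P3& outward_ref) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
  area += 0.5 * std::sqrt(nx * nx + ny * ny + nz * nz);
  // orient so the normal points along outward_ref, then accumulate the
  // divergence-theorem volume contribution dot(a, b x c) / 6
  double dot = nx * outward_ref.x + ny * outward_ref.y + nz * outward_ref.z;
  const P3& b2 = dot < 0 ? c : b;
  const P3& c2 = dot < 0 ? b : c;
  g_mesh_volume += (a.x * (b2.y * c2.z - b2.z * c2.y) -
                    a.y * (b2.x * c2.z - b2.z * c2.x) +
                    a.z * (b2.x * c2.y - b2.y * c2.x)) / 6.0;
}

// spacing ordered (z, y, x) in µm; the caller pads the volume with a zero
// shell so every surface is closed. Returns the mesh area and the enclosed
// (signed, outward-oriented) volume.
// [[Rcpp::export]]
List cpp_mesh_area(NumericVector vol, double level, NumericVector spacing) {
  int nz, ny, nx;
  get_dims(vol, nz, ny, nx);
  const double vz = spacing[0], vy = spacing[1], vx = spacing[2];
  // 6-tetrahedron decomposition of the unit cube around the 0->7 diagonal;
  // corner b = dx + 2*dy + 4*dz
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };
  double area = 0;
  g_mesh_volume = 0;
  double f[8]; P3 p[8];
  for (int ix = 0; ix < nx - 1; ++ix)
    for (int iy = 0; iy < ny - 1; ++iy)
      for (int iz = 0; iz < nz - 1; ++iz) {
        bool any_in = false, any_out = false;
        for (int b = 0; b < 8; ++b) {
          int cx = b & 1, cy = (b >> 1) & 1, cz = (b >> 2) & 1;
          f[b] = vol[(iz + cz) + (R_xlen_t)nz * ((iy + cy) + (R_xlen_t)ny * (ix + cx))];
          p[b].x = (ix + cx) * vx; p[b].y = (iy + cy) * vy; p[b].z = (iz + cz) * vz;
          if (f[b] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], nin = 0, out[4], nout = 0;
          for (int v = 0; v < 4; ++v) {
            int b = tets[t][v];
            if (f[b] > level) in[nin++] = b; else out[nout++] = b;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int* others = (nin == 1) ? out : in;
            P3 q0 = interp(p[apex], p[others[0]], f[apex], f[others[0]], level);
            P3 q1 = interp(p[apex], p[others[1]], f[apex], f[others[1]], level);
            P3 q2 = interp(p[apex], p[others[2]], f[apex], f[others[2]], level);
            // outward = from the inside region toward the outside region
            P3 ref;
            if (nin == 1) {
              ref.x = (p[out[0]].x + p[out[1]].x + p[out[2]].x) / 3.0 - p[apex].x;
              ref.y = (p[out[0]].y + p[out[1]].y + p[out[2]].y) / 3.0 - p[apex].y;
              ref.z = (p[out[0]].z + p[out[1]].z + p[out[2]].z) / 3.0 - p[apex].z;
            } else {
              ref.x = p[apex].x - (p[in[0]].x + p[in[1]].x + p[in[2]].x) / 3.0;
              ref.y = p[apex].y - (p[in[0]].y + p[in[1]].y + p[in[2]].y) / 3.0;
              ref.z = p[apex].z - (p[in[0]].z + p[in[1]].z + p[in[2]].z) / 3.0;
            }
            add_tri(area, q0, q1, q2, ref);
          } else {  // 2 in / 2 out -> quad
            P3 q0 = interp(p[in[0]], p[out[0]], f[in[0]], f[out[0]], level);
            P3 q1 = interp(p[in[0]], p[out[1]], f[in[0]], f[out[1]], level);
            P3 q2 = interp(p[in[1]], p[out[1]], f[in[1]], f[out[1]], level);
            P3 q3 = interp(p[in[1]], p[out[0]], f[in[1]], f[out[0]], level);
            P3 ref;
            ref.x = (p[out[0]].x + p[out[1]].x - p[in[0]].x - p[in[1]].x) / 2.0;
            ref.y = (p[out[0]].y + p[out[1]].y - p[in[0]].y - p[in[1]].y) / 2.0;
            ref.z = (p[out[0]].z + p[out[1]].z - p[in[0]].z - p[in[1]].z) / 2.0;
            add_tri(area, q0, q1, q2, ref);
            add_tri(area, q0, q2, q3, ref);
          }
        }
      }
  return List::create(_["area"] = area, _["volume"] = g_mesh_volume);
}

// ---- k-d tree k-nearest-neighbour distances ------------------------------

struct KDTree {
  const NumericMatrix& pts;  // n x 3
  std::vector<int> idx;
  KDTree(const NumericMatrix& p) : pts(p), idx(p.nrow()) {
    for (int i = 0; i < p.nrow(); ++i) idx[i] = i;
    build(0, (int)idx.size(), 0);
  }
  void build(int lo, int hi, int axis) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    const NumericMatrix& pp = pts;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&pp, axis](int a, int b) { return pp(a, axis) < pp(b, axis); });
    build(lo, mid, (axis + 1) % 3);
    build(mid + 1, hi, (axis + 1) % 3);
  }
  void query(double qx, double qy, double qz, int skip, int k,
             std::vector<double>& heap, std::vector<int>& hidx) const {
    heap.assign(k, R_PosInf); hidx.assign(k, -1);
    search(0, (int)idx.size(), 0, qx, qy, qz, skip, k, heap, hidx);
  }
  void search(int lo, int hi, int axis, double qx, double qy, double qz,
              int skip, int k, std::vector<double>& heap, std::vector<int>& hidx) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int i = idx[mid];
    double q[3] = {qx, qy, qz};
    if (i != skip) {
      double dx = pts(i, 0) - qx, dy = pts(i, 1) - qy, dz = pts(i, 2) - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < heap[0]) {  // replace max of heap
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = d2;
        std::push_heap(heap.begin(), heap.end());
      }
    }
    double diff = q[axis] - pts(i, axis);
    int nax = (axis + 1) % 3;
    if (diff <= 0) {
      search(lo, mid, nax, qx, qy, qz, skip, k, heap, hidx);
      if (diff * diff < heap[0]) search(mid + 1, hi, nax, qx, qy, qz, skip, k, heap, hidx);
    } else {
      search(mid + 1, hi, nax, qx, qy, qz, skip, k, heap, hidx);
      if (diff * diff < heap[0]) search(lo, mid, nax, qx, qy, qz, skip, k, heap, hidx);
    }
  }
};

// distances (sorted ascending, µm) from each query point to its k nearest
// reference points; self_index (1-based into ref, 0 = none) is excluded
// [[Rcpp::export]]
NumericMatrix cpp_knn(NumericMatrix ref, NumericMatrix query,
                      IntegerVector self_index, int k) {
  KDTree tree(ref);
  NumericMatrix out(query.nrow(), k);
  std::vector<double> heap;
  std::vector<int> hidx;
  for (int i = 0; i < query.nrow(); ++i) {
    tree.query(query(i, 0), query(i, 1), query(i, 2), self_index[i] - 1, k, heap, hidx);
    std::sort(heap.begin(), heap.end());
    for (int j = 0; j < k; ++j) out(i, j) = std::sqrt(heap[j]);
  }
  return out;
}

// ---- phantom rasterisation ----------------------------------------------

// paints a rotated ellipsoid with a linear core-to-rim intensity ramp
// I(r) = imax * (floor + (1 - floor) * r);  img modified in place (max)
// center (x,y,z) µm, semi (a,b,c) µm, rot: body -> world rotation (3x3)
// [[Rcpp::export]]
void cpp_paint_ellipsoid(NumericVector img, NumericVector voxel_zyx,
                         NumericVector center_xyz, NumericVector semi,
                         NumericMatrix rot, double imax, double gradient_floor) {
  int nz, ny, nx;
  get_dims(img, nz, ny, nx);
  const double vz = voxel_zyx[0], vy = voxel_zyx[1], vx = voxel_zyx[2];
  double rmax = std::max(semi[0], std::max(semi[1], semi[2]));
  int x0 = std::max(0, (int)std::floor((center_xyz[0] - rmax) / vx - 0.5));
  int x1 = std::min(nx - 1, (int)std::ceil((center_xyz[0] + rmax) / vx - 0.5));
  int y0 = std::max(0, (int)std::floor((center_xyz[1] - rmax) / vy - 0.5));
  int y1 = std::min(ny - 1, (int)std::ceil((center_xyz[1] + rmax) / vy - 0.5));
  int z0 = std::max(0, (int)std::floor((center_xyz[2] - rmax) / vz - 0.5));
  int z1 = std::min(nz - 1, (int)std::ceil((center_xyz[2] + rmax) / vz - 0.5));
  for (int ix = x0; ix <= x1; ++ix)
    for (int iy = y0; iy <= y1; ++iy)
      for (int iz = z0; iz <= z1; ++iz) {
        double wx = (ix + 0.5) * vx - center_xyz[0];
        double wy = (iy + 0.5) * vy - center_xyz[1];
        double wz = (iz + 0.5) * vz - center_xyz[2];
        // body coords: q = R^T w
        double qx = rot(0, 0) * wx + rot(1, 0) * wy + rot(2, 0) * wz;
        double qy = rot(0, 1) * wx + rot(1, 1) * wy + rot(2, 1) * wz;
        double qz = rot(0, 2) * wx + rot(1, 2) * wy + rot(2, 2) * wz;
        double u = (qx / semi[0]) * (qx / semi[0]) +
                   (qy / semi[1]) * (qy / semi[1]) +
                   (qz / semi[2]) * (qz / semi[2]);
        if (u > 1.0) continue;
        double I = imax * (gradient_floor + (1.0 - gradient_floor) * std::sqrt(u));
        R_xlen_t v = iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
        if (I > img[v]) img[v] = I;
      }
}

// sets img to `value` inside a capsule (cylinder with spherical caps)
// [[Rcpp::export]]
void cpp_paint_capsule(NumericVector img, NumericVector voxel_zyx,
                       NumericVector p0_xyz, NumericVector p1_xyz,
                       double radius, double value) {
  int nz, ny, nx;
  get_dims(img, nz, ny, nx);
  const double vz = voxel_zyx[0], vy = voxel_zyx[1], vx = voxel_zyx[2];
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = std::min(p0_xyz[a], p1_xyz[a]) - radius;
    hi[a] = std::max(p0_xyz[a], p1_xyz[a]) + radius;
  }
  int x0 = std::max(0, (int)std::floor(lo[0] / vx - 0.5));
  int x1 = std::min(nx - 1, (int)std::ceil(hi[0] / vx - 0.5));
  int y0 = std::max(0, (int)std::floor(lo[1] / vy - 0.5));
  int y1 = std::min(ny - 1, (int)std::ceil(hi[1] / vy - 0.5));
  int z0 = std::max(0, (int)std::floor(lo[2] / vz - 0.5));
  int z1 = std::min(nz - 1, (int)std::ceil(hi[2] / vz - 0.5));
  double ax = p1_xyz[0] - p0_xyz[0], ay = p1_xyz[1] - p0_xyz[1], az = p1_xyz[2] - p0_xyz[2];
  double len2 = ax * ax + ay * ay + az * az;
  for (int ix = x0; ix <= x1; ++ix)
    for (int iy = y0; iy <= y1; ++iy)
      for (int iz = z0; iz <= z1; ++iz) {
        double px = (ix + 0.5) * vx - p0_xyz[0];
        double py = (iy + 0.5) * vy - p0_xyz[1];
        double pz = (iz + 0.5) * vz - p0_xyz[2];
        double t = len2 > 0 ? (px * ax + py * ay + pz * az) / len2 : 0.0;
        t = std::min(1.0, std::max(0.0, t));
        double dx = px - t * ax, dy = py - t * ay, dz = pz - t * az;
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          img[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)] = value;
      }
}
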