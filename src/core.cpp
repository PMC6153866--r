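#include <Rcpp.h>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parallel-beam, stack-of-slices projector pair.
//
// Image grid: (nx, ny, nz), voxel centres at ((i - (nx-1)/2) * vox, ...) in mm,
// i.e. the projection geometry is always centred on the grid.
// Sinogram: (na, nr, nz); radial bin centres at (k - (nr-1)/2) * bin mm.
// Each voxel splats its value into the two radial bins nearest its signed
// distance r = x cos(theta) + y sin(theta), with linear interpolation weights.
// The back-projector is the exact algebraic transpose, which is what the
// EM updates and the adjoint-based fits require.

// [[Rcpp::export]]
NumericVector cpp_ray_forward(NumericVector img, IntegerVector dims,
                              NumericVector angles, int nrad,
                              double vox, double bin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles.size(), nr = nrad;
  NumericVector out(static_cast<R_xlen_t>(na) * nr * nz);
  out.attr("dim") = IntegerVector::create(na, nr, nz);
  std::vector<double> ca(na), sa(na);
  for (int a = 0; a < na; ++a) { ca[a] = std::cos(angles[a]); sa[a] = std::sin(angles[a]); }
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cr = 0.5 * (nr - 1);
  for (int z = 0; z < nz; ++z) {
    const double *ip = &img[static_cast<R_xlen_t>(z) * nx * ny];
    double *op = &out[static_cast<R_xlen_t>(z) * na * nr];
    for (int a = 0; a < na; ++a) {
      const double c = ca[a] * vox / bin, s = sa[a] * vox / bin;
      for (int j = 0; j < ny; ++j) {
        const double yc = (j - cy) * s;
        const double *row = ip + static_cast<R_xlen_t>(j) * nx;
        for (int i = 0; i < nx; ++i) {
          const double v = row[i];
          if (v == 0.0) continue;
          const double k = (i - cx) * c + yc + cr;
          const int k0 = static_cast<int>(std::floor(k));
          const double w1 = k - k0;
          if (k0 >= 0 && k0 < nr)      op[a + static_cast<R_xlen_t>(na) * k0]       += v * (1.0 - w1);
          if (k0 + 1 >= 0 && k0 + 1 < nr) op[a + static_cast<R_xlen_t>(na) * (k0 + 1)] += v * w1;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ray_back(NumericVector sino, IntegerVector sdims,
                           NumericVector angles, IntegerVector dims,
                           double vox, double bin) {
  const int na = sdims[0], nr = sdims[1], nz = sdims[2];
  const int nx = dims[0], ny = dims[1];
  if (dims[2] != nz) stop("slice count mismatch");
  if (angles.size() != na) stop("angle count mismatch");
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  out.attr("dim") = dims;
  std::vector<double> ca(na), sa(na);
  for (int a = 0; a < na; ++a) { ca[a] = std::cos(angles[a]); sa[a] = std::sin(angles[a]); }
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cr = 0.5 * (nr - 1);
  for (int z = 0; z < nz; ++z) {
    const double *sp = &sino[static_cast<R_xlen_t>(z) * na * nr];
    double *op = &out[static_cast<R_xlen_t>(z) * nx * ny];
    for (int a = 0; a < na; ++a) {
      const double c = ca[a] * vox / bin, s = sa[a] * vox / bin;
      for (int j = 0; j < ny; ++j) {
        const double yc = (j - cy) * s;
        double *row = op + static_cast<R_xlen_t>(j) * nx;
        for (int i = 0; i < nx; ++i) {
          const double k = (i - cx) * c + yc + cr;
          const int k0 = static_cast<int>(std::floor(k));
          const double w1 = k - k0;
          double acc = 0.0;
          if (k0 >= 0 && k0 < nr)         acc += sp[a + static_cast<R_xlen_t>(na) * k0] * (1.0 - w1);
          if (k0 + 1 >= 0 && k0 + 1 < nr) acc += sp[a + static_cast<R_xlen_t>(na) * (k0 + 1)] * w1;
          row[i] += acc;
        }
      }
    }
  }
  return out;
}

static void blur_axis(std::vector<double> &buf, NumericVector &img,
                      int n0, int n1, int n2, int axis, double sigma) {
  // blur along `axis` of a (n0, n1, n2) array with a normalised truncated
  // Gaussian, zero padding outside the grid (self-adjoint by symmetry)
  if (sigma <= 0.0) return;
  const int rad = std::max(1, static_cast<int>(std::ceil(3.5 * sigma)));
  std::vector<double> ker(2 * rad + 1);
  double ksum = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += ker[t + rad];
  }
  for (double &w : ker) w /= ksum;
  const int len = (axis == 0) ? n0 : (axis == 1) ? n1 : n2;
  const R_xlen_t stride = (axis == 0) ? 1 :
    (axis == 1) ? static_cast<R_xlen_t>(n0) : static_cast<R_xlen_t>(n0) * n1;
  const R_xlen_t ntot = static_cast<R_xlen_t>(n0) * n1 * n2;
  const R_xlen_t nlines = ntot / len;
  std::vector<double> line(len);
  for (R_xlen_t l = 0; l < nlines; ++l) {
    // compute base index of line l along the axis
    R_xlen_t base;
    if (axis == 0) base = l * n0;
    else if (axis == 1) { R_xlen_t plane = l / n0, rem = l % n0; base = plane * static_cast<R_xlen_t>(n0) * n1 + rem; }
    else base = l;
    for (int t = 0; t < len; ++t) line[t] = img[base + stride * t];
    for (int t = 0; t < len; ++t) {
      double acc = 0.0;
      const int lo = std::max(0, t - rad), hi = std::min(len - 1, t + rad);
      for (int u = lo; u <= hi; ++u) acc += line[u] * ker[u - t + rad];
      img[base + stride * t] = acc;
    }
  }
  (void)buf;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector img, IntegerVector dims,
                              NumericVector sigma_vox) {
  NumericVector out = clone(img);
  out.attr("dim") = dims;
  std::vector<double> buf;
  blur_axis(buf, out, dims[0], dims[1], dims[2], 0, sigma_vox[0]);
  blur_axis(buf, out, dims[0], dims[1], dims[2], 1, sigma_vox[1]);
  blur_axis(buf, out, dims[0], dims[1], dims[2], 2, sigma_vox[2]);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<std::array<int,3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / (static_cast<R_xlen_t>(nx) * ny);
      for (const auto &d : nb) {
        const int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t q = xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate_mask(LogicalVector mask, IntegerVector dims,
                              IntegerMatrix offsets) {
  // binary dilation by an arbitrary structuring element given as an
  // n x 3 matrix of voxel offsets (must include (0,0,0) to be extensive)
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  LogicalVector out(n);
  out.attr("dim") = dims;
  const int no = offsets.nrow();
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    const int x = s % nx, y = (s / nx) % ny, z = s / (static_cast<R_xlen_t>(nx) * ny);
    for (int o = 0; o < no; ++o) {
      const int xx = x + offsets(o, 0), yy = y + offsets(o, 1), zz = z + offsets(o, 2);
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      out[xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz)] = true;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sphere_occupancy(IntegerVector dims, NumericVector vox,
                                   NumericVector origin, NumericVector center,
                                   double diameter, int nsub) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  out.attr("dim") = dims;
  const double R = 0.5 * diameter, R2 = R * R;
  const double hx = 0.5 * vox[0], hy = 0.5 * vox[1], hz = 0.5 * vox[2];
  const double hd = std::sqrt(hx * hx + hy * hy + hz * hz); // half-diagonal
  // voxel index bounds of the bounding box
  int i0 = std::max(0, static_cast<int>(std::floor((center[0] - R - origin[0]) / vox[0])) - 1);
  int i1 = std::min(nx - 1, static_cast<int>(std::ceil((center[0] + R - origin[0]) / vox[0])) + 1);
  int j0 = std::max(0, static_cast<int>(std::floor((center[1] - R - origin[1]) / vox[1])) - 1);
  int j1 = std::min(ny - 1, static_cast<int>(std::ceil((center[1] + R - origin[1]) / vox[1])) + 1);
  int k0 = std::max(0, static_cast<int>(std::floor((center[2] - R - origin[2]) / vox[2])) - 1);
  int k1 = std::min(nz - 1, static_cast<int>(std::ceil((center[2] + R - origin[2]) / vox[2])) + 1);
  const double step = 1.0 / nsub;
  for (int k = k0; k <= k1; ++k) {
    const double zc = origin[2] + k * vox[2] - center[2];
    for (int j = j0; j <= j1; ++j) {
      const double yc = origin[1] + j * vox[1] - center[1];
      for (int i = i0; i <= i1; ++i) {
        const double xc = origin[0] + i * vox[0] - center[0];
        const double d = std::sqrt(xc * xc + yc * yc + zc * zc);
        double occ;
        if (d + hd <= R) occ = 1.0;               // voxel fully inside
        else if (d - hd >= R) occ = 0.0;          // fully outside
        else {
          int cnt = 0;
          for (int sz = 0; sz < nsub; ++sz) {
            const double pz = zc + ((sz + 0.5) * step - 0.5) * vox[2];
            for (int sy = 0; sy < nsub; ++sy) {
              const double py = yc + ((sy + 0.5) * step - 0.5) * vox[1];
              for (int sx = 0; sx < nsub; ++sx) {
                const double px = xc + ((sx + 0.5) * step - 0.5) * vox[0];
                if (px * px + py * py + pz * pz <= R2) ++cnt;
              }
            }
          }
          occ = static_cast<double>(cnt) / (static_cast<double>(nsub) * nsub * nsub);
        }
        if (occ > 0.0)
          out[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] = occ;
      }
    }
  }
  return out;
}
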