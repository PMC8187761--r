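// Low-level voxel kernels shared by the segmentation, metrics and cortical
// mapping code. All arrays are column-major with dim = (nx, ny, nz) and
// linear index x + nx*(y + ny*z); world coordinate of voxel centre (i,j,k)
// is (i*sx, j*sy, k*sz) mm, 0-based.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 6- or 26-connected component labelling by BFS. Labels are 1..K in
// decreasing order is NOT guaranteed; use cpp_component_sizes to rank.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity = 6) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int c = stack.back(); stack.pop_back();
          int cz = c / (nx * ny), rem = c % (nx * ny);
          int cy = rem / nx, cx = rem % nx;
          for (auto &o : offs) {
            int ux = cx + o[0], uy = cy + o[1], uz = cz + o[2];
            if (ux < 0 || uy < 0 || uz < 0 || ux >= nx || uy >= ny || uz >= nz)
              continue;
            int u = idx3(ux, uy, uz, nx, ny);
            if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
          }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}

// Fill 2D holes slice by slice (axis 3): background connected to the slice
// border stays background, enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_slices(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> outside(nx * ny);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    const int base = nx * ny * z;
    for (int x = 0; x < nx; ++x) {
      for (int y : {0, ny - 1}) {
        int i = x + nx * y;
        if (!mask[base + i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
    }
    for (int y = 0; y < ny; ++y) {
      for (int x : {0, nx - 1}) {
        int i = x + nx * y;
        if (!mask[base + i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
    }
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cy = c / nx, cx = c % nx;
      const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int ux = cx + dx[k], uy = cy + dy[k];
        if (ux < 0 || uy < 0 || ux >= nx || uy >= ny) continue;
        int u = ux + nx * uy;
        if (!mask[base + u] && !outside[u]) { outside[u] = 1; stack.push_back(u); }
      }
    }
    for (int i = 0; i < nx * ny; ++i)
      if (!mask[base + i] && !outside[i]) out[base + i] = true;
  }
  return out;
}

// separable box-filter sum over a cube of half-width r, zero padding
// [[Rcpp::export]]
NumericVector cpp_box3_sum(NumericVector a, IntegerVector dim, int r) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<double> buf(std::max(nx, std::max(ny, nz)) + 1);
  NumericVector out = clone(a);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double s = 0;
      buf[0] = 0;
      for (int x = 0; x < nx; ++x) {
        s += out[idx3(x, y, z, nx, ny)];
        buf[x + 1] = s;
      }
      for (int x = 0; x < nx; ++x) {
        int hi = std::min(x + r + 1, nx), lo = std::max(x - r, 0);
        out[idx3(x, y, z, nx, ny)] = buf[hi] - buf[lo];
      }
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      double s = 0;
      buf[0] = 0;
      for (int y = 0; y < ny; ++y) {
        s += out[idx3(x, y, z, nx, ny)];
        buf[y + 1] = s;
      }
      for (int y = 0; y < ny; ++y) {
        int hi = std::min(y + r + 1, ny), lo = std::max(y - r, 0);
        out[idx3(x, y, z, nx, ny)] = buf[hi] - buf[lo];
      }
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double s = 0;
      buf[0] = 0;
      for (int z = 0; z < nz; ++z) {
        s += out[idx3(x, y, z, nx, ny)];
        buf[z + 1] = s;
      }
      for (int z = 0; z < nz; ++z) {
        int hi = std::min(z + r + 1, nz), lo = std::max(z - r, 0);
        out[idx3(x, y, z, nx, ny)] = buf[hi] - buf[lo];
      }
    }
  (void)n;
  return out;
}

// 1D squared-distance transform (lower envelope of parabolas), Felzenszwalb
// & Huttenlocher. f in units of squared physical distance, sample step h.
static void dt1d(const double *f, double *d, int n, double h,
                 std::vector<int> &v, std::vector<double> &zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -INFINITY;
  zbuf[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INFINITY) continue;
    if (f[v[0]] == INFINITY) { k = 0; v[0] = q; zbuf[0] = -INFINITY; zbuf[1] = INFINITY; continue; }
    double s;
    while (true) {
      double qq = q * h, vv = v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INFINITY) { d[q] = INFINITY; continue; }
    while (zbuf[k + 1] < q * h) ++k;
    double diff = q * h - v[k] * h;
    d[q] = diff * diff + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance (mm) from each foreground
// voxel centre to the nearest background voxel centre; 0 on background.
// If no background exists, all distances are +Inf.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = fg[i] ? INFINITY : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zbuf(nmax + 1);
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(x, y, z, nx, ny)];
      dt1d(f.data(), d.data(), nx, spacing[0], v, zbuf);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(f.data(), d.data(), ny, spacing[1], v, zbuf);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(f.data(), d.data(), nz, spacing[2], v, zbuf);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = d[z];
    }
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Local thickness (Hildebrand & Rüegsegger): at each foreground voxel, the
// diameter (mm) of the largest inscribed sphere that covers it. Sphere
// painting from distance-ridge voxels; a voxel is skipped when its sphere is
// contained in a 26-neighbour's sphere.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector fg, IntegerVector dim,
                                  NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector edt = cpp_edt3d(fg, dim, spacing);
  NumericVector out(n, 0.0);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // collect ridge voxels
  std::vector<int> ridge;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!fg[i]) continue;
        double r = edt[i];
        bool dominated = false;
        for (int dz = -1; dz <= 1 && !dominated; ++dz)
          for (int dy = -1; dy <= 1 && !dominated; ++dy)
            for (int dx = -1; dx <= 1 && !dominated; ++dx) {
              if (!dx && !dy && !dz) continue;
              int ux = x + dx, uy = y + dy, uz = z + dz;
              if (ux < 0 || uy < 0 || uz < 0 || ux >= nx || uy >= ny || uz >= nz)
                continue;
              int u = idx3(ux, uy, uz, nx, ny);
              if (!fg[u]) continue;
              double dd = std::sqrt(dx * dx * sx * sx + dy * dy * sy * sy +
                                    dz * dz * sz * sz);
              if (edt[u] >= r + dd - 1e-12) dominated = true;
            }
        if (!dominated) ridge.push_back(i);
      }
  // paint spheres, largest first
  std::sort(ridge.begin(), ridge.end(), [&](int a, int b) {
    return edt[a] > edt[b];
  });
  for (int i : ridge) {
    double r = edt[i];
    if (r <= 0) continue;
    int z = i / (nx * ny), rem = i % (nx * ny);
    int y = rem / nx, x = rem % nx;
    int rx = (int)std::floor(r / sx), ry = (int)std::floor(r / sy),
        rz = (int)std::floor(r / sz);
    double diam = 2.0 * r;
    for (int dz = -rz; dz <= rz; ++dz) {
      int uz = z + dz;
      if (uz < 0 || uz >= nz) continue;
      for (int dy = -ry; dy <= ry; ++dy) {
        int uy = y + dy;
        if (uy < 0 || uy >= ny) continue;
        for (int dx = -rx; dx <= rx; ++dx) {
          int ux = x + dx;
          if (ux < 0 || ux >= nx) continue;
          double dd = dx * dx * sx * sx + dy * dy * sy * sy + dz * dz * sz * sz;
          if (dd > r * r) continue;
          int u = idx3(ux, uy, uz, nx, ny);
          if (fg[u] && out[u] < diam) out[u] = diam;
        }
      }
    }
  }
  return out;
}

// Laplace solver on a voxel domain with Dirichlet bands: potential fixed to
// 0 on band0, 1 on band1, harmonic (6-neighbour average) on the remaining
// domain voxels. SOR iteration; convergence when the maximum absolute
// update relative to the field range (1) is below tol.
// [[Rcpp::export]]
List cpp_laplace(LogicalVector domain, LogicalVector band0, LogicalVector band1,
                 IntegerVector dim, double tol = 1e-6, int max_iter = 5000,
                 double omega = 1.9) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector phi(n, NA_REAL);
  std::vector<int> free_idx;
  for (int i = 0; i < n; ++i) {
    if (band0[i]) phi[i] = 0.0;
    else if (band1[i]) phi[i] = 1.0;
    else if (domain[i]) { phi[i] = 0.5; free_idx.push_back(i); }
  }
  const int nxy = nx * ny;
  int it = 0;
  double delta = INFINITY;
  for (it = 0; it < max_iter && delta > tol; ++it) {
    delta = 0.0;
    for (int i : free_idx) {
      int z = i / nxy, rem = i % nxy, y = rem / nx, x = rem % nx;
      double s = 0.0;
      int cnt = 0;
      if (x > 0 && !ISNA(phi[i - 1]))      { s += phi[i - 1];   ++cnt; }
      if (x < nx-1 && !ISNA(phi[i + 1]))   { s += phi[i + 1];   ++cnt; }
      if (y > 0 && !ISNA(phi[i - nx]))     { s += phi[i - nx];  ++cnt; }
      if (y < ny-1 && !ISNA(phi[i + nx]))  { s += phi[i + nx];  ++cnt; }
      if (z > 0 && !ISNA(phi[i - nxy]))    { s += phi[i - nxy]; ++cnt; }
      if (z < nz-1 && !ISNA(phi[i + nxy])) { s += phi[i + nxy]; ++cnt; }
      if (cnt == 0) continue;
      double upd = s / cnt;
      double newv = phi[i] + omega * (upd - phi[i]);
      if (newv < 0) newv = 0;
      if (newv > 1) newv = 1;
      double ch = std::fabs(newv - phi[i]);
      if (ch > delta) delta = ch;
      phi[i] = newv;
    }
  }
  return List::create(_["potential"] = phi, _["iterations"] = it,
                      _["converged"] = delta <= tol, _["delta"] = delta);
}

static inline double trilin(const double *a, int nx, int ny, int nz,
                            double x, double y, double z, bool &ok) {
  // x,y,z in voxel units (0-based); NA treated as missing -> ok=false
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    ok = false; return NA_REAL;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) --x0;
  if (y0 == ny - 1) --y0;
  if (z0 == nz - 1) --z0;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double v = 0.0;
  ok = true;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        int xi = std::min(x0 + dx, nx - 1), yi = std::min(y0 + dy, ny - 1),
            zi = std::min(z0 + dz, nz - 1);
        double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
        double val = a[idx3(xi, yi, zi, nx, ny)];
        if (ISNAN(val)) { if (w > 1e-12) { ok = false; return NA_REAL; } else val = 0.0; }
        v += w * val;
      }
  return v;
}

// Trilinear sampling of a 3D array at voxel-unit coordinates (0-based).
// Out-of-grid or NA-neighbourhood samples return `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dim,
                            NumericMatrix coords, double fill = NA_REAL) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = coords.nrow();
  NumericVector out(m);
  const double *a = arr.begin();
  for (int i = 0; i < m; ++i) {
    bool ok;
    double v = trilin(a, nx, ny, nz, coords(i, 0), coords(i, 1), coords(i, 2), ok);
    out[i] = ok ? v : fill;
  }
  return out;
}

// Streamline tracing through a potential field phi in [0,1] (0 periosteal,
// 1 endosteal, NA outside an extended cortical domain). Seeds are world
// coordinates (mm); integration is explicit Euler on the normalised
// gradient with step `step_mm`. Termination: if `indicator` is non-empty
// (a smoothed cortical-mask field whose 0.5 level is the surface), the
// trace stops at the sub-step 0.5 downcrossing of the indicator once past
// mid-potential; otherwise at potential phi_stop, with the last step
// shortened proportionally. Returns per seed the arc length, a success
// flag, and the sampled polyline.
// [[Rcpp::export]]
List cpp_trace_streamlines(NumericVector phi, IntegerVector dim,
                           NumericVector spacing, NumericMatrix seeds,
                           double step_mm, double max_len,
                           double phi_stop = 0.995,
                           Nullable<NumericVector> indicator = R_NilValue) {
  bool use_ind = indicator.isNotNull();
  NumericVector ind_;
  const double *indp = nullptr;
  if (use_ind) {
    ind_ = indicator.get();
    indp = ind_.begin();
  }
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ns = seeds.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double *a = phi.begin();
  NumericVector arclen(ns, NA_REAL);
  LogicalVector okflag(ns, false);
  List lines(ns);
  const double h = 0.25; // voxel fraction for gradient finite differences
  for (int s = 0; s < ns; ++s) {
    double px = seeds(s, 0) / sx, py = seeds(s, 1) / sy, pz = seeds(s, 2) / sz;
    std::vector<double> pts;
    bool ok;
    double pv = trilin(a, nx, ny, nz, px, py, pz, ok);
    if (!ok) {
      // nudge: seeds sit on the (smoothed) periosteal surface, which can be
      // half a voxel outside the field; walk inward along +gradient of a
      // blurred field is not available here, so scan a small neighbourhood.
      bool found = false;
      for (double r = 0.25; r <= 2.0 && !found; r += 0.25)
        for (int dz = -1; dz <= 1 && !found; ++dz)
          for (int dy = -1; dy <= 1 && !found; ++dy)
            for (int dx = -1; dx <= 1 && !found; ++dx) {
              double qx = px + r * dx, qy = py + r * dy, qz = pz + r * dz;
              double qv = trilin(a, nx, ny, nz, qx, qy, qz, ok);
              if (ok) { px = qx; py = qy; pz = qz; pv = qv; found = true; }
            }
      if (!found) continue;
    }
    double len = 0.0;
    pts.push_back(px * sx); pts.push_back(py * sy); pts.push_back(pz * sz);
    bool success = false;
    int max_steps = (int)std::ceil(max_len / step_mm) + 4;
    for (int it = 0; it < max_steps; ++it) {
      // gradient in world units
      bool o1, o2;
      double gx = (trilin(a, nx, ny, nz, px + h, py, pz, o1) -
                   trilin(a, nx, ny, nz, px - h, py, pz, o2)) / (2 * h * sx);
      if (!o1 || !o2) gx = NA_REAL;
      double gy = (trilin(a, nx, ny, nz, px, py + h, pz, o1) -
                   trilin(a, nx, ny, nz, px, py - h, pz, o2)) / (2 * h * sy);
      if (!o1 || !o2) gy = NA_REAL;
      double gz = (trilin(a, nx, ny, nz, px, py, pz + h, o1) -
                   trilin(a, nx, ny, nz, px, py, pz - h, o2)) / (2 * h * sz);
      if (!o1 || !o2) gz = NA_REAL;
      if (ISNAN(gx)) gx = 0;
      if (ISNAN(gy)) gy = 0;
      if (ISNAN(gz)) gz = 0;
      double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (gn < 1e-10) break;
      double qx = px + step_mm * gx / (gn * sx);
      double qy = py + step_mm * gy / (gn * sy);
      double qz = pz + step_mm * gz / (gn * sz);
      double qv = trilin(a, nx, ny, nz, qx, qy, qz, ok);
      if (!ok) {
        // stepping out of the field on the endosteal side counts as arrival
        if (pv >= 0.5) { success = true; }
        break;
      }
      if (use_ind && qv >= 0.5) {
        bool oi1, oi2;
        double ip = trilin(indp, nx, ny, nz, px, py, pz, oi1);
        double iq = trilin(indp, nx, ny, nz, qx, qy, qz, oi2);
        if (oi1 && oi2 && ip >= 0.5 && iq < 0.5) {
          double frac = (ip - 0.5) / (ip - iq);
          if (frac < 0) frac = 0;
          if (frac > 1) frac = 1;
          px += frac * (qx - px); py += frac * (qy - py);
          pz += frac * (qz - pz);
          len += frac * step_mm;
          pts.push_back(px * sx); pts.push_back(py * sy);
          pts.push_back(pz * sz);
          success = true;
          break;
        }
      }
      if (qv >= phi_stop) {
        double frac = (qv > pv) ? (phi_stop - pv) / (qv - pv) : 1.0;
        if (frac < 0) frac = 0;
        if (frac > 1) frac = 1;
        px += frac * (qx - px); py += frac * (qy - py); pz += frac * (qz - pz);
        len += frac * step_mm;
        pts.push_back(px * sx); pts.push_back(py * sy); pts.push_back(pz * sz);
        success = true;
        break;
      }
      px = qx; py = qy; pz = qz; pv = qv;
      len += step_mm;
      pts.push_back(px * sx); pts.push_back(py * sy); pts.push_back(pz * sz);
      if (len > max_len) break;
    }
    if (success) {
      arclen[s] = len;
      okflag[s] = true;
    }
    NumericMatrix pm(pts.size() / 3, 3);
    for (size_t r = 0; r < pts.size() / 3; ++r) {
      pm(r, 0) = pts[3 * r]; pm(r, 1) = pts[3 * r + 1]; pm(r, 2) = pts[3 * r + 2];
    }
    lines[s] = pm;
  }
  return List::create(_["arc_length"] = arclen, _["ok"] = okflag,
                      _["points"] = lines);
}
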