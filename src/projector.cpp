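#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Geometry convention (all mm): right-handed, isocenter at origin, source
// rotates counter-clockwise viewed from +z. At view angle b the source sits
// at sad*(cos b, sin b, 0); the detector is a flat panel at distance sdd
// from the source, perpendicular to the central ray, with in-plane axis
// e_u = (-sin b, cos b, 0) and axial axis e_v = (0, 0, 1). det_off_{u,v}
// shift the detector center away from the central ray (offset detector /
// half-cone layouts). Voxel (i,j,k) center = origin + (i,j,k)*voxel.

static inline double trilin(const double *vol, int nx, int ny, int nz,
                            double gx, double gy, double gz) {
  // gx,gy,gz in voxel-center coordinates; outside samples read as 0
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    int k = k0 + dk;
    if (k < 0 || k >= nz) continue;
    double wk = dk ? fz : 1.0 - fz;
    for (int dj = 0; dj < 2; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      double wj = dj ? fy : 1.0 - fy;
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        double wi = di ? fx : 1.0 - fx;
        acc += wi * wj * wk * vol[i + (size_t)nx * (j + (size_t)ny * k)];
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector vdim,
                                  NumericVector voxel, NumericVector origin,
                                  double sad, double sdd,
                                  int det_rows, int det_cols, double pitch,
                                  double off_v, double off_u,
                                  NumericVector angles_rad, double step_mm) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int nv = angles_rad.size();
  const double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  // grid bounding box (outer faces of edge voxels)
  const double bx0 = ox - 0.5 * vx, bx1 = ox + (nx - 0.5) * vx;
  const double by0 = oy - 0.5 * vy, by1 = oy + (ny - 0.5) * vy;
  const double bz0 = oz - 0.5 * vz, bz1 = oz + (nz - 0.5) * vz;
  NumericVector out((size_t)det_rows * det_cols * nv);
  const double *v = vol.begin();
  double *o = out.begin();

  for (int a = 0; a < nv; ++a) {
    double cb = std::cos(angles_rad[a]), sb = std::sin(angles_rad[a]);
    double sx = sad * cb, sy = sad * sb, sz = 0.0;
    // detector center
    double dcx = -(sdd - sad) * cb + off_u * (-sb);
    double dcy = -(sdd - sad) * sb + off_u * (cb);
    double dcz = off_v;
    for (int c = 0; c < det_cols; ++c) {
      double uu = (c - 0.5 * (det_cols - 1)) * pitch;
      double px = dcx + uu * (-sb), py = dcy + uu * cb;
      for (int r = 0; r < det_rows; ++r) {
        double pz = dcz + (r - 0.5 * (det_rows - 1)) * pitch;
        double dx = px - sx, dy = py - sy, dz = pz - sz;
        double len = std::sqrt(dx * dx + dy * dy + dz * dz);
        dx /= len; dy /= len; dz /= len;
        // slab intersection with the bounding box
        double t0 = 0.0, t1 = len;
        bool miss = false;
        const double lo[3] = {bx0, by0, bz0}, hi[3] = {bx1, by1, bz1};
        const double sp[3] = {sx, sy, sz}, dir[3] = {dx, dy, dz};
        for (int ax = 0; ax < 3; ++ax) {
          if (std::fabs(dir[ax]) < 1e-12) {
            if (sp[ax] < lo[ax] || sp[ax] > hi[ax]) { miss = true; break; }
          } else {
            double ta = (lo[ax] - sp[ax]) / dir[ax];
            double tb = (hi[ax] - sp[ax]) / dir[ax];
            if (ta > tb) std::swap(ta, tb);
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
            if (t0 >= t1) { miss = true; break; }
          }
        }
        size_t idx = r + (size_t)det_rows * (c + (size_t)det_cols * a);
        if (miss) { o[idx] = 0.0; continue; }
        int nstep = (int)std::ceil((t1 - t0) / step_mm);
        if (nstep < 1) nstep = 1;
        double ds = (t1 - t0) / nstep;
        double acc = 0.0;
        for (int s = 0; s < nstep; ++s) {
          double t = t0 + (s + 0.5) * ds;
          double gx = (sx + t * dx - ox) / vx;
          double gy = (sy + t * dy - oy) / vy;
          double gz = (sz + t * dz - oz) / vz;
          acc += trilin(v, nx, ny, nz, gx, gy, gz);
        }
        o[idx] = acc * ds;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(det_rows, det_cols, nv);
  return out;
}

// weight_mode: 0 = FDK (sad^2/U^2, for filtered backprojection; caller
// multiplies by the angular step), 1 = plain average-style weights,
// 2 = approximate adjoint of the ray-driven projector:
//     (sdd/U)^2/pitch^2 * step weighting is applied by the caller.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector proj, IntegerVector pdim,
                              NumericVector voxel, NumericVector origin,
                              IntegerVector vdim,
                              double sad, double sdd, double pitch,
                              double off_v, double off_u,
                              NumericVector angles_rad, int weight_mode) {
  const int det_rows = pdim[0], det_cols = pdim[1];
  const int nv = angles_rad.size();
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  NumericVector out((size_t)nx * ny * nz);
  double *ov = out.begin();
  const double *p = proj.begin();

  std::vector<double> cbv(nv), sbv(nv);
  for (int a = 0; a < nv; ++a) { cbv[a] = std::cos(angles_rad[a]); sbv[a] = std::sin(angles_rad[a]); }

  for (int a = 0; a < nv; ++a) {
    const double cb = cbv[a], sb = sbv[a];
    const double *pv = p + (size_t)det_rows * det_cols * a;
    for (int k = 0; k < nz; ++k) {
      double z = oz + k * vz;
      for (int j = 0; j < ny; ++j) {
        double y = oy + j * vy;
        for (int i = 0; i < nx; ++i) {
          double x = ox + i * vx;
          double U = sad - x * cb - y * sb;           // distance along central ray
          if (U < 1e-6) continue;
          double t = (-x * sb + y * cb);              // transverse coordinate
          double u = sdd * t / U - off_u;             // detector u of the voxel
          double vcoord = sdd * z / U - off_v;
          double ci = u / pitch + 0.5 * (det_cols - 1);
          double ri = vcoord / pitch + 0.5 * (det_rows - 1);
          int c0 = (int)std::floor(ci), r0 = (int)std::floor(ri);
          if (c0 < -1 || c0 > det_cols - 1 || r0 < -1 || r0 > det_rows - 1) continue;
          double fc = ci - c0, fr = ri - r0;
          double val = 0.0;
          for (int dc = 0; dc < 2; ++dc) {
            int c = c0 + dc;
            if (c < 0 || c >= det_cols) continue;
            double wc = dc ? fc : 1.0 - fc;
            for (int dr = 0; dr < 2; ++dr) {
              int r = r0 + dr;
              if (r < 0 || r >= det_rows) continue;
              double wr = dr ? fr : 1.0 - fr;
              val += wc * wr * pv[r + (size_t)det_rows * c];
            }
          }
          double w = 1.0;
          if (weight_mode == 0) w = (sad * sad) / (U * U);
          else if (weight_mode == 2) w = (sdd * sdd) / (U * U);
          ov[i + (size_t)nx * (j + (size_t)ny * k)] += w * val;
        }
      }
    }
  }
  out.attr("dim") = vdim;
  return out;
}

// Total-variation style in-painting: nonlinear Gauss-Seidel over the masked
// voxels only, with edge-stopping weights 1/sqrt(diff^2 + eps^2) between
// 6-neighbors. Unmasked voxels are never touched. Works for 2-D inputs by
// passing nz = 1.
// [[Rcpp::export]]
NumericVector cpp_inpaint_tv(NumericVector values, IntegerVector vdim,
                             LogicalVector mask, int n_sweeps, double eps) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  NumericVector out = clone(values);
  double *v = out.begin();
  std::vector<size_t> idx;
  std::vector<int> ic, jc, kc;
  double init = 0.0; size_t nfree = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + (size_t)nx * (j + (size_t)ny * k);
        if (mask[id]) { idx.push_back(id); ic.push_back(i); jc.push_back(j); kc.push_back(k); }
        else { init += v[id]; ++nfree; }
      }
  if (idx.empty()) return out;
  init = nfree ? init / nfree : 0.0;
  for (size_t m = 0; m < idx.size(); ++m) v[idx[m]] = init;

  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (size_t m = 0; m < idx.size(); ++m) {
      double num = 0.0, den = 0.0, vc = v[idx[m]];
      for (int n = 0; n < 6; ++n) {
        int i = ic[m] + di[n], j = jc[m] + dj[n], k = kc[m] + dk[n];
        if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
        double vn = v[i + (size_t)nx * (j + (size_t)ny * k)];
        double w = 1.0 / std::sqrt((vc - vn) * (vc - vn) + eps * eps);
        num += w * vn; den += w;
      }
      if (den > 0) v[idx[m]] = num / den;
    }
  }
  out.attr("dim") = vdim;
  return out;
}

// 6-connected component labelling of a logical volume (iterative BFS).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector vdim) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  IntegerVector lab((size_t)nx * ny * nz);
  int cur = 0;
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  std::vector<size_t> stack;
  for (size_t s = 0; s < (size_t)lab.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t id = stack.back(); stack.pop_back();
      int i = id % nx, j = (id / nx) % ny, k = id / ((size_t)nx * ny);
      for (int n = 0; n < 6; ++n) {
        int ii = i + di[n], jj = j + dj[n], kk = k + dk[n];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        size_t nid = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[nid] && !lab[nid]) { lab[nid] = cur; stack.push_back(nid); }
      }
    }
  }
  lab.attr("dim") = vdim;
  return lab;
}
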