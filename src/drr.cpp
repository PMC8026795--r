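#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear interpolation at continuous index (ix, iy, iz); out-of-grid -> 0.
static inline double trilerp(const double *v, int nx, int ny, int nz,
                             double ix, double iy, double iz) {
  if (ix < 0.0 || iy < 0.0 || iz < 0.0 ||
      ix > nx - 1.0 || iy > ny - 1.0 || iz > nz - 1.0) return 0.0;
  int x0 = (int)ix, y0 = (int)iy, z0 = (int)iz;
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = ix - x0, fy = iy - y0, fz = iz - z0;
  const double *p = v + (size_t)z0 * nx * ny + (size_t)y0 * nx + x0;
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Slot-scan fan-beam DRR renderer.
//
// The volume lives in its own (CT) frame on a regular axis-aligned lattice;
// `tinv` maps world (EOS) coordinates into CT coordinates (the inverse of the
// CT->EOS pose).  For each requested pixel the horizontal ray of the scanning
// fan is intersected with the volume's bounding box and the attenuation line
// integral is accumulated by stepping `step` mm with trilinear interpolation.
//
// plane: 0 = frontal (source at y = -f, detector axis = x),
//        1 = lateral (source at x = -f, detector axis = y).
// rows/cols are 0-based pixel indices (v and h).
// [[Rcpp::export]]
NumericMatrix render_drr_cpp(NumericVector vol, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericMatrix tinv, int plane,
                             double f, double z0, double lambda_z,
                             double lambda_h, double principal,
                             IntegerVector rows, IntegerVector cols,
                             double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nr = rows.size(), nc = cols.size();
  NumericMatrix out(nr, nc);
  const double *v = REAL(vol);

  double R[3][3], tr[3];
  for (int i = 0; i < 3; i++) {
    for (int j = 0; j < 3; j++) R[i][j] = tinv(i, j);
    tr[i] = tinv(i, 3);
  }

  // sampling domain in continuous-index space: [0, n-1] per axis
  double lo[3] = {0.0, 0.0, 0.0};
  double hi[3] = {nx - 1.0, ny - 1.0, nz - 1.0};

  for (int ri = 0; ri < nr; ri++) {
    double z = z0 - lambda_z * rows[ri];
    for (int ci = 0; ci < nc; ci++) {
      double off = (cols[ci] - principal) * lambda_h;
      double S[3], D[3];
      if (plane == 0) {            // frontal
        S[0] = 0.0;  S[1] = -f;  S[2] = z;
        D[0] = off;  D[1] = 0.0; D[2] = z;
      } else {                     // lateral
        S[0] = -f;   S[1] = 0.0; S[2] = z;
        D[0] = 0.0;  D[1] = off; D[2] = z;
      }
      double dir[3] = {D[0] - S[0], D[1] - S[1], D[2] - S[2]};
      double nrm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
      for (int k = 0; k < 3; k++) dir[k] /= nrm;

      // into CT continuous-index space
      double Sc[3], dc[3];
      for (int i = 0; i < 3; i++) {
        Sc[i] = R[i][0] * S[0] + R[i][1] * S[1] + R[i][2] * S[2] + tr[i];
        dc[i] = R[i][0] * dir[0] + R[i][1] * dir[1] + R[i][2] * dir[2];
        Sc[i] = (Sc[i] - origin[i]) / spacing[i];
        dc[i] /= spacing[i];       // index units per mm of ray length
      }

      // clip t (mm along the ray) against the index-space slab
      double t0 = 0.0, t1 = 1e30;
      bool miss = false;
      for (int i = 0; i < 3 && !miss; i++) {
        if (std::fabs(dc[i]) < 1e-12) {
          if (Sc[i] < lo[i] || Sc[i] > hi[i]) miss = true;
        } else {
          double ta = (lo[i] - Sc[i]) / dc[i];
          double tb = (hi[i] - Sc[i]) / dc[i];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
        }
      }
      if (miss || t1 <= t0) { out(ri, ci) = 0.0; continue; }

      int nstep = (int)std::floor((t1 - t0) / step);
      double acc = 0.0;
      for (int k = 0; k < nstep; k++) {
        double t = t0 + (k + 0.5) * step;
        acc += trilerp(v, nx, ny, nz,
                       Sc[0] + t * dc[0], Sc[1] + t * dc[1], Sc[2] + t * dc[2]);
      }
      // remainder segment so the integral covers [t0, t1] exactly
      double rem = (t1 - t0) - nstep * step;
      if (rem > 1e-12) {
        double t = t0 + nstep * step + 0.5 * rem;
        acc = acc * step + rem * trilerp(v, nx, ny, nz,
                                         Sc[0] + t * dc[0], Sc[1] + t * dc[1],
                                         Sc[2] + t * dc[2]);
      } else {
        acc *= step;
      }
      out(ri, ci) = acc;
    }
  }
  return out;
}

// Squared distance from point p to triangle (a, b, c).
// Closest-point-on-triangle via Voronoi regions (Ericson, RTCD ch. 5).
static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; k++) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3], cp[3];
    for (int k = 0; k < 3; k++) {
      bp[k] = p[k] - b[k];
      cp[k] = p[k] - c[k];
    }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else if (d6 >= 0.0 && d5 <= d6) {
      q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; k++) q[k] = a[k] + v * ab[k];
      } else {
        double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          double w = d2 / (d2 - d6);
          for (int k = 0; k < 3; k++) q[k] = a[k] + w * ac[k];
        } else {
          double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
            for (int k = 0; k < 3; k++) q[k] = b[k] + w * (c[k] - b[k]);
          } else {
            double denom = 1.0 / (va + vb + vc);
            double v = vb * denom, w = vc * denom;
            for (int k = 0; k < 3; k++) q[k] = a[k] + v * ab[k] + w * ac[k];
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// Minimum distance from each query point to a triangle mesh (exact
// point-to-triangle, not vertex-to-vertex).  faces are 1-based indices.
// [[Rcpp::export]]
NumericVector point_mesh_distance_cpp(NumericMatrix query, NumericMatrix verts,
                                      IntegerMatrix faces) {
  int nq = query.nrow(), nf = faces.nrow();
  NumericVector out(nq);
  for (int qi = 0; qi < nq; qi++) {
    double p[3] = {query(qi, 0), query(qi, 1), query(qi, 2)};
    double best = 1e300;
    for (int fi = 0; fi < nf; fi++) {
      int ia = faces(fi, 0) - 1, ib = faces(fi, 1) - 1, ic = faces(fi, 2) - 1;
      double a[3] = {verts(ia, 0), verts(ia, 1), verts(ia, 2)};
      double b[3] = {verts(ib, 0), verts(ib, 1), verts(ib, 2)};
      double c[3] = {verts(ic, 0), verts(ic, 1), verts(ic, 2)};
      double d = point_tri_dist2(p, a, b, c);
      if (d < best) best = d;
    }
    out[qi] = std::sqrt(best);
  }
  return out;
}

// 6-connected component labelling of a 3D logical mask (flood fill).
// Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  const int *m = LOGICAL(mask);
  for (size_t i = 0; i < n; i++) {
    if (!m[i] || lab[i] != 0) continue;
    next++;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; k++) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        size_t j = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (m[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}
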