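// Siddon ray tracing for a rotating cone-beam geometry.
//
// Conventions (shared with the R side):
//   * volume array dims (nx, ny, nz), column-major, voxel centers at
//     world = origin + (i - (n-1)/2) * voxel  (i 0-based, mm)
//   * rotation axis = y; at angle 0 the source sits on +z
//   * source(beta)   = ( SID sin b, 0,  SID cos b )
//   * detector center = (-DID sin b, 0, -DID cos b ), u-axis = (cos b, 0, -sin b),
//     v-axis = (0, 1, 0)
// Line integrals are returned in dimensionless units (cm^-1 * cm): segment
// lengths are tracked in mm and scaled by 0.1.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double vx, vy, vz;     // voxel pitch, mm
  double x0, y0, z0;     // box lower corner, mm
};

inline Grid make_grid(const IntegerVector& dims, const NumericVector& voxel,
                      const NumericVector& origin) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.vx = voxel[0]; g.vy = voxel[1]; g.vz = voxel[2];
  g.x0 = origin[0] - 0.5 * g.nx * g.vx;
  g.y0 = origin[1] - 0.5 * g.ny * g.vy;
  g.z0 = origin[2] - 0.5 * g.nz * g.vz;
  return g;
}

// Walk one ray from s to p over the grid; call f(voxel_index, length_mm).
template <typename F>
inline void walk_ray(const Grid& g, const double s[3], const double p[3], F&& f) {
  const double d[3] = { p[0] - s[0], p[1] - s[1], p[2] - s[2] };
  const double lo[3] = { g.x0, g.y0, g.z0 };
  const double hi[3] = { g.x0 + g.nx * g.vx, g.y0 + g.ny * g.vy, g.z0 + g.nz * g.vz };

  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (s[a] <= lo[a] || s[a] >= hi[a]) return;
    } else {
      double t1 = (lo[a] - s[a]) / d[a];
      double t2 = (hi[a] - s[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmin >= tmax) return;

  const double ray_len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  const double vox[3] = { g.vx, g.vy, g.vz };

  // parametric step per voxel and next-crossing parameter per axis
  double tnext[3], dt[3];
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      tnext[a] = 2.0;  // never crossed
      dt[a] = 0.0;
    } else {
      dt[a] = vox[a] / std::fabs(d[a]);
      double entry = s[a] + tmin * d[a];
      double idx = (entry - lo[a]) / vox[a];
      double bound = (d[a] > 0) ? std::ceil(idx) : std::floor(idx);
      // guard: if exactly on a boundary, advance to the next one
      if (std::fabs(bound - idx) < 1e-9) bound += (d[a] > 0) ? 1.0 : -1.0;
      tnext[a] = (lo[a] + bound * vox[a] - s[a]) / d[a];
    }
  }

  double tcur = tmin;
  const int n[3] = { g.nx, g.ny, g.nz };
  while (tcur < tmax - 1e-12) {
    double tstep = tmax;
    for (int a = 0; a < 3; ++a) if (tnext[a] < tstep) tstep = tnext[a];
    if (tstep > tmax) tstep = tmax;
    const double tmid = 0.5 * (tcur + tstep);
    int ix[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      ix[a] = (int)std::floor((s[a] + tmid * d[a] - lo[a]) / vox[a]);
      if (ix[a] < 0 || ix[a] >= n[a]) { inside = false; break; }
    }
    if (inside) {
      const double len = (tstep - tcur) * ray_len;
      f(ix[0] + g.nx * (ix[1] + (R_xlen_t)g.ny * ix[2]), len);
    }
    for (int a = 0; a < 3; ++a)
      if (tnext[a] <= tstep + 1e-15) tnext[a] += dt[a];
    tcur = tstep;
  }
}

inline void source_pos(double beta, double sid, double out[3]) {
  out[0] = sid * std::sin(beta); out[1] = 0.0; out[2] = sid * std::cos(beta);
}

inline void det_cell(double beta, double did, double u, double v, double out[3]) {
  const double cb = std::cos(beta), sb = std::sin(beta);
  out[0] = -did * sb + u * cb;
  out[1] = v;
  out[2] = -did * cb - u * sb;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_siddon_project(NumericVector vol, IntegerVector dims,
                                 NumericVector voxel, NumericVector origin,
                                 NumericVector angles_rad, double sid, double did,
                                 int nu, int nv, double du, double dv) {
  const Grid g = make_grid(dims, voxel, origin);
  const int na = angles_rad.size();
  NumericVector out(Dimension(nu, nv, na));
  const double* V = vol.begin();
  double* O = out.begin();

  for (int ia = 0; ia < na; ++ia) {
    const double beta = angles_rad[ia];
    double s[3];
    source_pos(beta, sid, s);
    for (int iv = 0; iv < nv; ++iv) {
      const double v = (iv - 0.5 * (nv - 1)) * dv;
      for (int iu = 0; iu < nu; ++iu) {
        const double u = (iu - 0.5 * (nu - 1)) * du;
        double p[3];
        det_cell(beta, did, u, v, p);
        double acc = 0.0;
        walk_ray(g, s, p, [&](R_xlen_t idx, double len) { acc += len * V[idx]; });
        O[iu + (R_xlen_t)nu * (iv + (R_xlen_t)nv * ia)] = acc * 0.1;  // mm -> cm
      }
    }
  }
  return out;
}

// Exact adjoint of cpp_siddon_project: splats ray values back with the same
// intersection lengths (used for adjoint-consistency checks).
// [[Rcpp::export]]
NumericVector cpp_siddon_backproject(NumericVector proj, IntegerVector dims,
                                     NumericVector voxel, NumericVector origin,
                                     NumericVector angles_rad, double sid, double did,
                                     int nu, int nv, double du, double dv) {
  const Grid g = make_grid(dims, voxel, origin);
  const int na = angles_rad.size();
  NumericVector out(Dimension(dims[0], dims[1], dims[2]));
  double* O = out.begin();
  const double* P = proj.begin();

  for (int ia = 0; ia < na; ++ia) {
    const double beta = angles_rad[ia];
    double s[3];
    source_pos(beta, sid, s);
    for (int iv = 0; iv < nv; ++iv) {
      const double v = (iv - 0.5 * (nv - 1)) * dv;
      for (int iu = 0; iu < nu; ++iu) {
        const double q = P[iu + (R_xlen_t)nu * (iv + (R_xlen_t)nv * ia)] * 0.1;
        if (q == 0.0) continue;
        const double u = (iu - 0.5 * (nu - 1)) * du;
        double p[3];
        det_cell(beta, did, u, v, p);
        walk_ray(g, s, p, [&](R_xlen_t idx, double len) { O[idx] += len * q; });
      }
    }
  }
  return out;
}

// Voxel-driven FDK backprojection with bilinear detector interpolation.
// `proj` must already be cosine-weighted, ramp-filtered and scaled by
// 0.5 * dbeta per view (done on the R side); detector pitch is given on the
// virtual detector through the isocenter.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector proj, int nu, int nv,
                                  double du_iso, double dv_iso,
                                  NumericVector angles_rad, double sid,
                                  IntegerVector dims, NumericVector voxel,
                                  NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  NumericVector out(Dimension(nx, ny, nz));
  double* O = out.begin();
  const double* P = proj.begin();

  std::vector<double> cb(na), sb(na);
  for (int ia = 0; ia < na; ++ia) { cb[ia] = std::cos(angles_rad[ia]); sb[ia] = std::sin(angles_rad[ia]); }

  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);

  for (int iz = 0; iz < nz; ++iz) {
    const double z = origin[2] + (iz - 0.5 * (nz - 1)) * voxel[2];
    for (int iy = 0; iy < ny; ++iy) {
      const double y = origin[1] + (iy - 0.5 * (ny - 1)) * voxel[1];
      for (int ix = 0; ix < nx; ++ix) {
        const double x = origin[0] + (ix - 0.5 * (nx - 1)) * voxel[0];
        double acc = 0.0;
        for (int ia = 0; ia < na; ++ia) {
          const double t = x * cb[ia] - z * sb[ia];      // along detector u
          const double s = x * sb[ia] + z * cb[ia];      // toward source
          const double denom = sid - s;
          if (denom <= 1e-6) continue;
          const double mag = sid / denom;
          const double fu = t * mag / du_iso + cu;
          const double fv = y * mag / dv_iso + cv;
          const int iu0 = (int)std::floor(fu), iv0 = (int)std::floor(fv);
          if (iu0 < 0 || iu0 >= nu - 1 || iv0 < 0 || iv0 >= nv - 1) continue;
          const double au = fu - iu0, av = fv - iv0;
          const double* base = P + (R_xlen_t)nu * nv * ia;
          const double p00 = base[iu0 + (R_xlen_t)nu * iv0];
          const double p10 = base[iu0 + 1 + (R_xlen_t)nu * iv0];
          const double p01 = base[iu0 + (R_xlen_t)nu * (iv0 + 1)];
          const double p11 = base[iu0 + 1 + (R_xlen_t)nu * (iv0 + 1)];
          const double sample = (1 - au) * (1 - av) * p00 + au * (1 - av) * p10 +
                                (1 - au) * av * p01 + au * av * p11;
          acc += mag * mag * sample;
        }
        O[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = acc;
      }
    }
  }
  return out;
}
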