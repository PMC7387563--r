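#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit forward-Euler step of the Pennes bioheat equation on a regular
// voxel grid with a 7-point conduction stencil.
//
//   rho c dT/dt = div(k grad T) + a (Ta - T) + src
//
// a = rho_b c_b omega (perfusion heat exchange, W/(m^3 K)), src = Q_met +
// Q_laser (W/m^3).  Face conductivities (harmonic means) are precomputed on
// the R side.  The top surface (iz = 0) loses heat radiatively as
// eps * sigma_SB * (T^4 - Tamb^4) plus an optional convective term
// h * (T - Tamb); conduction through the top face is zero.  Lateral and
// bottom boundaries are either insulated (bc_mode = 0) or clamped to a
// frozen reference field one voxel outside the domain (bc_mode = 1), which
// emulates an open boundary backed by equilibrated far-field tissue.
//
// Returns the final field, surface (iz = 0) snapshots at the requested
// 1-based step indices, and the max |dT| of the final step.

static const double SIGMA_SB = 5.670374419e-8;

// [[Rcpp::export]]
List cpp_run_solver(NumericVector T0,
                    IntegerVector dims,
                    NumericVector spacing,
                    NumericVector kxf, NumericVector kyf, NumericVector kzf,
                    NumericVector kvox,
                    NumericVector rhoc,
                    NumericVector perf_a,
                    NumericVector src,
                    double Ta,
                    double eps_emis, double T_amb, double h_conv,
                    int bc_mode,
                    NumericVector ghost,
                    double dt, int nsteps,
                    IntegerVector record_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double dx2 = spacing[0] * spacing[0];
  const double dy2 = spacing[1] * spacing[1];
  const double dz2 = spacing[2] * spacing[2];
  const double dz = spacing[2];
  const double Tamb4 = T_amb * T_amb * T_amb * T_amb;

  std::vector<double> A(T0.begin(), T0.end());
  std::vector<double> B(n);
  const double *kx = kxf.begin(), *ky = kyf.begin(), *kz = kzf.begin();
  const double *kv = kvox.begin(), *rc = rhoc.begin();
  const double *pa = perf_a.begin(), *q = src.begin();
  const double *gh = ghost.begin();

  const int nrec = record_steps.size();
  NumericVector surf((R_xlen_t)nx * ny * std::max(nrec, 1));
  int irec = 0;
  double max_dT = 0.0;

  // strides: idx = ix + nx*(iy + ny*iz); face arrays have the reduced dim
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t sy_x = nx - 1;               // kxf: (nx-1, ny, nz)
  const R_xlen_t sz_x = (R_xlen_t)(nx - 1) * ny;
  const R_xlen_t sz_y = (R_xlen_t)nx * (ny - 1); // kyf: (nx, ny-1, nz)

  for (int step = 1; step <= nsteps; ++step) {
    max_dT = 0.0;
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) {
        R_xlen_t base = sy * iy + sz * iz;
        for (int ix = 0; ix < nx; ++ix) {
          R_xlen_t i = base + ix;
          double Ti = A[i];
          double flux = 0.0;
          // x faces
          if (ix > 0)
            flux += kx[(ix - 1) + sy_x * iy + sz_x * iz] * (A[i - 1] - Ti) / dx2;
          else if (bc_mode == 1)
            flux += kv[i] * (gh[i] - Ti) / dx2;
          if (ix < nx - 1)
            flux += kx[ix + sy_x * iy + sz_x * iz] * (A[i + 1] - Ti) / dx2;
          else if (bc_mode == 1)
            flux += kv[i] * (gh[i] - Ti) / dx2;
          // y faces
          if (iy > 0)
            flux += ky[ix + sy * (iy - 1) + sz_y * iz] * (A[i - sy] - Ti) / dy2;
          else if (bc_mode == 1)
            flux += kv[i] * (gh[i] - Ti) / dy2;
          if (iy < ny - 1)
            flux += ky[ix + sy * iy + sz_y * iz] * (A[i + sy] - Ti) / dy2;
          else if (bc_mode == 1)
            flux += kv[i] * (gh[i] - Ti) / dy2;
          // z faces: iz = 0 is the imaged top surface
          if (iz > 0)
            flux += kz[ix + sy * iy + sz * (iz - 1)] * (A[i - sz] - Ti) / dz2;
          else {
            // radiative (+ optional convective) surface loss, W/m^3
            double Ti4 = Ti * Ti * Ti * Ti;
            flux -= (eps_emis * SIGMA_SB * (Ti4 - Tamb4) + h_conv * (Ti - T_amb)) / dz;
          }
          if (iz < nz - 1)
            flux += kz[ix + sy * iy + sz * iz] * (A[i + sz] - Ti) / dz2;
          else if (bc_mode == 1)
            flux += kv[i] * (gh[i] - Ti) / dz2;

          double dTi = dt * (flux + pa[i] * (Ta - Ti) + q[i]) / rc[i];
          B[i] = Ti + dTi;
          double ad = std::fabs(dTi);
          if (ad > max_dT) max_dT = ad;
        }
      }
    }
    A.swap(B);
    if (!std::isfinite(max_dT))
      stop("temperature field became non-finite at step %d", step);
    if (irec < nrec && record_steps[irec] == step) {
      std::copy(A.begin(), A.begin() + sz, surf.begin() + (R_xlen_t)irec * sz);
      ++irec;
    }
  }

  NumericVector Tout(n);
  std::copy(A.begin(), A.end(), Tout.begin());
  return List::create(_["T"] = Tout, _["surface"] = surf,
                      _["max_dT"] = max_dT, _["n_recorded"] = irec);
}
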