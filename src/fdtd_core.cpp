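#include <Rcpp.h>
#include <vector>
#include <complex>
#include <cmath>
using namespace Rcpp;

// 2D TM (Ez, Hx, Hy) Yee solver, c = eps0 = mu0 = 1, lengths in nm.
// x: propagation axis (index i, 0..nx-1), CPML at both x ends.
// y: lateral axis (index j, 0..ny-1), periodic.
// Ez(i,j); Hx(i,j) at (i, j+1/2); Hy(i,j) at (i+1/2, j), i < nx-1.
// A uniform soft line source drives Ez at column isrc; running DFTs of Ez
// and of Hy colocated to the Ez points are accumulated at two monitor
// columns (reflection side and transmission side).
//
// [[Rcpp::export]]
List fdtd_core(NumericMatrix eps, double dx, double dt, int nsteps, int npml,
               int isrc, int imon_r, int imon_t,
               NumericVector src, NumericVector omega, double n_bg) {
  const int nx = eps.nrow(), ny = eps.ncol(), nw = omega.size();
  const double dy = dx;
  std::vector<double> Ez(nx * ny, 0.0), Hx(nx * ny, 0.0), Hy(nx * ny, 0.0);
  auto id = [nx](int i, int j) { return i + (size_t)j * nx; };

  // CPML (Roden & Gedney), kappa = 1, graded sigma, x direction only
  const int m = 3;
  const double smax = 0.8 * (m + 1) / (dx / n_bg); // eta = 1/n_bg in these units
  const double alpha = 0.02;
  std::vector<double> be(nx, 1.0), ae(nx, 0.0), bh(nx, 1.0), ah(nx, 0.0);
  for (int i = 0; i < nx; ++i) {
    // Ez points: distance into PML measured from inner PML edge
    double de = 0.0;
    if (i < npml) de = (npml - i) / (double)npml;
    else if (i >= nx - npml) de = (i - (nx - npml - 1)) / (double)npml;
    if (de > 0) {
      double s = smax * std::pow(de, m);
      be[i] = std::exp(-(s + alpha) * dt);
      ae[i] = s / (s + alpha) * (be[i] - 1.0);
    }
    // Hy points at i + 1/2
    double dhh = 0.0;
    double ih = i + 0.5;
    if (ih < npml) dhh = (npml - ih) / (double)npml;
    else if (ih > nx - 1 - npml) dhh = (ih - (nx - 1 - npml)) / (double)npml;
    if (dhh > 0) {
      double s = smax * std::pow(dhh, m);
      bh[i] = std::exp(-(s + alpha) * dt);
      ah[i] = s / (s + alpha) * (bh[i] - 1.0);
    }
  }
  std::vector<double> psiE(nx * ny, 0.0), psiH(nx * ny, 0.0);

  // DFT accumulators (complex) at the two monitor columns
  std::vector<std::complex<double>> EzR(nw * ny, 0.0), HyR(nw * ny, 0.0),
      EzT(nw * ny, 0.0), HyT(nw * ny, 0.0);
  std::complex<double> I(0.0, 1.0);

  for (int n = 0; n < nsteps; ++n) {
    const double tE = (n + 1) * dt, tH = (n + 0.5) * dt;
    // H update (to t + dt/2)
    for (int j = 0; j < ny; ++j) {
      const int jp = (j + 1 == ny) ? 0 : j + 1;
      double *ez = &Ez[id(0, j)], *ezp = &Ez[id(0, jp)];
      double *hx = &Hx[id(0, j)], *hy = &Hy[id(0, j)], *pH = &psiH[id(0, j)];
      for (int i = 0; i < nx; ++i) hx[i] -= dt / dy * (ezp[i] - ez[i]);
      for (int i = 0; i < nx - 1; ++i) {
        const double dEdx = (ez[i + 1] - ez[i]) / dx;
        pH[i] = bh[i] * pH[i] + ah[i] * dEdx;
        hy[i] += dt * (dEdx + pH[i]);
      }
    }
    // E update (to t + dt)
    for (int j = 0; j < ny; ++j) {
      const int jm = (j == 0) ? ny - 1 : j - 1;
      double *ez = &Ez[id(0, j)];
      double *hx = &Hx[id(0, j)], *hxm = &Hx[id(0, jm)];
      double *hy = &Hy[id(0, j)], *pE = &psiE[id(0, j)];
      const double *ep = &eps[0] + (size_t)j * nx;
      for (int i = 1; i < nx - 1; ++i) {
        const double dHdx = (hy[i] - hy[i - 1]) / dx;
        pE[i] = be[i] * pE[i] + ae[i] * dHdx;
        ez[i] += dt / ep[i] * (dHdx + pE[i] - (hx[i] - hxm[i]) / dy);
      }
    }
    // soft plane-wave line source
    const double s = dt * src[n];
    for (int j = 0; j < ny; ++j) Ez[id(isrc, j)] += s;
    // DFT accumulation at the monitors
    for (int w = 0; w < nw; ++w) {
      const std::complex<double> phE = std::exp(-I * omega[w] * tE) * dt;
      const std::complex<double> phH = std::exp(-I * omega[w] * tH) * dt;
      for (int j = 0; j < ny; ++j) {
        EzR[w + (size_t)j * nw] += phE * Ez[id(imon_r, j)];
        HyR[w + (size_t)j * nw] +=
            phH * 0.5 * (Hy[id(imon_r - 1, j)] + Hy[id(imon_r, j)]);
        EzT[w + (size_t)j * nw] += phE * Ez[id(imon_t, j)];
        HyT[w + (size_t)j * nw] +=
            phH * 0.5 * (Hy[id(imon_t - 1, j)] + Hy[id(imon_t, j)]);
      }
    }
  }
  // residual field energy (decay diagnostic)
  double energy = 0.0;
  for (size_t k = 0; k < Ez.size(); ++k)
    energy += Ez[k] * Ez[k] + Hx[k] * Hx[k] + Hy[k] * Hy[k];

  ComplexMatrix ezr(nw, ny), hyr(nw, ny), ezt(nw, ny), hyt(nw, ny);
  for (int j = 0; j < ny; ++j)
    for (int w = 0; w < nw; ++w) {
      size_t k = w + (size_t)j * nw;
      ezr(w, j) = Rcomplex{EzR[k].real(), EzR[k].imag()};
      hyr(w, j) = Rcomplex{HyR[k].real(), HyR[k].imag()};
      ezt(w, j) = Rcomplex{EzT[k].real(), EzT[k].imag()};
      hyt(w, j) = Rcomplex{HyT[k].real(), HyT[k].imag()};
    }
  return List::create(_["EzR"] = ezr, _["HyR"] = hyr, _["EzT"] = ezt,
                      _["HyT"] = hyt, _["residual_energy"] = energy);
}
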