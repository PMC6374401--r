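// Yee-grid FDTD kernels for monochromatic plane-wave propagation through a
// real refractive-index volume.  Natural units: lengths in micrometres,
// c = eps0 = mu0 = 1, so the optical period equals the vacuum wavelength.
//
// - 2D solver, modes "TM" (out-of-plane E: Ey, Hx, Hz) and "TE" (in-plane E:
//   Ex, Ez, Hy); grid (x lateral, z propagation); lateral boundaries periodic
//   or CPML; total-field/scattered-field injection either on a single plane
//   (plane wave spanning the width) or on a rectangular box (for scattering
//   oracles, TM only).
// - 3D solver: full Yee cell, periodic lateral boundaries, CPML along z,
//   single-plane TF/SF injection, x- or y-polarised source.
// - The incident wave is fed from a 1D auxiliary FDTD line with the same
//   time step and mesh, so injection is exact at normal incidence.
// - Steady-state phasors are extracted by discrete Fourier projection at the
//   source frequency over the final two optical periods.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <complex>

using namespace Rcpp;

namespace {

struct Cpml {
  // kappa = 1, cubic sigma grading, linear alpha grading
  std::vector<double> bE, aE, bH, aH; // indexed by node along the axis
  int n, npml;
  void init(int n_, int npml_, double dx, double dt) {
    n = n_; npml = npml_;
    bE.assign(n, 1.0); aE.assign(n, 0.0);
    bH.assign(n, 1.0); aH.assign(n, 0.0);
    const double m = 3.0;
    const double smax = 0.8 * (m + 1.0) / dx;
    const double amax = 0.05;
    for (int k = 0; k < n; ++k) {
      // E nodes at integer k, H nodes at k + 1/2
      double dE = 0.0, dH = 0.0;
      if (k < npml) { dE = (npml - k) / (double)npml; }
      if (k >= n - npml) { dE = (k - (n - 1 - npml)) / (double)npml; }
      const double kh = k + 0.5;
      if (kh < npml) { dH = (npml - kh) / (double)npml; }
      if (kh > n - 1 - npml) { dH = (kh - (n - 1 - npml)) / (double)npml; }
      if (dE > 0.0) {
        const double s = smax * std::pow(dE, m), al = amax * (1.0 - dE);
        bE[k] = std::exp(-(s + al) * dt);
        aE[k] = s / (s + al) * (bE[k] - 1.0);
      }
      if (dH > 0.0 && dH <= 1.0) {
        const double s = smax * std::pow(dH, m), al = amax * (1.0 - dH);
        bH[k] = std::exp(-(s + al) * dt);
        aH[k] = s / (s + al) * (bH[k] - 1.0);
      }
    }
  }
};

// 1D auxiliary incident-field line: e at integer nodes, h at half nodes.
// sgn = +1 for the (Ey, Hx) pair, -1 for the (Ex, Hy) pair.  The line is
// sized so the wavefront never reaches the far end within the simulated
// time, so the incident wave in the monitored region is the exact discrete
// rightward mode with unit amplitude (no ABC approximation).
struct AuxLine {
  std::vector<double> e, h;
  double n0, dt, dx, omega, rampT, sgn;
  int n;
  void init(int nzMain, long nsteps, double n0_, double dt_, double dx_,
            double omega_, double rampT_, double sgn_) {
    n0 = n0_; dt = dt_; dx = dx_; omega = omega_; rampT = rampT_; sgn = sgn_;
    const int travel = (int)std::ceil(nsteps * dt / (n0 * dx)) + 16;
    n = nzMain + travel;
    e.assign(n, 0.0); h.assign(n, 0.0);
  }
  double src(double t) const {
    double w = 1.0;
    if (t < rampT) w = 0.5 * (1.0 - std::cos(M_PI * t / rampT));
    return w * std::cos(omega * t);
  }
  void stepH() {
    const double a = sgn * dt / dx;
    for (int k = 0; k < n - 1; ++k) h[k] += a * (e[k + 1] - e[k]);
  }
  void stepE(double t) {
    const double b = sgn * dt / (n0 * n0 * dx);
    for (int k = 1; k < n - 1; ++k) e[k] += b * (h[k] - h[k - 1]);
    e[0] = src(t); // hard source at the line origin
  }
};

inline void phAcc(std::vector<double>& re, std::vector<double>& im,
                  const double* f, int n, double c, double s) {
  for (int i = 0; i < n; ++i) { re[i] += f[i] * c; im[i] += f[i] * s; }
}

// Least-squares projection onto {cos(wt), sin(wt)} over the sampling
// window: solving the 2x2 normal equations is exact for a pure steady-state
// oscillation even when the window is not a whole number of periods.
struct LsqWin {
  double scc, sss, scs;
  LsqWin() : scc(0), sss(0), scs(0) {}
  void acc(double c, double s) { scc += c * c; sss += s * s; scs += c * s; }
  // phasor in the E(t) = Re(E exp(-i w t)) convention
  std::complex<double> solve(double sc, double ss) const {
    const double det = scc * sss - scs * scs;
    return std::complex<double>((sss * sc - scs * ss) / det,
                                (scc * ss - scs * sc) / det);
  }
};

} // namespace

// ---------------------------------------------------------------------------
// 2D solver
// [[Rcpp::export]]
List cpp_fdtd_2d(NumericMatrix n2grid, double dx, double wavelength,
                 double courant, double nPeriods, int npml,
                 bool lateralPml, std::string mode, std::string tfsf,
                 IntegerVector boxCells, int ks, int kexit, int krefl,
                 double n0, double rampPeriods) {
  const int nx = n2grid.nrow(), nz = n2grid.ncol();
  const double dt = courant * dx / std::sqrt(2.0);
  const double T = wavelength;             // c = 1
  const double omega = 2.0 * M_PI / T;
  const long nsteps = (long)std::ceil(nPeriods * T / dt);
  const long wsteps = (long)std::ceil(2.0 * T / dt);
  const bool tm = (mode == "TM");
  const bool box = (tfsf == "box");

  std::vector<double> eps(n2grid.begin(), n2grid.end()); // n^2 per voxel
  for (size_t i = 0; i < eps.size(); ++i) eps[i] *= eps[i];

  // fields (full-size arrays; staggering by convention)
  std::vector<double> F1((size_t)nx * nz, 0.0); // TM: Ey | TE: Ex
  std::vector<double> F2((size_t)nx * nz, 0.0); // TM: Hx | TE: Ez
  std::vector<double> F3((size_t)nx * nz, 0.0); // TM: Hz | TE: Hy
  std::vector<double> psiEz((size_t)nx * nz, 0.0), psiHz((size_t)nx * nz, 0.0);
  std::vector<double> psiEx, psiHx;
  if (lateralPml) { psiEx.assign((size_t)nx * nz, 0.0); psiHx.assign((size_t)nx * nz, 0.0); }

  Cpml pz; pz.init(nz, npml, dx, dt);
  Cpml px; if (lateralPml) px.init(nx, npml, dx, dt);

  AuxLine aux;
  aux.init(nz, nsteps, n0, dt, dx, omega, rampPeriods * T, tm ? 1.0 : -1.0);

  const int bi1 = boxCells[0], bi2 = boxCells[1], bk1 = boxCells[2],
            bk2 = boxCells[3];

  std::vector<double> accRe((size_t)nx * nz, 0.0), accIm((size_t)nx * nz, 0.0);
  std::vector<double> acc2Re, acc2Im;
  if (!tm) { acc2Re.assign((size_t)nx * nz, 0.0); acc2Im.assign((size_t)nx * nz, 0.0); }
  double auxExitRe = 0, auxExitIm = 0, auxReflRe = 0, auxReflIm = 0;
  LsqWin win;
  std::vector<double> energy;

  const double cH = dt / dx;
  const long checkEvery = std::max(1L, (long)(T / dt));
  const long wstart = nsteps - wsteps;

  #define IDX(i, k) ((size_t)(i) + (size_t)nx * (k))
  for (long stp = 0; stp < nsteps; ++stp) {
    const double tE = (stp + 1) * dt;
    aux.stepH();

    if (tm) {
      // Hx(i,k+1/2) += dt/dx (Ey(i,k+1)-Ey(i,k)), with z-CPML
      for (int k = 0; k < nz - 1; ++k) {
        const double bh = pz.bH[k], ah = pz.aH[k];
        for (int i = 0; i < nx; ++i) {
          const double d = (F1[IDX(i, k + 1)] - F1[IDX(i, k)]) / dx;
          double dd = d;
          if (ah != 0.0 || bh != 1.0) {
            psiHz[IDX(i, k)] = bh * psiHz[IDX(i, k)] + ah * d;
            dd += psiHz[IDX(i, k)];
          }
          F2[IDX(i, k)] += dt * dd;
        }
      }
      // Hz(i+1/2,k) -= dt/dx (Ey(i+1,k)-Ey(i,k))
      for (int k = 0; k < nz; ++k) {
        for (int i = 0; i < nx; ++i) {
          const int ip = (i + 1 < nx) ? i + 1 : (lateralPml ? i : 0);
          if (lateralPml && i == nx - 1) { continue; }
          const double d = (F1[IDX(ip, k)] - F1[IDX(i, k)]) / dx;
          double dd = d;
          if (lateralPml && (px.bH[i] != 1.0 || px.aH[i] != 0.0)) {
            psiHx[IDX(i, k)] = px.bH[i] * psiHx[IDX(i, k)] + px.aH[i] * d;
            dd += psiHx[IDX(i, k)];
          }
          F3[IDX(i, k)] -= dt * dd;
        }
      }
      // TF/SF H corrections
      if (!box) {
        for (int i = 0; i < nx; ++i) F2[IDX(i, ks - 1)] -= cH * aux.e[ks];
      } else {
        for (int i = bi1; i <= bi2; ++i) {
          F2[IDX(i, bk1 - 1)] -= cH * aux.e[bk1];
          F2[IDX(i, bk2)] += cH * aux.e[bk2];
        }
        for (int k = bk1; k <= bk2; ++k) {
          F3[IDX(bi1 - 1, k)] += cH * aux.e[k];
          F3[IDX(bi2, k)] -= cH * aux.e[k];
        }
      }
      aux.stepE(tE);
      // Ey(i,k) += dt/eps [ (Hx(k+1/2)-Hx(k-1/2))/dx - (Hz(i+1/2)-Hz(i-1/2))/dx ]
      for (int k = 1; k < nz - 1; ++k) {
        const double be = pz.bE[k], ae = pz.aE[k];
        for (int i = 0; i < nx; ++i) {
          const int im = (i > 0) ? i - 1 : (lateralPml ? i : nx - 1);
          if (lateralPml && i == 0) continue;
          const double dz = (F2[IDX(i, k)] - F2[IDX(i, k - 1)]) / dx;
          const double dxh = (F3[IDX(i, k)] - F3[IDX(im, k)]) / dx;
          double dzz = dz;
          if (ae != 0.0 || be != 1.0) {
            psiEz[IDX(i, k)] = be * psiEz[IDX(i, k)] + ae * dz;
            dzz += psiEz[IDX(i, k)];
          }
          double dxx = dxh;
          if (lateralPml && (px.bE[i] != 1.0 || px.aE[i] != 0.0)) {
            psiEx[IDX(i, k)] = px.bE[i] * psiEx[IDX(i, k)] + px.aE[i] * dxh;
            dxx += psiEx[IDX(i, k)];
          }
          F1[IDX(i, k)] += dt / eps[IDX(i, k)] * (dzz - dxx);
        }
      }
      // TF/SF E corrections
      if (!box) {
        for (int i = 0; i < nx; ++i)
          F1[IDX(i, ks)] -= dt / (eps[IDX(i, ks)] * dx) * aux.h[ks - 1];
      } else {
        for (int i = bi1; i <= bi2; ++i) {
          F1[IDX(i, bk1)] -= dt / (eps[IDX(i, bk1)] * dx) * aux.h[bk1 - 1];
          F1[IDX(i, bk2)] += dt / (eps[IDX(i, bk2)] * dx) * aux.h[bk2];
        }
      }
    } else {
      // TE: Hy(i+1/2,k+1/2) += dt [ -(Ex(i+1/2,k+1)-Ex(i+1/2,k))/dx
      //                             + (Ez(i+1,k+1/2)-Ez(i,k+1/2))/dx ]
      for (int k = 0; k < nz - 1; ++k) {
        const double bh = pz.bH[k], ah = pz.aH[k];
        for (int i = 0; i < nx; ++i) {
          const int ip = (i + 1 < nx) ? i + 1 : (lateralPml ? i : 0);
          if (lateralPml && i == nx - 1) continue;
          const double dEx = (F1[IDX(i, k + 1)] - F1[IDX(i, k)]) / dx;
          const double dEz = (F2[IDX(ip, k)] - F2[IDX(i, k)]) / dx;
          double dExx = dEx;
          if (ah != 0.0 || bh != 1.0) {
            psiHz[IDX(i, k)] = bh * psiHz[IDX(i, k)] + ah * dEx;
            dExx += psiHz[IDX(i, k)];
          }
          double dEzz = dEz;
          if (lateralPml && (px.bH[i] != 1.0 || px.aH[i] != 0.0)) {
            psiHx[IDX(i, k)] = px.bH[i] * psiHx[IDX(i, k)] + px.aH[i] * dEz;
            dEzz += psiHx[IDX(i, k)];
          }
          F3[IDX(i, k)] += dt * (-dExx + dEzz);
        }
      }
      // TF/SF H corrections (plane only)
      for (int i = 0; i < nx; ++i) F3[IDX(i, ks - 1)] += cH * aux.e[ks];
      aux.stepE(tE);
      // Ex(i+1/2,k) += -dt/eps (Hy(i+1/2,k+1/2)-Hy(i+1/2,k-1/2))/dx
      for (int k = 1; k < nz - 1; ++k) {
        const double be = pz.bE[k], ae = pz.aE[k];
        for (int i = 0; i < nx; ++i) {
          const double d = (F3[IDX(i, k)] - F3[IDX(i, k - 1)]) / dx;
          double dd = d;
          if (ae != 0.0 || be != 1.0) {
            psiEz[IDX(i, k)] = be * psiEz[IDX(i, k)] + ae * d;
            dd += psiEz[IDX(i, k)];
          }
          F1[IDX(i, k)] -= dt / eps[IDX(i, k)] * dd;
        }
      }
      // Ez(i,k+1/2) += dt/eps (Hy(i+1/2,k+1/2)-Hy(i-1/2,k+1/2))/dx
      for (int k = 0; k < nz - 1; ++k) {
        for (int i = 0; i < nx; ++i) {
          const int im = (i > 0) ? i - 1 : (lateralPml ? i : nx - 1);
          if (lateralPml && i == 0) continue;
          const double d = (F3[IDX(i, k)] - F3[IDX(im, k)]) / dx;
          double dd = d;
          if (lateralPml && (px.bE[i] != 1.0 || px.aE[i] != 0.0)) {
            psiEx[IDX(i, k)] = px.bE[i] * psiEx[IDX(i, k)] + px.aE[i] * d;
            dd += psiEx[IDX(i, k)];
          }
          F2[IDX(i, k)] += dt / eps[IDX(i, k)] * dd;
        }
      }
      // TF/SF E correction
      for (int i = 0; i < nx; ++i)
        F1[IDX(i, ks)] += dt / (eps[IDX(i, ks)] * dx) * aux.h[ks - 1];
    }

    // phasor accumulation over the final two periods
    if (stp >= wstart) {
      const double c = std::cos(omega * tE), s = std::sin(omega * tE);
      win.acc(c, s);
      phAcc(accRe, accIm, F1.data(), nx * nz, c, s);
      if (!tm) phAcc(acc2Re, acc2Im, F2.data(), nx * nz, c, s);
      auxExitRe += aux.e[kexit] * c; auxExitIm += aux.e[kexit] * s;
      auxReflRe += aux.e[krefl] * c; auxReflIm += aux.e[krefl] * s;
    }
    if (stp % checkEvery == 0) {
      double en = 0.0;
      for (size_t q = 0; q < F1.size(); ++q) en += F1[q] * F1[q];
      energy.push_back(en);
      if (!R_finite(en) || en > 1e12 * (double)F1.size())
        stop("FDTD instability detected: field energy diverged");
      Rcpp::checkUserInterrupt();
    }
  }
  #undef IDX

  ComplexMatrix Eph(nx, nz);
  for (size_t q = 0; q < accRe.size(); ++q) {
    const std::complex<double> z = win.solve(accRe[q], accIm[q]);
    Eph[q].r = z.real(); Eph[q].i = z.imag();
  }
  List out = List::create(
    _["Ephasor"] = Eph,
    _["incExit"] = win.solve(auxExitRe, auxExitIm),
    _["incRefl"] = win.solve(auxReflRe, auxReflIm),
    _["energy"] = wrap(energy),
    _["steps"] = (double)nsteps, _["dt"] = dt);
  if (!tm) {
    ComplexMatrix E2(nx, nz);
    for (size_t q = 0; q < acc2Re.size(); ++q) {
      const std::complex<double> z = win.solve(acc2Re[q], acc2Im[q]);
      E2[q].r = z.real(); E2[q].i = z.imag();
    }
    out["EzPhasor"] = E2;
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D solver (periodic laterals, CPML along z, single-plane TF/SF)
// [[Rcpp::export]]
List cpp_fdtd_3d(NumericVector n2vals, int nx, int ny, int nz,
                 double dx, double wavelength, double courant,
                 double nPeriods, int npml, std::string pol,
                 int ks, int kexit, int krefl, double n0,
                 double rampPeriods) {
  const double dt = courant * dx / std::sqrt(3.0);
  const double T = wavelength;
  const double omega = 2.0 * M_PI / T;
  const long nsteps = (long)std::ceil(nPeriods * T / dt);
  const long wsteps = (long)std::ceil(2.0 * T / dt);
  const long wstart = nsteps - wsteps;
  const bool polx = (pol == "x");
  const size_t N = (size_t)nx * ny * nz;
  const size_t NP = (size_t)nx * ny;

  std::vector<double> eps(N);
  for (size_t q = 0; q < N; ++q) eps[q] = n2vals[q] * n2vals[q];

  std::vector<double> Ex(N, 0), Ey(N, 0), Ez(N, 0), Hx(N, 0), Hy(N, 0), Hz(N, 0);
  std::vector<double> psiExz(N, 0), psiEyz(N, 0), psiHxz(N, 0), psiHyz(N, 0);

  Cpml pz; pz.init(nz, npml, dx, dt);
  AuxLine aux;
  aux.init(nz, nsteps, n0, dt, dx, omega, rampPeriods * T, polx ? -1.0 : 1.0);

  std::vector<double> exRe(NP, 0), exIm(NP, 0), eyRe(NP, 0), eyIm(NP, 0);
  std::vector<double> rxRe(NP, 0), rxIm(NP, 0), ryRe(NP, 0), ryIm(NP, 0);
  double auxExitRe = 0, auxExitIm = 0, auxReflRe = 0, auxReflIm = 0;
  LsqWin win;
  std::vector<double> energy;
  const long checkEvery = std::max(1L, (long)(T / dt));
  const double cH = dt / dx;

  #define ID3(i, j, k) ((size_t)(i) + (size_t)nx * ((size_t)(j) + (size_t)ny * (k)))
  #define IPX(i) (((i) + 1 < nx) ? (i) + 1 : 0)
  #define IMX(i) (((i) > 0) ? (i) - 1 : nx - 1)
  #define JPY(j) (((j) + 1 < ny) ? (j) + 1 : 0)
  #define JMY(j) (((j) > 0) ? (j) - 1 : ny - 1)

  for (long stp = 0; stp < nsteps; ++stp) {
    const double tE = (stp + 1) * dt;
    aux.stepH();

    // H updates
    for (int k = 0; k < nz - 1; ++k) {
      const double bh = pz.bH[k], ah = pz.aH[k];
      const bool inPml = (ah != 0.0 || bh != 1.0);
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const size_t q = ID3(i, j, k);
          // Hx(i,j+1/2,k+1/2) += dt [ (Ey(k+1)-Ey(k))/dx - (Ez(j+1)-Ez(j))/dx ]
          {
            const double dEyz = (Ey[ID3(i, j, k + 1)] - Ey[q]) / dx;
            const double dEzy = (Ez[ID3(i, JPY(j), k)] - Ez[q]) / dx;
            double dd = dEyz;
            if (inPml) { psiHxz[q] = bh * psiHxz[q] + ah * dEyz; dd += psiHxz[q]; }
            Hx[q] += dt * (dd - dEzy);
          }
          // Hy(i+1/2,j,k+1/2) += dt [ (Ez(i+1)-Ez(i))/dx - (Ex(k+1)-Ex(k))/dx ]
          {
            const double dEzx = (Ez[ID3(IPX(i), j, k)] - Ez[q]) / dx;
            const double dExz = (Ex[ID3(i, j, k + 1)] - Ex[q]) / dx;
            double dd = dExz;
            if (inPml) { psiHyz[q] = bh * psiHyz[q] + ah * dExz; dd += psiHyz[q]; }
            Hy[q] += dt * (dEzx - dd);
          }
          // Hz(i+1/2,j+1/2,k) += dt [ (Ex(j+1)-Ex(j))/dx - (Ey(i+1)-Ey(i))/dx ]
          {
            const double dExy = (Ex[ID3(i, JPY(j), k)] - Ex[q]) / dx;
            const double dEyx = (Ey[ID3(IPX(i), j, k)] - Ey[q]) / dx;
            Hz[q] += dt * (dExy - dEyx);
          }
        }
      }
    }
    // Hz on the top plane k = nz-1 (no z-derivative involved)
    {
      const int k = nz - 1;
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const size_t q = ID3(i, j, k);
          const double dExy = (Ex[ID3(i, JPY(j), k)] - Ex[q]) / dx;
          const double dEyx = (Ey[ID3(IPX(i), j, k)] - Ey[q]) / dx;
          Hz[q] += dt * (dExy - dEyx);
        }
    }

    // TF/SF H corrections at ks - 1/2
    if (polx) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          Hy[ID3(i, j, ks - 1)] += cH * aux.e[ks];
    } else {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          Hx[ID3(i, j, ks - 1)] -= cH * aux.e[ks];
    }

    aux.stepE(tE);

    // E updates (interior in z)
    for (int k = 1; k < nz - 1; ++k) {
      const double be = pz.bE[k], ae = pz.aE[k];
      const bool inPml = (ae != 0.0 || be != 1.0);
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const size_t q = ID3(i, j, k);
          const double ieps = dt / eps[q];
          // Ex(i+1/2,j,k) += dt/eps [ (Hz(j+1/2)-Hz(j-1/2))/dx - (Hy(k+1/2)-Hy(k-1/2))/dx ]
          {
            const double dHzy = (Hz[q] - Hz[ID3(i, JMY(j), k)]) / dx;
            const double dHyz = (Hy[q] - Hy[ID3(i, j, k - 1)]) / dx;
            double dd = dHyz;
            if (inPml) { psiExz[q] = be * psiExz[q] + ae * dHyz; dd += psiExz[q]; }
            Ex[q] += ieps * (dHzy - dd);
          }
          // Ey(i,j+1/2,k) += dt/eps [ (Hx(k+1/2)-Hx(k-1/2))/dx - (Hz(i+1/2)-Hz(i-1/2))/dx ]
          {
            const double dHxz = (Hx[q] - Hx[ID3(i, j, k - 1)]) / dx;
            const double dHzx = (Hz[q] - Hz[ID3(IMX(i), j, k)]) / dx;
            double dd = dHxz;
            if (inPml) { psiEyz[q] = be * psiEyz[q] + ae * dHxz; dd += psiEyz[q]; }
            Ey[q] += ieps * (dd - dHzx);
          }
          // Ez(i,j,k+1/2) += dt/eps [ (Hy(i+1/2)-Hy(i-1/2))/dx - (Hx(j+1/2)-Hx(j-1/2))/dx ]
          {
            const double dHyx = (Hy[q] - Hy[ID3(IMX(i), j, k)]) / dx;
            const double dHxy = (Hx[q] - Hx[ID3(i, JMY(j), k)]) / dx;
            Ez[q] += ieps * (dHyx - dHxy);
          }
        }
      }
    }

    // TF/SF E corrections at ks
    if (polx) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const size_t q = ID3(i, j, ks);
          Ex[q] += dt / (eps[q] * dx) * aux.h[ks - 1];
        }
    } else {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const size_t q = ID3(i, j, ks);
          Ey[q] -= dt / (eps[q] * dx) * aux.h[ks - 1];
        }
    }

    if (stp >= wstart) {
      const double c = std::cos(omega * tE), s = std::sin(omega * tE);
      win.acc(c, s);
      phAcc(exRe, exIm, Ex.data() + (size_t)kexit * NP, (int)NP, c, s);
      phAcc(eyRe, eyIm, Ey.data() + (size_t)kexit * NP, (int)NP, c, s);
      phAcc(rxRe, rxIm, Ex.data() + (size_t)krefl * NP, (int)NP, c, s);
      phAcc(ryRe, ryIm, Ey.data() + (size_t)krefl * NP, (int)NP, c, s);
      auxExitRe += aux.e[kexit] * c; auxExitIm += aux.e[kexit] * s;
      auxReflRe += aux.e[krefl] * c; auxReflIm += aux.e[krefl] * s;
    }
    if (stp % checkEvery == 0) {
      double en = 0.0;
      const double* base = polx ? Ex.data() : Ey.data();
      for (size_t q = 0; q < N; ++q) en += base[q] * base[q];
      energy.push_back(en);
      if (!R_finite(en) || en > 1e12 * (double)N)
        stop("FDTD instability detected: field energy diverged");
      Rcpp::checkUserInterrupt();
    }
  }
  #undef ID3
  #undef IPX
  #undef IMX
  #undef JPY
  #undef JMY

  ComplexMatrix exitEx(nx, ny), exitEy(nx, ny), reflEx(nx, ny), reflEy(nx, ny);
  for (size_t q = 0; q < NP; ++q) {
    std::complex<double> z;
    z = win.solve(exRe[q], exIm[q]); exitEx[q].r = z.real(); exitEx[q].i = z.imag();
    z = win.solve(eyRe[q], eyIm[q]); exitEy[q].r = z.real(); exitEy[q].i = z.imag();
    z = win.solve(rxRe[q], rxIm[q]); reflEx[q].r = z.real(); reflEx[q].i = z.imag();
    z = win.solve(ryRe[q], ryIm[q]); reflEy[q].r = z.real(); reflEy[q].i = z.imag();
  }
  return List::create(
    _["exitEx"] = exitEx, _["exitEy"] = exitEy,
    _["reflEx"] = reflEx, _["reflEy"] = reflEy,
    _["incExit"] = win.solve(auxExitRe, auxExitIm),
    _["incRefl"] = win.solve(auxReflRe, auxReflIm),
    _["energy"] = wrap(energy),
    _["steps"] = (double)nsteps, _["dt"] = dt);
}
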