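// First-order k-space pseudospectral acoustic solver (homogeneous 2D medium).
//
// State: pressure p at integer time steps, particle velocity (ux, uy) on
// spatially staggered grids at half time steps, and the density field split
// into rhox/rhoy so a split-field PML can damp each direction independently.
// Spectral derivative multipliers (with the k-space dispersion correction
// sinc(c|k|dt/2) and the +/- dx/2 staggering shifts) are precomputed in R and
// passed in combined Hermitian-packed form:
//   C1 = Mx_p + i*My_p            -> one inverse FFT yields (dp/dx, dp/dy)
//   A  = (Mx_u + My_u)/2, B = (Mx_u - My_u)/2
//      with U = fft(ux + i*uy):   -> ifft(A.*U + B.*conj(U(-k))) yields
//                                    (dux/dx, duy/dy) in its (re, im) parts.
// Both tricks rely on the multipliers being Hermitian (M(-k) = conj(M(k))),
// which holds for the staggered spectral derivative including the Nyquist bin.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline void conj_flip(const cx_mat& U, const uvec& flipidx, cx_mat& out) {
  const std::complex<double>* src = U.memptr();
  std::complex<double>* dst = out.memptr();
  const uword n = U.n_elem;
  for (uword i = 0; i < n; ++i) dst[i] = std::conj(src[flipidx[i]]);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List kspace_run_cpp(const arma::mat& p0,
                          const arma::cx_mat& C1,
                          const arma::cx_mat& A,
                          const arma::cx_mat& B,
                          const arma::uvec& flipidx,
                          const arma::mat& PX, const arma::mat& PXS,
                          const arma::mat& PY, const arma::mat& PYS,
                          double dt, double rho0, double c2,
                          int nt,
                          const arma::uvec& sensor_idx,
                          bool record,
                          const arma::mat& tr_series,
                          bool tr_mode,
                          bool record_energy) {
  const uword N = p0.n_rows;
  const uword ns = sensor_idx.n_elem;
  const double dtrho = dt / rho0;

  mat p = p0, ux(N, N, fill::zeros), uy(N, N, fill::zeros);
  mat rhox = p0 / (2.0 * c2), rhoy = p0 / (2.0 * c2);
  mat ux_prev, uy_prev;
  const mat zero(N, N, fill::zeros);
  cx_mat U(N, N), Uf(N, N), G(N, N), D(N, N);

  mat series;
  if (record) {
    series.set_size(ns, nt);
    for (uword m = 0; m < ns; ++m) series(m, 0) = p(sensor_idx[m]);
  }
  if (tr_mode) {
    // Dirichlet enforcement of the (already time-reversed) recorded data,
    // mirroring the recording convention at t = 0.
    for (uword m = 0; m < ns; ++m) {
      double s = tr_series(m, 0);
      p(sensor_idx[m]) = s;
      rhox(sensor_idx[m]) = s / (2.0 * c2);
      rhoy(sensor_idx[m]) = s / (2.0 * c2);
    }
  }

  const int nsteps = nt - 1;
  vec energy;
  if (record_energy) energy.set_size(nsteps);

  double pot = 0.0;
  for (int t = 0; t < nsteps; ++t) {
    // pressure gradient on the staggered grids
    G = ifft2(C1 % fft2(cx_mat(p, zero)));
    const double fac = (t == 0 && !tr_mode) ? 0.5 * dtrho : dtrho; // leapfrog half-start
    if (record_energy) {
      ux_prev = ux; uy_prev = uy;
      pot = accu(square(p)) / (2.0 * rho0 * c2); // p^n, bracketed by u^(n -/+ 1/2)
    }
    ux = PXS % (PXS % ux - fac * real(G));
    uy = PYS % (PYS % uy - fac * imag(G));

    // x/y components of the velocity divergence
    U = fft2(cx_mat(ux, uy));
    conj_flip(U, flipidx, Uf);
    D = ifft2(A % U + B % Uf);
    rhox = PX % (PX % rhox - (dt * rho0) * real(D));
    rhoy = PY % (PY % rhoy - (dt * rho0) * imag(D));
    p = c2 * (rhox + rhoy);

    if (tr_mode) {
      const uword col = std::min<uword>((uword)t + 1, tr_series.n_cols - 1);
      for (uword m = 0; m < ns; ++m) {
        double s = tr_series(m, col);
        p(sensor_idx[m]) = s;
        rhox(sensor_idx[m]) = s / (2.0 * c2);
        rhoy(sensor_idx[m]) = s / (2.0 * c2);
      }
    }
    if (record) for (uword m = 0; m < ns; ++m) series(m, t + 1) = p(sensor_idx[m]);
    if (record_energy) {
      // discrete leapfrog invariant: kinetic term uses the product of the
      // two half-step velocities bracketing the pressure sample p^n
      double kin = 0.5 * rho0 * (accu(ux_prev % ux) + accu(uy_prev % uy));
      energy[t] = pot + kin;
    }
  }

  return Rcpp::List::create(Rcpp::Named("p") = p,
                            Rcpp::Named("series") = series,
                            Rcpp::Named("energy") = energy);
}
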