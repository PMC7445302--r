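#include <Rcpp.h>
using namespace Rcpp;

// Harmonic bond forces F = -k (|r| - r0) rhat, accumulated per bead.
static void harmonic_forces(const NumericMatrix& x, const IntegerMatrix& bonds,
                            double k, double r0, NumericMatrix& f) {
  std::fill(f.begin(), f.end(), 0.0);
  const int d = x.ncol();
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = bonds(b, 0), j = bonds(b, 1);
    double r2 = 0.0;
    for (int c = 0; c < d; ++c) {
      const double dx = x(j, c) - x(i, c);
      r2 += dx * dx;
    }
    const double r = std::sqrt(r2);
    if (r < 1e-12)
      stop("zero-length bond between beads %d and %d", i + 1, j + 1);
    const double mag = k * (r - r0) / r; // >0 pulls i towards j
    for (int c = 0; c < d; ++c) {
      const double dx = x(j, c) - x(i, c);
      f(i, c) += mag * dx;
      f(j, c) -= mag * dx;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix bonded_forces_cpp(NumericMatrix x, IntegerMatrix bonds,
                                double k, double r0) {
  NumericMatrix f(x.nrow(), x.ncol());
  harmonic_forces(x, bonds, k, r0, f);
  return f;
}

// Langevin dynamics: velocity half-kicks around an analytically exact joint
// (x, v) Ornstein-Uhlenbeck substep over dt (Langevin-impulse scheme).
// Coefficients use expm1 to avoid cancellation at small zeta*dt/m.
// Noise comes from R's RNG (norm_rand) so set.seed() governs trajectories.
// [[Rcpp::export]]
List langevin_run_cpp(NumericMatrix x0, NumericMatrix v0, IntegerMatrix bonds,
                      double k, double r0, double zeta, double dt, double kT,
                      double mass, int nsteps, int sample_every) {
  const int M = x0.nrow(), d = x0.ncol();
  NumericMatrix x = clone(x0), v = clone(v0), f(M, d);

  const double gamma = zeta / mass;
  const double gh = gamma * dt;
  const double e = -std::expm1(-gh); // 1 - exp(-gh), accurate
  const double c1 = 1.0 - e;
  const double var_v = kT / mass * (2.0 * e - e * e);
  const double var_x = kT / mass / (gamma * gamma) * (2.0 * (gh - e) - e * e);
  const double cov_xv = kT / mass / gamma * e * e;
  const double sv = std::sqrt(var_v);
  const double a_xv = cov_xv / var_v;
  const double sx = std::sqrt(std::max(0.0, var_x - cov_xv * cov_xv / var_v));
  const double xdrift = e / gamma;
  const double hk = 0.5 * dt / mass; // half-kick factor

  const int nb = bonds.nrow();
  const int nframes = sample_every > 0 ? nsteps / sample_every : 0;
  List frames(nframes);
  NumericVector ke(nframes), bond_mean(nframes), bond_msd(nframes);
  IntegerVector frame_step(nframes);
  int fr = 0;

  RNGScope scope;
  harmonic_forces(x, bonds, k, r0, f);
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < M; ++i)
      for (int c = 0; c < d; ++c)
        v(i, c) += hk * f(i, c);
    for (int i = 0; i < M; ++i) {
      for (int c = 0; c < d; ++c) {
        const double xiv = sv * norm_rand();
        const double xix = a_xv * xiv + sx * norm_rand();
        x(i, c) += xdrift * v(i, c) + xix;
        v(i, c) = c1 * v(i, c) + xiv;
      }
    }
    harmonic_forces(x, bonds, k, r0, f);
    for (int i = 0; i < M; ++i)
      for (int c = 0; c < d; ++c)
        v(i, c) += hk * f(i, c);

    if (!R_finite(x(0, 0)) || !R_finite(v(0, 0)))
      stop("non-finite coordinates at step %d", step + 1);

    if (sample_every > 0 && (step + 1) % sample_every == 0) {
      double kin = 0.0;
      for (int i = 0; i < M; ++i)
        for (int c = 0; c < d; ++c) {
          if (!R_finite(x(i, c)))
            stop("non-finite coordinates at step %d", step + 1);
          kin += v(i, c) * v(i, c);
        }
      double bm = 0.0, bs = 0.0;
      for (int b = 0; b < nb; ++b) {
        double r2 = 0.0;
        for (int c = 0; c < d; ++c) {
          const double dx = x(bonds(b, 1), c) - x(bonds(b, 0), c);
          r2 += dx * dx;
        }
        const double r = std::sqrt(r2);
        bm += r;
        bs += (r - r0) * (r - r0);
      }
      frames[fr] = clone(x);
      ke[fr] = 0.5 * mass * kin;
      bond_mean[fr] = bm / nb;
      bond_msd[fr] = bs / nb;
      frame_step[fr] = step + 1;
      ++fr;
    }
  }

  return List::create(
    _["x"] = x, _["v"] = v, _["frames"] = frames, _["ke"] = ke,
    _["bond_mean"] = bond_mean, _["bond_msd"] = bond_msd,
    _["frame_step"] = frame_step);
}
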