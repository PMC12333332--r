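// Computational core: Kabsch RMSD, ion-gas interaction potential,
// classical scattering trajectories, trajectory-method and
// projection-approximation collision cross sections.
//
// Unit system: length Angstrom, energy kcal/mol, mass Da, charge e,
// time fs.  1 kcal/mol = 4.184e-4 Da A^2/fs^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double KCAL_AKMA = 4.184e-4;   // kcal/mol -> Da A^2 fs^-2
static const double KB_KCAL   = 0.0019872041; // kcal/(mol K)
static const double COULOMB_K = 332.0637;   // kcal A / (mol e^2)

// ---------------------------------------------------------------------------
// Deterministic RNG (splitmix64): platform-independent, cheap, seedable per
// stream so per-cycle results do not depend on how many cycles precede them.
// ---------------------------------------------------------------------------
struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

static uint64_t mix_seed(uint64_t master, uint64_t stream) {
  SplitMix s(master * 0x9e3779b97f4a7c15ULL + stream + 1ULL);
  s.next();
  return s.next();
}

// Uniform random rotation matrix (Shoemake quaternion method).
static arma::mat33 random_rotation(SplitMix &rng) {
  double u1 = rng.unif(), u2 = rng.unif(), u3 = rng.unif();
  double a = std::sqrt(1.0 - u1), b = std::sqrt(u1);
  double qx = a * std::sin(2.0 * M_PI * u2);
  double qy = a * std::cos(2.0 * M_PI * u2);
  double qz = b * std::sin(2.0 * M_PI * u3);
  double qw = b * std::cos(2.0 * M_PI * u3);
  arma::mat33 R;
  R(0,0) = 1 - 2*(qy*qy + qz*qz); R(0,1) = 2*(qx*qy - qz*qw); R(0,2) = 2*(qx*qz + qy*qw);
  R(1,0) = 2*(qx*qy + qz*qw); R(1,1) = 1 - 2*(qx*qx + qz*qz); R(1,2) = 2*(qy*qz - qx*qw);
  R(2,0) = 2*(qx*qz - qy*qw); R(2,1) = 2*(qy*qz + qx*qw); R(2,2) = 1 - 2*(qx*qx + qy*qy);
  return R;
}

// ---------------------------------------------------------------------------
// RMSD (Kabsch optimal superposition, rotations only, no reflection)
// ---------------------------------------------------------------------------
static double kabsch_rmsd(const arma::mat &A, const arma::mat &B) {
  const arma::uword n = A.n_rows;
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat X = A.each_row() - ca;
  arma::mat Y = B.each_row() - cb;
  arma::mat H = X.t() * Y;           // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t()) < 0.0 ? -1.0 : 1.0;
  double e0 = arma::accu(X % X) + arma::accu(Y % Y);
  double msd = (e0 - 2.0 * (s(0) + s(1) + d * s(2))) / double(n);
  return std::sqrt(std::max(msd, 0.0));
}

// [[Rcpp::export]]
double rmsd_kabsch_cpp(const arma::mat &a, const arma::mat &b) {
  return kabsch_rmsd(a, b);
}

// [[Rcpp::export]]
arma::mat rmsd_matrix_cpp(const Rcpp::List &coords) {
  const int n = coords.size();
  std::vector<arma::mat> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = Rcpp::as<arma::mat>(coords[i]);
  arma::mat D(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      D(i, j) = D(j, i) = kabsch_rmsd(xs[i], xs[j]);
  return D;
}

// ---------------------------------------------------------------------------
// Ion-gas interaction potential: sum of per-atom 12-6 Lennard-Jones terms
// plus the charge-induced-dipole term -(k alpha/2) |E|^2, where E is the
// Coulomb field of the partial charges at the probe.
// ---------------------------------------------------------------------------
struct Potential {
  arma::mat coords;       // n x 3
  arma::vec eps, rmin, q; // per-atom
  double alpha;           // gas polarizability, A^3
  bool has_charge;

  Potential(const arma::mat &c, const arma::vec &e, const arma::vec &rm,
            const arma::vec &qq, double a)
    : coords(c), eps(e), rmin(rm), q(qq), alpha(a) {
    has_charge = arma::any(arma::abs(q) > 0.0) && alpha > 0.0;
  }

  // energy and gradient with respect to the probe position
  double eval(const arma::vec3 &p, arma::vec3 &grad) const {
    double V = 0.0;
    grad.zeros();
    arma::vec3 field; field.zeros();
    arma::mat33 J; J.zeros();
    const arma::uword n = coords.n_rows;
    for (arma::uword a = 0; a < n; ++a) {
      arma::vec3 d = p - coords.row(a).t();
      double r2 = arma::dot(d, d);
      double r = std::sqrt(r2);
      double sr2 = (rmin(a) * rmin(a)) / r2;
      double sr6 = sr2 * sr2 * sr2;
      V += eps(a) * (sr6 * sr6 - 2.0 * sr6);
      double dVdr = (12.0 * eps(a) / r) * (sr6 - sr6 * sr6);
      grad += (dVdr / r) * d;
      if (has_charge && q(a) != 0.0) {
        double r3 = r2 * r, r5 = r3 * r2;
        field += q(a) * d / r3;
        // d field / d probe
        J += q(a) * (arma::eye(3, 3) / r3 - 3.0 * (d * d.t()) / r5);
      }
    }
    if (has_charge) {
      double f2 = arma::dot(field, field);
      V -= 0.5 * COULOMB_K * alpha * f2;
      grad -= COULOMB_K * alpha * (J * field); // J symmetric
    }
    return V;
  }

  double energy(const arma::vec3 &p) const {
    arma::vec3 g;
    return eval(p, g);
  }
};

// [[Rcpp::export]]
Rcpp::List ion_gas_potential_cpp(const arma::mat &coords, const arma::vec &eps,
                                 const arma::vec &rmin, const arma::vec &q,
                                 double alpha, const arma::vec &probe) {
  Potential pot(coords, eps, rmin, q, alpha);
  arma::vec3 g;
  arma::vec3 p = probe.subvec(0, 2);
  double V = pot.eval(p, g);
  return Rcpp::List::create(Rcpp::Named("energy") = V,
                            Rcpp::Named("gradient") = arma::vec(g));
}

// ---------------------------------------------------------------------------
// Classical scattering trajectory: a gas pseudo-atom of (reduced) mass m
// approaches the frozen ion along -z with impact parameter b and speed g.
// Velocity-Verlet with a local adaptive step; returns the deflection angle.
// ---------------------------------------------------------------------------
struct TrajResult {
  double chi;
  double drift;    // relative energy drift
  bool orbiting;
  int steps;
};

static double min_atom_dist(const Potential &pot, const arma::vec3 &p) {
  double dmin = std::numeric_limits<double>::infinity();
  for (arma::uword a = 0; a < pot.coords.n_rows; ++a) {
    double d = arma::norm(p - pot.coords.row(a).t());
    if (d < dmin) dmin = d;
  }
  return dmin;
}

// pick a start distance where the potential is negligible against the
// collision energy (long-range induced-dipole tail decays as r^-4)
static double start_distance(const Potential &pot, double extent, double ke) {
  double r = extent + 10.0;
  double tol = std::max(1e-9 * ke, 1e-12);
  for (int it = 0; it < 60; ++it) {
    arma::vec3 p = {0.0, 0.0, r};
    arma::vec3 p2 = {r, 0.0, 0.0};
    double v = std::max(std::fabs(pot.energy(p)), std::fabs(pot.energy(p2)));
    if (v < tol) break;
    r *= 1.35;
    if (r > 600.0) break;
  }
  return r;
}

static TrajResult integrate_trajectory(const Potential &pot, double mass,
                                       double b, double g, double eta,
                                       int max_steps, double r_start) {
  TrajResult out{0.0, 0.0, false, 0};
  if (b >= r_start) r_start = 1.05 * b + 5.0;
  double z0 = std::sqrt(std::max(r_start * r_start - b * b, 1.0));
  arma::vec3 pos = {b, 0.0, z0};
  arma::vec3 vel = {0.0, 0.0, -g};
  arma::vec3 grad;
  double V = pot.eval(pos, grad);
  arma::vec3 acc = -grad * (KCAL_AKMA / mass);
  double ke0 = 0.5 * mass * g * g / KCAL_AKMA;
  double e0 = ke0 + V;
  double r_exit = r_start;
  int step = 0;
  for (; step < max_steps; ++step) {
    double dmin = min_atom_dist(pot, pos);
    double vmag = arma::norm(vel);
    double amag = arma::norm(acc);
    double dt_v = dmin / std::max(vmag, 1e-12);
    double dt_a = std::sqrt(dmin / std::max(amag, 1e-12));
    double dt = eta * std::min(dt_v, dt_a);
    // velocity Verlet
    pos += vel * dt + 0.5 * acc * dt * dt;
    arma::vec3 grad_new;
    V = pot.eval(pos, grad_new);
    arma::vec3 acc_new = -grad_new * (KCAL_AKMA / mass);
    vel += 0.5 * (acc + acc_new) * dt;
    acc = acc_new;
    double r = arma::norm(pos);
    if (r > r_exit && arma::dot(pos, vel) > 0.0) break;
  }
  double ke = 0.5 * mass * arma::dot(vel, vel) / KCAL_AKMA;
  out.drift = std::fabs((ke + V) - e0) / std::max(ke0, 1e-300);
  out.steps = step;
  if (step >= max_steps) {
    out.orbiting = true;
    out.chi = M_PI;
    return out;
  }
  double c = -vel(2) / std::max(arma::norm(vel), 1e-300); // vs incoming -z
  c = std::min(1.0, std::max(-1.0, c));
  out.chi = std::acos(c);
  return out;
}

// with energy-drift control: halve eta until drift within tolerance
static TrajResult shoot(const Potential &pot, double mass, double b, double g,
                        double eta, int max_steps, double r_start,
                        double drift_tol) {
  double e = eta;
  TrajResult res = integrate_trajectory(pot, mass, b, g, e, max_steps, r_start);
  for (int k = 0; k < 4 && !res.orbiting && res.drift > drift_tol; ++k) {
    e *= 0.5;
    res = integrate_trajectory(pot, mass, b, g, e, max_steps, r_start);
  }
  return res;
}

// [[Rcpp::export]]
Rcpp::List deflection_angle_cpp(const arma::mat &coords, const arma::vec &eps,
                                const arma::vec &rmin, const arma::vec &q,
                                double alpha, double mass, double b, double g,
                                double eta, int max_steps) {
  Potential pot(coords, eps, rmin, q, alpha);
  double extent = 0.0;
  for (arma::uword a = 0; a < coords.n_rows; ++a)
    extent = std::max(extent, arma::norm(coords.row(a)));
  double ke = 0.5 * mass * g * g / KCAL_AKMA;
  double r0 = start_distance(pot, extent + arma::max(rmin) * 3.0, ke);
  TrajResult res = shoot(pot, mass, b, g, eta, max_steps, r0, 1e-4);
  return Rcpp::List::create(Rcpp::Named("chi") = res.chi,
                            Rcpp::Named("energy_drift") = res.drift,
                            Rcpp::Named("orbiting") = res.orbiting,
                            Rcpp::Named("steps") = res.steps);
}

// smallest b (at a given speed) where |chi| < 1e-3 over a fixed set of
// probe orientations; doubling search then bisection
static double find_bmax(const Potential &pot,
                        const std::vector<arma::mat> &rots, double mass,
                        double g, double eta, int max_steps, double r0,
                        double extent, double b_start) {
  auto max_chi = [&](double b) {
    double m = 0.0;
    for (size_t i = 0; i < rots.size(); ++i) {
      Potential p2(rots[i], pot.eps, pot.rmin, pot.q, pot.alpha);
      TrajResult r = shoot(p2, mass, b, g, eta, max_steps, r0, 1e-4);
      m = std::max(m, std::fabs(r.chi));
    }
    return m;
  };
  double b_lo = std::max(extent + 1.0, 0.25 * b_start), b_hi = b_lo;
  while (max_chi(b_hi) > 1e-3 && b_hi < 500.0) {
    b_lo = b_hi;
    b_hi *= 2.0;
  }
  for (int it = 0; it < 8; ++it) {
    double mid = 0.5 * (b_lo + b_hi);
    if (max_chi(mid) > 1e-3) b_lo = mid; else b_hi = mid;
  }
  return b_hi;
}

// ---------------------------------------------------------------------------
// Trajectory-method CCS: temperature-averaged collision integral Omega(1,1).
// Relative speeds from a Gauss-Legendre quadrature on the reduced speed
// gamma = g sqrt(mu / 2 kT) with weight gamma^5 exp(-gamma^2); impact
// parameters area-uniform in [0, bmax^2]; integrand (1 - cos chi).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List tm_ccs_cpp(const arma::mat &coords, const arma::vec &eps,
                      const arma::vec &rmin, const arma::vec &q, double alpha,
                      double mass, double temperature, int n_cycles,
                      const arma::vec &gl_nodes, const arma::vec &gl_weights,
                      int n_mc, double seed, double eta, int max_steps,
                      int n_orient_bmax) {
  // recentre on the geometric centre so b is referenced to the body frame
  arma::mat C = coords;
  arma::rowvec ctr = arma::mean(C, 0);
  C.each_row() -= ctr;
  Potential pot(C, eps, rmin, q, alpha);
  uint64_t mseed = (uint64_t)seed;

  const int n_vel = gl_nodes.n_elem;
  double g_scale = std::sqrt(2.0 * KB_KCAL * temperature * KCAL_AKMA / mass);
  arma::vec w(n_vel);
  for (int k = 0; k < n_vel; ++k) {
    double gam = gl_nodes(k);
    w(k) = gl_weights(k) * std::pow(gam, 5) * std::exp(-gam * gam);
  }
  double wsum = arma::accu(w);

  double extent = 0.0;
  for (arma::uword a = 0; a < C.n_rows; ++a)
    extent = std::max(extent, arma::norm(C.row(a)));
  double ke_typ = KB_KCAL * temperature;
  double r0 = start_distance(pot, extent + arma::max(rmin) * 3.0, ke_typ);

  // per-velocity-node maximum impact parameter (|chi| < 1e-3 rule) probed
  // over a fixed orientation set; nodes are ascending in speed, so each
  // search starts from the previous (slower) node's value
  SplitMix rng_b(mix_seed(mseed, 0xB0ULL));
  std::vector<arma::mat> rots(n_orient_bmax);
  for (int i = 0; i < n_orient_bmax; ++i)
    rots[i] = C * random_rotation(rng_b).t();
  arma::vec bmax(n_vel);
  double b_prev = extent + 8.0;
  for (int k = 0; k < n_vel; ++k) {
    double g = gl_nodes(k) * g_scale;
    bmax(k) = find_bmax(pot, rots, mass, g, eta, max_steps, r0, extent,
                        b_prev);
    b_prev = bmax(k);
  }
  double bmax_all = bmax.max();
  if (bmax_all > r0) r0 = bmax_all + 10.0;

  arma::vec omega_c(n_cycles);
  long n_traj = 0, n_orbit = 0;
  for (int c = 0; c < n_cycles; ++c) {
    SplitMix rng(mix_seed(mseed, (uint64_t)(c + 1)));
    double acc_cycle = 0.0;
    for (int k = 0; k < n_vel; ++k) {
      double g = gl_nodes(k) * g_scale;
      double s = 0.0;
      for (int j = 0; j < n_mc; ++j) {
        arma::mat Crot = C * random_rotation(rng).t();
        Potential prot(Crot, eps, rmin, q, alpha);
        // stratified area-uniform impact parameters: one draw per equal
        // annulus of b^2 with a random offset (unbiased, low variance)
        double b = bmax(k) * std::sqrt((j + rng.unif()) / n_mc);
        TrajResult res = shoot(prot, mass, b, g, eta, max_steps, r0, 1e-4);
        s += 1.0 - std::cos(res.chi);
        ++n_traj;
        if (res.orbiting) ++n_orbit;
      }
      double Qk = M_PI * bmax(k) * bmax(k) * (s / n_mc);
      acc_cycle += w(k) * Qk;
    }
    omega_c(c) = acc_cycle / wsum;
  }
  double ccs = arma::mean(omega_c);
  double se = n_cycles > 1 ? arma::stddev(omega_c) / std::sqrt((double)n_cycles)
                           : 0.0;
  return Rcpp::List::create(
      Rcpp::Named("ccs") = ccs, Rcpp::Named("std_error") = se,
      Rcpp::Named("cycle_values") = arma::vec(omega_c),
      Rcpp::Named("b_max") = arma::vec(bmax),
      Rcpp::Named("orbit_fraction") = (double)n_orbit / (double)n_traj);
}

// ---------------------------------------------------------------------------
// Projection approximation: Monte-Carlo shadow area averaged over uniform
// random orientations; per-atom collision radii supplied by the caller.
// ---------------------------------------------------------------------------
// first orientation of the PA stream for a given seed (for tests that need
// the exact projection plane of orientation 1)
// [[Rcpp::export]]
arma::mat pa_orientation_matrix(double seed) {
  SplitMix rng(mix_seed((uint64_t)seed, 0xAAULL));
  return random_rotation(rng);
}

// [[Rcpp::export]]
Rcpp::List pa_ccs_cpp(const arma::mat &coords, const arma::vec &radii,
                      int n_orientations, int n_shots, double seed) {
  arma::mat C = coords;
  arma::rowvec ctr = arma::mean(C, 0);
  C.each_row() -= ctr;
  const arma::uword n = C.n_rows;
  SplitMix rng(mix_seed((uint64_t)seed, 0xAAULL));
  arma::vec areas(n_orientations);
  for (int o = 0; o < n_orientations; ++o) {
    arma::mat R = random_rotation(rng);
    arma::mat P = C * R.t(); // use x, y columns as the projection plane
    double xmin = arma::datum::inf, xmax = -arma::datum::inf;
    double ymin = arma::datum::inf, ymax = -arma::datum::inf;
    for (arma::uword a = 0; a < n; ++a) {
      xmin = std::min(xmin, P(a, 0) - radii(a));
      xmax = std::max(xmax, P(a, 0) + radii(a));
      ymin = std::min(ymin, P(a, 1) - radii(a));
      ymax = std::max(ymax, P(a, 1) + radii(a));
    }
    double box = (xmax - xmin) * (ymax - ymin);
    int hits = 0;
    for (int s = 0; s < n_shots; ++s) {
      double x = xmin + (xmax - xmin) * rng.unif();
      double y = ymin + (ymax - ymin) * rng.unif();
      for (arma::uword a = 0; a < n; ++a) {
        double dx = x - P(a, 0), dy = y - P(a, 1);
        if (dx * dx + dy * dy <= radii(a) * radii(a)) { ++hits; break; }
      }
    }
    areas(o) = box * (double)hits / (double)n_shots;
  }
  double ccs = arma::mean(areas);
  double se = n_orientations > 1
                  ? arma::stddev(areas) / std::sqrt((double)n_orientations)
                  : 0.0;
  return Rcpp::List::create(Rcpp::Named("ccs") = ccs,
                            Rcpp::Named("std_error") = se);
}
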