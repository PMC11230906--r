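// Coarse-grained implicit-solvent engine for K/E polyampholyte slabs.
//
// Pair interactions: Ashbaugh-Hatch scaled Lennard-Jones (hydrophobicity
// scale model) plus Debye-Hueckel screened electrostatics, both energy-
// shifted to zero at their cutoffs. Bonds are harmonic. Dynamics is BAOAB
// Langevin with a counter-based per-bead, per-step RNG so trajectories are
// exactly reproducible and restartable from (seed, step).
//
// Internal units: Angstrom, Dalton, kcal/mol; derived time unit
// sqrt(Da A^2 mol / kcal) = 48.8882 fs. All conversions happen on the R
// side; this file sees internal units only.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0019872041;    // kcal/mol/K
static const double COULOMB = 332.0637;   // kcal A / mol / e^2

// ---------------------------------------------------------------------------
// counter-based RNG: splitmix64 hash of (seed, step, bead) -> N(0,1) draws
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// four N(0,1) values for (seed, step, bead) via two Box-Muller pairs
static inline void gauss4(uint64_t seed, uint64_t step, uint64_t bead,
                          double out[4]) {
  uint64_t h1 = splitmix64(seed ^ splitmix64(step ^ splitmix64(bead)));
  uint64_t h2 = splitmix64(h1);
  uint64_t parts[4] = {h1 & 0xffffffffULL, h1 >> 32,
                       h2 & 0xffffffffULL, h2 >> 32};
  double u[4];
  for (int k = 0; k < 4; ++k) {
    u[k] = (static_cast<double>(parts[k]) + 0.5) / 4294967296.0;
  }
  double r1 = std::sqrt(-2.0 * std::log(u[0]));
  double r2 = std::sqrt(-2.0 * std::log(u[2]));
  out[0] = r1 * std::cos(2.0 * M_PI * u[1]);
  out[1] = r1 * std::sin(2.0 * M_PI * u[1]);
  out[2] = r2 * std::cos(2.0 * M_PI * u[3]);
  out[3] = r2 * std::sin(2.0 * M_PI * u[3]);
}

// ---------------------------------------------------------------------------
// force-field tables
// ---------------------------------------------------------------------------
struct ForceField {
  int n_types;
  std::vector<double> sigma;    // per type
  std::vector<double> lambda;   // per type
  std::vector<double> mass;     // per type
  std::vector<int> is_core;     // per type: purely repulsive scaffold bead
  double eps;                   // pair energy scale (kcal/mol)
  double debye;                 // screening length (A)
  double dielectric;            // relative dielectric
  double rc_lj;                 // short-range cutoff (A)
  double rc_coul;               // electrostatic cutoff (A)
  double bond_k;                // kcal/mol/A^2 (U = 1/2 k (r-r0)^2)
  double bond_r0;               // A

  // precomputed per type-pair
  std::vector<double> sig2_ij, lam_ij, shift_lj_ij;
  double coul_shift_unit;       // exp(-rc/debye)/rc

  // Debye-Hueckel radial term tabulated on a uniform grid in x = r^2 with
  // cubic Hermite interpolation; the interpolated force is the exact
  // derivative of the interpolated energy, so force/energy consistency is
  // preserved to machine-level finite differences.
  static const int TAB_N = 4096;
  double tab_x0, tab_h, tab_inv_h;
  std::vector<double> tab_u, tab_m;   // U(x) and dU/dx at nodes

  // unit-charge DH energy (shifted) and its x-derivative, analytic
  inline double dh_u(double r) const {
    return std::exp(-r / debye) / r - coul_shift_unit;
  }
  inline double dh_dudx(double r) const {
    // dU/dx = U'(r) / (2 r), U'(r) = -exp(-r/debye) (1/(debye r) + 1/r^2)
    return -std::exp(-r / debye) * (1.0 / (debye * r) + 1.0 / (r * r)) /
           (2.0 * r);
  }

  void precompute() {
    sig2_ij.assign(n_types * n_types, 0.0);
    lam_ij.assign(n_types * n_types, 0.0);
    shift_lj_ij.assign(n_types * n_types, 0.0);
    for (int a = 0; a < n_types; ++a) {
      for (int b = 0; b < n_types; ++b) {
        double sij = 0.5 * (sigma[a] + sigma[b]);
        double lij = 0.5 * (lambda[a] + lambda[b]);
        if (is_core[a] || is_core[b]) lij = 0.0;  // scaffold: excluded volume only
        sig2_ij[a * n_types + b] = sij * sij;
        lam_ij[a * n_types + b] = lij;
        // LJ value at the cutoff (cutoff is beyond the minimum by contract)
        double s2 = sij * sij / (rc_lj * rc_lj);
        double s6 = s2 * s2 * s2;
        shift_lj_ij[a * n_types + b] = lij * 4.0 * eps * (s6 * s6 - s6);
      }
    }
    coul_shift_unit = std::exp(-rc_coul / debye) / rc_coul;
    tab_x0 = 1.0;  // r < 1 A falls back to the analytic expression
    tab_h = (rc_coul * rc_coul - tab_x0) / (TAB_N - 1);
    tab_inv_h = 1.0 / tab_h;
    tab_u.resize(TAB_N);
    tab_m.resize(TAB_N);
    for (int i = 0; i < TAB_N; ++i) {
      double x = tab_x0 + i * tab_h;
      double r = std::sqrt(x);
      tab_u[i] = dh_u(r);
      tab_m[i] = dh_dudx(r);
    }
  }

  // Hermite-interpolated (U, dU/dx) at x = r^2
  inline void dh_eval(double x, double& u, double& dudx) const {
    if (x < tab_x0) {
      double r = std::sqrt(x);
      u = dh_u(r);
      dudx = dh_dudx(r);
      return;
    }
    double s = (x - tab_x0) * tab_inv_h;
    int i = static_cast<int>(s);
    if (i >= TAB_N - 1) i = TAB_N - 2;
    double t = s - i;
    double u0 = tab_u[i], u1 = tab_u[i + 1];
    double m0 = tab_m[i] * tab_h, m1 = tab_m[i + 1] * tab_h;
    double t2 = t * t, t3 = t2 * t;
    u = (2 * t3 - 3 * t2 + 1) * u0 + (t3 - 2 * t2 + t) * m0 +
        (-2 * t3 + 3 * t2) * u1 + (t3 - t2) * m1;
    dudx = ((6 * t2 - 6 * t) * (u0 - u1) + (3 * t2 - 4 * t + 1) * m0 +
            (3 * t2 - 2 * t) * m1) * tab_inv_h;
  }
};

static ForceField ff_from_list(const List& ffl) {
  ForceField ff;
  NumericVector sigma = ffl["sigma"], lambda = ffl["lambda"], mass = ffl["mass"];
  IntegerVector is_core = ffl["is_core"];
  ff.n_types = sigma.size();
  ff.sigma.assign(sigma.begin(), sigma.end());
  ff.lambda.assign(lambda.begin(), lambda.end());
  ff.mass.assign(mass.begin(), mass.end());
  ff.is_core.assign(is_core.begin(), is_core.end());
  ff.eps = as<double>(ffl["epsilon"]);
  ff.debye = as<double>(ffl["debye_length"]);
  ff.dielectric = as<double>(ffl["dielectric"]);
  ff.rc_lj = as<double>(ffl["cutoff_lj"]);
  ff.rc_coul = as<double>(ffl["cutoff_coul"]);
  ff.bond_k = as<double>(ffl["bond_k"]);
  ff.bond_r0 = as<double>(ffl["bond_r0"]);
  ff.precompute();
  return ff;
}

// ---------------------------------------------------------------------------
// simulation system
// ---------------------------------------------------------------------------
struct System {
  int n;
  std::vector<double> pos, vel, frc;     // 3n
  std::vector<int> type;                 // 0-based type index
  std::vector<double> charge, mass;
  std::vector<int> bond_i, bond_j;       // 0-based
  std::vector<std::vector<int>> excl;    // bonded (1-2) exclusions
  double box[3];

  // Verlet neighbour list
  double skin;
  std::vector<int> nbr, nbr_start;
  std::vector<double> pos_at_build;

  // accumulated energies / virial from the last force evaluation
  double e_pair, e_bond;
  double virial[3];

  // positions are kept wrapped, so |d| < L and two branches suffice
  // (cheaper than std::round in the hot loop)
  inline double min_image(double d, int ax) const {
    double L = box[ax];
    if (d > 0.5 * L) return d - L;
    if (d < -0.5 * L) return d + L;
    return d;
  }

  void build_neighbours(const ForceField& ff) {
    double rl = std::max(ff.rc_lj, ff.rc_coul) + skin;
    double rl2 = rl * rl;
    nbr_start.assign(n + 1, 0);
    nbr.clear();
    nbr.reserve(64 * n);
    // cell binning along z only (slab boxes are long in z); O(N^2) within
    // candidate sets, adequate for the <= 10^4 bead systems targeted here
    for (int i = 0; i < n; ++i) {
      nbr_start[i] = static_cast<int>(nbr.size());
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(pos[3 * i] - pos[3 * j], 0);
        double dy = min_image(pos[3 * i + 1] - pos[3 * j + 1], 1);
        double dz = min_image(pos[3 * i + 2] - pos[3 * j + 2], 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < rl2) {
          bool ex = false;
          for (int e : excl[i]) if (e == j) { ex = true; break; }
          if (!ex) nbr.push_back(j);
        }
      }
    }
    nbr_start[n] = static_cast<int>(nbr.size());
    pos_at_build = pos;
  }

  bool needs_rebuild() const {
    // displacements must be folded through the periodic boundaries, or a
    // bead wrapping across the box looks like an L-sized jump
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = min_image(pos[3 * i] - pos_at_build[3 * i], 0);
      double dy = min_image(pos[3 * i + 1] - pos_at_build[3 * i + 1], 1);
      double dz = min_image(pos[3 * i + 2] - pos_at_build[3 * i + 2], 2);
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void compute_forces(const ForceField& ff, bool check_overlap) {
    std::fill(frc.begin(), frc.end(), 0.0);
    e_pair = e_bond = 0.0;
    virial[0] = virial[1] = virial[2] = 0.0;
    const double rc_lj2 = ff.rc_lj * ff.rc_lj;
    const double rc_c2 = ff.rc_coul * ff.rc_coul;
    const double cpref = COULOMB / ff.dielectric;
    const int nt = ff.n_types;

    for (int i = 0; i < n; ++i) {
      const double xi = pos[3 * i], yi = pos[3 * i + 1], zi = pos[3 * i + 2];
      const int ti = type[i];
      const double qi = charge[i];
      for (int k = nbr_start[i]; k < nbr_start[i + 1]; ++k) {
        const int j = nbr[k];
        double dx = min_image(xi - pos[3 * j], 0);
        double dy = min_image(yi - pos[3 * j + 1], 1);
        double dz = min_image(zi - pos[3 * j + 2], 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc_c2 && r2 >= rc_lj2) continue;
        const int tp = ti * nt + type[j];
        double fpair = 0.0;  // force factor: F_vec = fpair * d_vec
        if (r2 < rc_lj2) {
          double sig2 = ff.sig2_ij[tp];
          if (check_overlap && r2 < 0.04 * sig2) {
            stop("overlapping beads %d and %d (r = %.3f A)", i + 1, j + 1,
                 std::sqrt(r2));
          }
          double inv_r2 = 1.0 / r2;
          double s2 = sig2 * inv_r2;
          double s6 = s2 * s2 * s2;
          double s12 = s6 * s6;
          double ulj = 4.0 * ff.eps * (s12 - s6);
          double flj = 24.0 * ff.eps * (2.0 * s12 - s6) * inv_r2;
          double lam = ff.lam_ij[tp];
          if (s6 > 0.5) {  // r < 2^(1/6) sigma: repulsive core region
            e_pair += ulj + (1.0 - lam) * ff.eps - ff.shift_lj_ij[tp];
            fpair += flj;
          } else {
            e_pair += lam * ulj - ff.shift_lj_ij[tp];
            fpair += lam * flj;
          }
        }
        double qq = qi * charge[j];
        if (qq != 0.0 && r2 < rc_c2) {
          double u, dudx;
          ff.dh_eval(r2, u, dudx);
          double pref = cpref * qq;
          e_pair += pref * u;
          fpair += pref * (-2.0 * dudx);
        }
        if (fpair != 0.0) {
          double fx = fpair * dx, fy = fpair * dy, fz = fpair * dz;
          frc[3 * i] += fx;       frc[3 * i + 1] += fy;   frc[3 * i + 2] += fz;
          frc[3 * j] -= fx;       frc[3 * j + 1] -= fy;   frc[3 * j + 2] -= fz;
          virial[0] += fx * dx;   virial[1] += fy * dy;   virial[2] += fz * dz;
        }
      }
    }

    for (size_t b = 0; b < bond_i.size(); ++b) {
      int i = bond_i[b], j = bond_j[b];
      double dx = min_image(pos[3 * i] - pos[3 * j], 0);
      double dy = min_image(pos[3 * i + 1] - pos[3 * j + 1], 1);
      double dz = min_image(pos[3 * i + 2] - pos[3 * j + 2], 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - ff.bond_r0;
      e_bond += 0.5 * ff.bond_k * dr * dr;
      double fpair = -ff.bond_k * dr / r;   // F_vec on i = fpair * d_vec
      double fx = fpair * dx, fy = fpair * dy, fz = fpair * dz;
      frc[3 * i] += fx;       frc[3 * i + 1] += fy;   frc[3 * i + 2] += fz;
      frc[3 * j] -= fx;       frc[3 * j + 1] -= fy;   frc[3 * j + 2] -= fz;
      virial[0] += fx * dx;   virial[1] += fy * dy;   virial[2] += fz * dz;
    }
  }

  double kinetic_energy() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      ke += 0.5 * mass[i] * (vel[3 * i] * vel[3 * i] +
                             vel[3 * i + 1] * vel[3 * i + 1] +
                             vel[3 * i + 2] * vel[3 * i + 2]);
    }
    return ke;
  }

  void pressure_tensor(double p[3]) const {
    double v = box[0] * box[1] * box[2];
    double kin[3] = {0.0, 0.0, 0.0};
    for (int i = 0; i < n; ++i) {
      kin[0] += mass[i] * vel[3 * i] * vel[3 * i];
      kin[1] += mass[i] * vel[3 * i + 1] * vel[3 * i + 1];
      kin[2] += mass[i] * vel[3 * i + 2] * vel[3 * i + 2];
    }
    for (int a = 0; a < 3; ++a) p[a] = (kin[a] + virial[a]) / v;
  }

  void wrap() {
    for (int i = 0; i < n; ++i) {
      for (int a = 0; a < 3; ++a) {
        double& x = pos[3 * i + a];
        x -= box[a] * std::floor(x / box[a]);
      }
    }
  }
};

static System system_from_args(const NumericMatrix& positions,
                               const NumericVector& box,
                               const IntegerVector& type,
                               const NumericVector& charge,
                               const IntegerMatrix& bonds,
                               const ForceField& ff) {
  System sys;
  sys.n = positions.nrow();
  sys.pos.resize(3 * sys.n);
  sys.vel.assign(3 * sys.n, 0.0);
  sys.frc.assign(3 * sys.n, 0.0);
  for (int i = 0; i < sys.n; ++i) {
    sys.pos[3 * i] = positions(i, 0);
    sys.pos[3 * i + 1] = positions(i, 1);
    sys.pos[3 * i + 2] = positions(i, 2);
  }
  sys.type.assign(type.begin(), type.end());
  sys.charge.assign(charge.begin(), charge.end());
  sys.mass.resize(sys.n);
  for (int i = 0; i < sys.n; ++i) sys.mass[i] = ff.mass[sys.type[i]];
  for (int a = 0; a < 3; ++a) sys.box[a] = box[a];
  sys.excl.assign(sys.n, {});
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    sys.bond_i.push_back(i);
    sys.bond_j.push_back(j);
    sys.excl[std::min(i, j)].push_back(std::max(i, j));
    sys.excl[std::max(i, j)].push_back(std::min(i, j));
  }
  sys.skin = 4.0;
  return sys;
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix positions, NumericVector box,
                        IntegerVector type, NumericVector charge,
                        IntegerMatrix bonds, List ffl,
                        bool check_overlap = true) {
  ForceField ff = ff_from_list(ffl);
  System sys = system_from_args(positions, box, type, charge, bonds, ff);
  sys.build_neighbours(ff);
  sys.compute_forces(ff, check_overlap);
  NumericMatrix forces(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    forces(i, 0) = sys.frc[3 * i];
    forces(i, 1) = sys.frc[3 * i + 1];
    forces(i, 2) = sys.frc[3 * i + 2];
  }
  double v = sys.box[0] * sys.box[1] * sys.box[2];
  NumericVector vir(3);
  for (int a = 0; a < 3; ++a) vir[a] = sys.virial[a] / v;
  return List::create(
    _["forces"] = forces,
    _["energy"] = sys.e_pair + sys.e_bond,
    _["energy_pair"] = sys.e_pair,
    _["energy_bond"] = sys.e_bond,
    _["virial_pressure"] = vir);
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix positions, NumericMatrix velocities,
                NumericVector box, IntegerVector type, NumericVector charge,
                IntegerMatrix bonds, List ffl,
                int n_steps, double dt, double temperature, double friction,
                int seed, int report_every, bool store_frames,
                NumericVector box_end, int step_offset = 0,
                bool thermostat = true, double abort_temp_factor = 10.0,
                double fcap = 0.0) {
  ForceField ff = ff_from_list(ffl);
  System sys = system_from_args(positions, box, type, charge, bonds, ff);
  bool has_vel = velocities.nrow() == sys.n;
  if (has_vel) {
    for (int i = 0; i < sys.n; ++i) {
      sys.vel[3 * i] = velocities(i, 0);
      sys.vel[3 * i + 1] = velocities(i, 1);
      sys.vel[3 * i + 2] = velocities(i, 2);
    }
  } else if (thermostat && temperature > 0) {
    // Maxwell-Boltzmann initialization from the counter-based stream
    for (int i = 0; i < sys.n; ++i) {
      double g[4];
      gauss4(static_cast<uint64_t>(seed), 0xfffffffeULL, i, g);
      double s = std::sqrt(KB * temperature / sys.mass[i]);
      for (int a = 0; a < 3; ++a) sys.vel[3 * i + a] = s * g[a];
    }
  }

  // optional box deformation schedule (linear in edge lengths)
  bool deform = box_end.size() == 3;
  double box0[3] = {sys.box[0], sys.box[1], sys.box[2]};

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  bool noise = thermostat && temperature > 0 && friction > 0;

  // per-bead force-magnitude cap: used while relaxing freshly assembled or
  // compressing configurations; 0 disables (production default)
  auto cap_forces = [&]() {
    if (fcap <= 0.0) return;
    for (int i = 0; i < sys.n; ++i) {
      double fx = sys.frc[3 * i], fy = sys.frc[3 * i + 1],
             fz = sys.frc[3 * i + 2];
      double f2 = fx * fx + fy * fy + fz * fz;
      if (f2 > fcap * fcap) {
        double s = fcap / std::sqrt(f2);
        sys.frc[3 * i] *= s;
        sys.frc[3 * i + 1] *= s;
        sys.frc[3 * i + 2] *= s;
      }
    }
  };

  sys.wrap();
  sys.build_neighbours(ff);
  sys.compute_forces(ff, false);
  cap_forces();
  int n_rebuilds = 0;

  int n_report = (report_every > 0) ? (n_steps / report_every) : 0;
  std::vector<double> st_step, st_epot, st_ekin, st_temp, st_pxx, st_pyy,
      st_pzz, st_lz;
  List frames(store_frames ? n_report + 1 : 0);
  int frame_idx = 0;
  auto snapshot = [&]() {
    NumericMatrix fr(sys.n, 3);
    for (int i = 0; i < sys.n; ++i) {
      fr(i, 0) = sys.pos[3 * i];
      fr(i, 1) = sys.pos[3 * i + 1];
      fr(i, 2) = sys.pos[3 * i + 2];
    }
    frames[frame_idx++] = fr;
  };
  auto record = [&](int step) {
    double ke = sys.kinetic_energy();
    double p[3];
    sys.pressure_tensor(p);
    st_step.push_back(step + step_offset);
    st_epot.push_back(sys.e_pair + sys.e_bond);
    st_ekin.push_back(ke);
    st_temp.push_back(2.0 * ke / (3.0 * sys.n * KB));
    st_pxx.push_back(p[0]);
    st_pyy.push_back(p[1]);
    st_pzz.push_back(p[2]);
    st_lz.push_back(sys.box[2]);
  };
  if (store_frames) snapshot();
  record(0);

  bool aborted = false;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < sys.n; ++i) {
      double inv = 0.5 * dt / sys.mass[i];
      sys.vel[3 * i] += inv * sys.frc[3 * i];
      sys.vel[3 * i + 1] += inv * sys.frc[3 * i + 1];
      sys.vel[3 * i + 2] += inv * sys.frc[3 * i + 2];
    }
    // A
    for (int k = 0; k < 3 * sys.n; ++k) sys.pos[k] += 0.5 * dt * sys.vel[k];
    // O
    if (noise) {
      uint64_t ustep = static_cast<uint64_t>(step + step_offset);
      for (int i = 0; i < sys.n; ++i) {
        double g[4];
        gauss4(static_cast<uint64_t>(seed), ustep, i, g);
        double s = c2 * std::sqrt(KB * temperature / sys.mass[i]);
        for (int a = 0; a < 3; ++a) {
          sys.vel[3 * i + a] = c1 * sys.vel[3 * i + a] + s * g[a];
        }
      }
    } else if (friction > 0) {
      for (int k = 0; k < 3 * sys.n; ++k) sys.vel[k] *= c1;
    }
    // A
    for (int k = 0; k < 3 * sys.n; ++k) sys.pos[k] += 0.5 * dt * sys.vel[k];
    // box deformation (affine rescaling of positions)
    if (deform) {
      double fscale = static_cast<double>(step) / n_steps;
      for (int a = 0; a < 3; ++a) {
        double newL = box0[a] + fscale * (box_end[a] - box0[a]);
        double s = newL / sys.box[a];
        if (s != 1.0) {
          for (int i = 0; i < sys.n; ++i) sys.pos[3 * i + a] *= s;
          sys.box[a] = newL;
        }
      }
      // the affine shift is tiny per step; the Verlet displacement
      // criterion below picks it up through pos_at_build
    }
    sys.wrap();
    if (sys.needs_rebuild()) {
      sys.build_neighbours(ff);
      ++n_rebuilds;
    }
    sys.compute_forces(ff, false);
    cap_forces();
    // B
    for (int i = 0; i < sys.n; ++i) {
      double inv = 0.5 * dt / sys.mass[i];
      sys.vel[3 * i] += inv * sys.frc[3 * i];
      sys.vel[3 * i + 1] += inv * sys.frc[3 * i + 1];
      sys.vel[3 * i + 2] += inv * sys.frc[3 * i + 2];
    }

    if (report_every > 0 && step % report_every == 0) {
      record(step);
      if (store_frames) snapshot();
      // stability guard: runaway kinetic temperature aborts with partial output
      if (thermostat && temperature > 0 &&
          st_temp.back() > abort_temp_factor * temperature) {
        aborted = true;
        break;
      }
      Rcpp::checkUserInterrupt();
    }
    if (!std::isfinite(sys.frc[0])) {
      aborted = true;
      break;
    }
  }

  NumericMatrix out_pos(sys.n, 3), out_vel(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    for (int a = 0; a < 3; ++a) {
      out_pos(i, a) = sys.pos[3 * i + a];
      out_vel(i, a) = sys.vel[3 * i + a];
    }
  }
  if (store_frames && frame_idx < frames.size()) {
    frames = frames[Range(0, std::max(frame_idx - 1, 0))];
  }
  return List::create(
    _["positions"] = out_pos,
    _["velocities"] = out_vel,
    _["box"] = NumericVector::create(sys.box[0], sys.box[1], sys.box[2]),
    _["frames"] = frames,
    _["stats"] = DataFrame::create(
      _["step"] = st_step, _["e_pot"] = st_epot, _["e_kin"] = st_ekin,
      _["temperature"] = st_temp, _["p_xx"] = st_pxx, _["p_yy"] = st_pyy,
      _["p_zz"] = st_pzz, _["lz"] = st_lz),
    _["n_rebuilds"] = n_rebuilds,
    _["aborted"] = aborted);
}

// inter-molecular contact counts for the bond-ratio observable: a contact is
// an inter-molecular bead pair with r < cutoff_factor * sigma_ij
// [[Rcpp::export]]
List cpp_count_contacts(NumericMatrix positions, NumericVector box,
                        IntegerVector type, IntegerVector molecule,
                        IntegerVector species, List ffl,
                        double cutoff_factor, int target_species) {
  ForceField ff = ff_from_list(ffl);
  int n = positions.nrow();
  double L[3] = {box[0], box[1], box[2]};
  double hetero = 0.0, homo = 0.0;
  double cf2 = cutoff_factor * cutoff_factor;
  for (int i = 0; i < n; ++i) {
    if (ff.is_core[type[i]]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (molecule[i] == molecule[j]) continue;
      if (ff.is_core[type[j]]) continue;
      bool i_t = species[i] == target_species;
      bool j_t = species[j] == target_species;
      if (!i_t && !j_t) continue;
      double d2 = 0.0;
      for (int a = 0; a < 3; ++a) {
        double d = positions(i, a) - positions(j, a);
        d -= L[a] * std::round(d / L[a]);
        d2 += d * d;
      }
      if (d2 < cf2 * ff.sig2_ij[type[i] * ff.n_types + type[j]]) {
        if (i_t && j_t) homo += 1.0;
        else hetero += 1.0;
      }
    }
  }
  return List::create(_["heterotypic"] = hetero, _["homotypic"] = homo);
}
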