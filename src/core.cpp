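#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Units: A, ps, amu, kcal/mol, K.
static const double KB_KCAL = 0.0019872041;   // kcal/(mol K)
static const double AKMA = 418.4;             // (kcal/mol)/(amu) -> A^2/ps^2
static const double COULOMB_KCAL = 332.0636;  // q1*q2/r in e^2/A -> kcal/mol
static const double REP_CAP = 1e3;            // kcal/mol, soft-sphere cap

struct Potential {
  NumericMatrix wells;   // k x 5: cx, cy, cz, depth, width
  NumericMatrix beads;   // m x 3 receptor bead positions
  double eps, sigma;
  bool use_coulomb;
  NumericVector bead_charge;  // length m
  double dielectric;
};

static Potential unpack(const List &pot) {
  Potential p;
  p.wells = as<NumericMatrix>(pot["wells"]);
  p.beads = as<NumericMatrix>(pot["beads"]);
  p.eps = as<double>(pot["eps"]);
  p.sigma = as<double>(pot["sigma"]);
  p.use_coulomb = as<bool>(pot["use_coulomb"]);
  if (p.use_coulomb) {
    p.bead_charge = as<NumericVector>(pot["bead_charge"]);
    p.dielectric = as<double>(pot["dielectric"]);
  } else {
    p.dielectric = 1.0;
  }
  return p;
}

// Energy of a single ligand atom at (x,y,z); optionally accumulate force.
static double atom_energy_force(const Potential &p, double q,
                                double x, double y, double z,
                                double *fx, double *fy, double *fz) {
  double U = 0.0;
  const int nw = p.wells.nrow(), nb = p.beads.nrow();
  for (int k = 0; k < nw; ++k) {
    double dx = x - p.wells(k, 0), dy = y - p.wells(k, 1), dz = z - p.wells(k, 2);
    double depth = p.wells(k, 3), w = p.wells(k, 4);
    double r2 = dx * dx + dy * dy + dz * dz;
    double e = -depth * std::exp(-r2 / (2.0 * w * w));
    U += e;
    if (fx) {
      // dU/dr_i = -e * r_i / w^2 ; force = -dU/dr
      double g = e / (w * w);
      *fx += g * dx; *fy += g * dy; *fz += g * dz;
    }
  }
  const double s2 = p.sigma * p.sigma;
  for (int b = 0; b < nb; ++b) {
    double dx = x - p.beads(b, 0), dy = y - p.beads(b, 1), dz = z - p.beads(b, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (p.eps > 0.0) {
      if (r2 <= 0.0) {
        U += REP_CAP;  // coincident with a bead center: capped, zero force
      } else {
        double sr2 = s2 / r2;
        double sr6 = sr2 * sr2 * sr2;
        double rep = p.eps * sr6 * sr6;
        if (rep >= REP_CAP) {
          U += REP_CAP;  // flat cap region: no force contribution
        } else {
          U += rep;
          if (fx) {
            double g = 12.0 * rep / r2;  // force = +12 rep / r^2 * dr (repulsive)
            *fx += g * dx; *fy += g * dy; *fz += g * dz;
          }
        }
      }
    }
    if (p.use_coulomb && q != 0.0 && r2 > 0.0) {
      double r = std::sqrt(r2);
      double qq = COULOMB_KCAL * q * p.bead_charge[b] / p.dielectric;
      U += qq / r;
      if (fx) {
        double g = qq / (r2 * r);
        *fx += g * dx; *fy += g * dy; *fz += g * dz;
      }
    }
  }
  return U;
}

// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix lig, NumericVector charge, List pot) {
  Potential p = unpack(pot);
  double U = 0.0;
  for (int i = 0; i < lig.nrow(); ++i)
    U += atom_energy_force(p, charge[i], lig(i, 0), lig(i, 1), lig(i, 2),
                           nullptr, nullptr, nullptr);
  return U;
}

// [[Rcpp::export]]
NumericMatrix cpp_potential_forces(NumericMatrix lig, NumericVector charge, List pot) {
  Potential p = unpack(pot);
  NumericMatrix F(lig.nrow(), 3);
  for (int i = 0; i < lig.nrow(); ++i) {
    double fx = 0, fy = 0, fz = 0;
    atom_energy_force(p, charge[i], lig(i, 0), lig(i, 1), lig(i, 2), &fx, &fy, &fz);
    F(i, 0) = fx; F(i, 1) = fy; F(i, 2) = fz;
  }
  return F;
}

// BAOAB Langevin integrator for the mobile ligand atoms; receptor beads are
// frozen. Reflecting walls at +/- box_half. Frames are recorded every
// frame_every steps (not including the initial state). Uses R's RNG stream.
// [[Rcpp::export]]
List cpp_baoab(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
               NumericVector charge, List pot, double dt, int nsteps,
               double friction, double temperature, int frame_every,
               NumericVector box_half) {
  Potential p = unpack(pot);
  const int n = pos0.nrow();
  NumericMatrix x(clone(pos0)), v(clone(vel0));
  const double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  const int nframes = (frame_every > 0) ? nsteps / frame_every : 0;
  NumericVector frames(Dimension(n, 3, std::max(nframes, 0)));
  std::vector<double> c2(n);
  for (int i = 0; i < n; ++i)
    c2[i] = (friction > 0.0 && temperature > 0.0)
              ? std::sqrt((1.0 - c1 * c1) * KB_KCAL * temperature * AKMA / mass[i])
              : 0.0;

  // initial forces
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    double fx = 0, fy = 0, fz = 0;
    atom_energy_force(p, charge[i], x(i, 0), x(i, 1), x(i, 2), &fx, &fy, &fz);
    F(i, 0) = fx; F(i, 1) = fy; F(i, 2) = fz;
  }

  int frame = 0;
  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      double s = 0.5 * dt * AKMA / mass[i];
      // B
      for (int d = 0; d < 3; ++d) v(i, d) += s * F(i, d);
      // A
      for (int d = 0; d < 3; ++d) x(i, d) += 0.5 * dt * v(i, d);
      // O
      if (friction > 0.0) {
        for (int d = 0; d < 3; ++d) v(i, d) = c1 * v(i, d) + c2[i] * norm_rand();
      }
      // A
      for (int d = 0; d < 3; ++d) x(i, d) += 0.5 * dt * v(i, d);
      // reflecting walls
      for (int d = 0; d < 3; ++d) {
        double h = box_half[d];
        while (x(i, d) > h || x(i, d) < -h) {
          if (x(i, d) > h) x(i, d) = 2.0 * h - x(i, d);
          else x(i, d) = -2.0 * h - x(i, d);
          v(i, d) = -v(i, d);
        }
      }
      // B (new forces)
      double fx = 0, fy = 0, fz = 0;
      atom_energy_force(p, charge[i], x(i, 0), x(i, 1), x(i, 2), &fx, &fy, &fz);
      F(i, 0) = fx; F(i, 1) = fy; F(i, 2) = fz;
      for (int d = 0; d < 3; ++d) v(i, d) += s * F(i, d);
      if (!std::isfinite(x(i, 0)) || !std::isfinite(x(i, 1)) || !std::isfinite(x(i, 2)))
        stop("integration blow-up: non-finite coordinates at step %d", step);
    }
    if (frame_every > 0 && step % frame_every == 0 && frame < nframes) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[i + n * d + 3 * n * frame] = x(i, d);
      ++frame;
    }
  }
  return List::create(_["frames"] = frames, _["nframes"] = nframes,
                      _["pos"] = x, _["vel"] = v);
}
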