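#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "kc_ff.h"

using namespace Rcpp;

namespace kc {

FFData parse_ff(const List& ff) {
  FFData d;
  IntegerMatrix bonds = ff["bonds"];
  NumericVector br0 = ff["bond_r0"];
  d.k_bond = as<double>(ff["k_bond"]);
  for (int i = 0; i < bonds.nrow(); ++i)
    d.bonds.push_back({bonds(i, 0), bonds(i, 1), br0[i]});

  IntegerMatrix ang = ff["angles"];
  NumericVector th0 = ff["angle_th0"];
  d.k_angle = as<double>(ff["k_angle"]);
  for (int i = 0; i < ang.nrow(); ++i)
    d.angles.push_back({ang(i, 0), ang(i, 1), ang(i, 2), th0[i]});

  IntegerMatrix dih = ff["dihedrals"];
  NumericVector ph0 = ff["dihedral_phi0"];
  NumericVector kd = ff["k_dihedral"];
  for (int i = 0; i < dih.nrow(); ++i)
    d.dihedrals.push_back({dih(i, 0), dih(i, 1), dih(i, 2), dih(i, 3), ph0[i],
                           kd[i], std::cos(ph0[i]), std::sin(ph0[i])});

  IntegerMatrix con = ff["contacts"];
  NumericVector cr0 = ff["contact_r0"];
  d.eps = as<double>(ff["eps_contact"]);
  d.sigma_g = as<double>(ff["sigma_g"]);
  d.r_ex = as<double>(ff["r_ex"]);
  for (int i = 0; i < con.nrow(); ++i)
    d.contacts.push_back({con(i, 0), con(i, 1), cr0[i]});

  IntegerMatrix nn = ff["nonnative"];
  for (int i = 0; i < nn.nrow(); ++i)
    d.nonnative.push_back({nn(i, 0), nn(i, 1)});
  d.nn_cut = 2.5 * d.r_ex;
  d.nn_shift = std::pow(d.r_ex / d.nn_cut, 12);

  d.has_cage = as<bool>(ff["has_cage"]);
  if (d.has_cage) {
    d.cage_L = as<double>(ff["cage_L"]);        // Angstrom
    d.cage_eps = as<double>(ff["cage_eps"]);
    d.cage_cut = as<double>(ff["cage_cutoff"]);
  }
  return d;
}

static inline double wall_term(double dist, double eps_c, double cut,
                               double* dVdd) {
  // V(d) = eps_c * ((2/d)^2 - 1)^2 for d < cut (cut = 2 A by default);
  // both V and dV/dd vanish at d = 2, so the truncation is smooth.
  if (dist >= cut) { if (dVdd) *dVdd = 0.0; return 0.0; }
  if (dist <= 0.0) stop("bead outside cage");
  double u = 4.0 / (dist * dist);   // (2/d)^2
  double um1 = u - 1.0;
  if (dVdd) *dVdd = 2.0 * eps_c * um1 * (-8.0 / (dist * dist * dist));
  return eps_c * um1 * um1;
}

// energy/forces in one pass; forces optional
double eval_ff(const FFData& d, const double* x, int n, double* f,
               double* comps) {
  double e_bond = 0, e_angle = 0, e_dih = 0, e_con = 0, e_nn = 0, e_cage = 0;
  if (f) std::fill(f, f + 3 * n, 0.0);

  // bonds
  for (const auto& b : d.bonds) {
    double dx = x[3 * b.j] - x[3 * b.i];
    double dy = x[3 * b.j + 1] - x[3 * b.i + 1];
    double dz = x[3 * b.j + 2] - x[3 * b.i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0) stop("zero distance");
    double dr = r - b.r0;
    e_bond += 0.5 * d.k_bond * dr * dr;
    if (f) {
      double g = d.k_bond * dr / r;  // dV/dr / r
      f[3 * b.i] += g * dx; f[3 * b.i + 1] += g * dy; f[3 * b.i + 2] += g * dz;
      f[3 * b.j] -= g * dx; f[3 * b.j + 1] -= g * dy; f[3 * b.j + 2] -= g * dz;
    }
  }

  // angles: V = 1/2 k (theta - theta0)^2
  for (const auto& a : d.angles) {
    double ux = x[3 * a.i] - x[3 * a.j], uy = x[3 * a.i + 1] - x[3 * a.j + 1],
           uz = x[3 * a.i + 2] - x[3 * a.j + 2];
    double vx = x[3 * a.k] - x[3 * a.j], vy = x[3 * a.k + 1] - x[3 * a.j + 1],
           vz = x[3 * a.k + 2] - x[3 * a.j + 2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - a.th0;
    e_angle += 0.5 * d.k_angle * dth * dth;
    if (f) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double coef = d.k_angle * dth / s;  // = -dV/dth * (-1/sin)
      // dcos/dri and dcos/drk
      double dix = (vx / (nu * nv)) - c * ux / (nu * nu);
      double diy = (vy / (nu * nv)) - c * uy / (nu * nu);
      double diz = (vz / (nu * nv)) - c * uz / (nu * nu);
      double dkx = (ux / (nu * nv)) - c * vx / (nv * nv);
      double dky = (uy / (nu * nv)) - c * vy / (nv * nv);
      double dkz = (uz / (nu * nv)) - c * vz / (nv * nv);
      f[3 * a.i] += coef * dix; f[3 * a.i + 1] += coef * diy; f[3 * a.i + 2] += coef * diz;
      f[3 * a.k] += coef * dkx; f[3 * a.k + 1] += coef * dky; f[3 * a.k + 2] += coef * dkz;
      f[3 * a.j] -= coef * (dix + dkx);
      f[3 * a.j + 1] -= coef * (diy + dky);
      f[3 * a.j + 2] -= coef * (diz + dkz);
    }
  }

  // dihedrals: V = k [ (1 - cos(dphi)) + 1/2 (1 - cos(3 dphi)) ]
  for (const auto& t : d.dihedrals) {
    double b1x = x[3 * t.j] - x[3 * t.i], b1y = x[3 * t.j + 1] - x[3 * t.i + 1],
           b1z = x[3 * t.j + 2] - x[3 * t.i + 2];
    double b2x = x[3 * t.k] - x[3 * t.j], b2y = x[3 * t.k + 1] - x[3 * t.j + 1],
           b2z = x[3 * t.k + 2] - x[3 * t.j + 2];
    double b3x = x[3 * t.l] - x[3 * t.k], b3y = x[3 * t.l + 1] - x[3 * t.k + 1],
           b3z = x[3 * t.l + 2] - x[3 * t.k + 2];
    double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z,
           n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z,
           n2z = b2x * b3y - b2y * b3x;
    double nb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    double mx = n1y * n2z - n1z * n2y, my = n1z * n2x - n1x * n2z,
           mz = n1x * n2y - n1y * n2x;
    double sy = (mx * b2x + my * b2y + mz * b2z) / nb2;
    double sx = n1x * n2x + n1y * n2y + n1z * n2z;
    // sin/cos of (phi - phi0) without atan2, via angle-difference and
    // triple-angle identities (phi0's sin/cos are precomputed)
    double hyp = std::sqrt(sx * sx + sy * sy);
    double cphi, sphi;
    if (hyp < 1e-15) { cphi = 1.0; sphi = 0.0; }
    else { cphi = sx / hyp; sphi = sy / hyp; }
    double cd = cphi * t.cos_phi0 + sphi * t.sin_phi0;   // cos(dphi)
    double sd = sphi * t.cos_phi0 - cphi * t.sin_phi0;   // sin(dphi)
    double c3 = cd * (4.0 * cd * cd - 3.0);              // cos(3 dphi)
    double s3 = sd * (3.0 - 4.0 * sd * sd);              // sin(3 dphi)
    e_dih += t.kphi * ((1.0 - cd) + 0.5 * (1.0 - c3));
    if (f) {
      double dV = t.kphi * (sd + 1.5 * s3);
      double n1sq = n1x * n1x + n1y * n1y + n1z * n1z;
      double n2sq = n2x * n2x + n2y * n2y + n2z * n2z;
      if (n1sq < 1e-16 || n2sq < 1e-16) continue;  // collinear: no torque
      // sign fixed to the atan2 convention used for phi above
      // (validated against central finite differences)
      double c1 = dV * nb2 / n1sq;
      double c4 = -dV * nb2 / n2sq;
      double fix = c1 * n1x, fiy = c1 * n1y, fiz = c1 * n1z;
      double flx = c4 * n2x, fly = c4 * n2y, flz = c4 * n2z;
      double p = (b1x * b2x + b1y * b2y + b1z * b2z) / (nb2 * nb2);
      double q = (b3x * b2x + b3y * b2y + b3z * b2z) / (nb2 * nb2);
      double fjx = -(1.0 + p) * fix + q * flx;
      double fjy = -(1.0 + p) * fiy + q * fly;
      double fjz = -(1.0 + p) * fiz + q * flz;
      double fkx = p * fix - (1.0 + q) * flx;
      double fky = p * fiy - (1.0 + q) * fly;
      double fkz = p * fiz - (1.0 + q) * flz;
      f[3 * t.i] += fix; f[3 * t.i + 1] += fiy; f[3 * t.i + 2] += fiz;
      f[3 * t.j] += fjx; f[3 * t.j + 1] += fjy; f[3 * t.j + 2] += fjz;
      f[3 * t.k] += fkx; f[3 * t.k + 1] += fky; f[3 * t.k + 2] += fkz;
      f[3 * t.l] += flx; f[3 * t.l + 1] += fly; f[3 * t.l + 2] += flz;
    }
  }

  // native contacts: Gaussian well with excluded-volume core
  // V = eps [ (1 + (r_ex/r)^12)(1 - G) - 1 ],  G = exp(-(r-r0)^2 / 2 sigma^2)
  double s2 = d.sigma_g * d.sigma_g;
  double rex2 = d.r_ex * d.r_ex;
  for (const auto& cn : d.contacts) {
    double dx = x[3 * cn.j] - x[3 * cn.i];
    double dy = x[3 * cn.j + 1] - x[3 * cn.i + 1];
    double dz = x[3 * cn.j + 2] - x[3 * cn.i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0) stop("zero distance");
    double u = rex2 / (r * r);
    double u3 = u * u * u;
    double A = u3 * u3;  // (r_ex/r)^12
    double G = std::exp(-(r - cn.r0) * (r - cn.r0) / (2.0 * s2));
    e_con += d.eps * ((1.0 + A) * (1.0 - G) - 1.0);
    if (f) {
      double dVdr = d.eps * (-12.0 * A / r * (1.0 - G) +
                             (1.0 + A) * G * (r - cn.r0) / s2);
      double g = dVdr / r;
      f[3 * cn.i] += g * dx; f[3 * cn.i + 1] += g * dy; f[3 * cn.i + 2] += g * dz;
      f[3 * cn.j] -= g * dx; f[3 * cn.j + 1] -= g * dy; f[3 * cn.j + 2] -= g * dz;
    }
  }

  // non-native excluded volume, truncated and shifted at 2.5 r_ex
  double nn_cut2 = d.nn_cut * d.nn_cut;
  for (const auto& p : d.nonnative) {
    double dx = x[3 * p.second] - x[3 * p.first];
    double dy = x[3 * p.second + 1] - x[3 * p.first + 1];
    double dz = x[3 * p.second + 2] - x[3 * p.first + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= nn_cut2) continue;
    if (r2 <= 0) stop("zero distance");
    double u = rex2 / r2;
    double u3 = u * u * u;
    double A = u3 * u3;
    e_nn += d.eps * (A - d.nn_shift);
    if (f) {
      double g = d.eps * (-12.0 * A) / r2;
      f[3 * p.first] += g * dx; f[3 * p.first + 1] += g * dy; f[3 * p.first + 2] += g * dz;
      f[3 * p.second] -= g * dx; f[3 * p.second + 1] -= g * dy; f[3 * p.second + 2] -= g * dz;
    }
  }

  // cylindrical cage: lateral wall + two caps, each independent
  if (d.has_cage) {
    for (int i = 0; i < n; ++i) {
      double px = x[3 * i], py = x[3 * i + 1], pz = x[3 * i + 2];
      double rho = std::sqrt(px * px + py * py);
      double d_lat = d.cage_L - rho;
      double d_top = d.cage_L - pz;
      double d_bot = d.cage_L + pz;
      if (d_lat <= 0 || d_top <= 0 || d_bot <= 0) stop("bead outside cage");
      double dV;
      if (d_lat < d.cage_cut) {
        e_cage += wall_term(d_lat, d.cage_eps, d.cage_cut, &dV);
        if (f && rho > 1e-12) {
          // d(d_lat)/dx = -x/rho ; F = -dV/dd * d d/dx
          double g = dV / rho;  // -(-dV)*(x/rho)/x... F_x = dV * x / rho
          f[3 * i] += g * px;
          f[3 * i + 1] += g * py;
        }
      }
      if (d_top < d.cage_cut) {
        e_cage += wall_term(d_top, d.cage_eps, d.cage_cut, &dV);
        if (f) f[3 * i + 2] += dV;  // F_z = -dV/dd * (-1)
      }
      if (d_bot < d.cage_cut) {
        e_cage += wall_term(d_bot, d.cage_eps, d.cage_cut, &dV);
        if (f) f[3 * i + 2] -= dV;
      }
    }
  }

  if (comps) {
    comps[0] = e_bond; comps[1] = e_angle; comps[2] = e_dih;
    comps[3] = e_con; comps[4] = e_nn; comps[5] = e_cage;
  }
  return e_bond + e_angle + e_dih + e_con + e_nn + e_cage;
}

}  // namespace kc

// [[Rcpp::export(name = ".ff_energy_cpp")]]
List ff_energy_cpp(NumericMatrix coords, List ff) {
  kc::FFData d = kc::parse_ff(ff);
  int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double comps[6];
  double e = kc::eval_ff(d, x.data(), n, nullptr, comps);
  return List::create(
      _["total"] = e,
      _["components"] = NumericVector::create(
          _["bond"] = comps[0], _["angle"] = comps[1], _["dihedral"] = comps[2],
          _["contact"] = comps[3], _["nonnative"] = comps[4],
          _["cage"] = comps[5]));
}

// [[Rcpp::export(name = ".ff_forces_cpp")]]
NumericMatrix ff_forces_cpp(NumericMatrix coords, List ff) {
  kc::FFData d = kc::parse_ff(ff);
  int n = coords.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  kc::eval_ff(d, x.data(), n, f.data(), nullptr);
  // eval_ff accumulates forces directly: f holds -dE/dx
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = f[3 * i + k];
  return out;
}
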