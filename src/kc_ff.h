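#ifndef KC_FF_H
#define KC_FF_H

#include <Rcpp.h>
#include <vector>
#include <utility>

namespace kc {

struct Bond { int i, j; double r0; };
struct Angle { int i, j, k; double th0; };
struct Dihedral { int i, j, k, l; double phi0, kphi, cos_phi0, sin_phi0; };
struct Contact { int i, j; double r0; };

struct FFData {
  std::vector<Bond> bonds;
  std::vector<Angle> angles;
  std::vector<Dihedral> dihedrals;
  std::vector<Contact> contacts;
  std::vector<std::pair<int, int> > nonnative;
  double k_bond, k_angle;
  double eps, sigma_g, r_ex, nn_cut, nn_shift;
  bool has_cage;
  double cage_L, cage_eps, cage_cut;
};

FFData parse_ff(const Rcpp::List& ff);
double eval_ff(const FFData& d, const double* x, int n, double* f,
               double* comps);

}  // namespace kc

#endif
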