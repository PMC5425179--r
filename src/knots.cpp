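#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };
static inline V3 sub(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

// Does segment PQ intersect triangle ABC?  Conservative: borderline cases
// report an intersection (so KMT keeps the vertex; topology is never broken
// by refusing a deletion).
bool seg_hits_tri(const V3& P, const V3& Q, const V3& A, const V3& B,
                  const V3& C, double scale) {
  const double eps = 1e-10 * scale;
  V3 ab = sub(B, A), ac = sub(C, A);
  V3 n = cross(ab, ac);
  double nn = norm(n);
  if (nn < 1e-14 * scale * scale) return false;  // degenerate triangle: caller handles
  double d1 = dot(n, sub(P, A));
  double d2 = dot(n, sub(Q, A));
  if (d1 > eps * nn && d2 > eps * nn) return false;
  if (d1 < -eps * nn && d2 < -eps * nn) return false;
  double denom = d1 - d2;
  if (std::fabs(denom) < 1e-14 * nn) return true;  // coplanar-ish: conservative
  double t = d1 / denom;
  if (t < -1e-12 || t > 1.0 + 1e-12) return false;
  V3 X = {P.x + t * (Q.x - P.x), P.y + t * (Q.y - P.y), P.z + t * (Q.z - P.z)};
  // barycentric with tolerance: borderline counts as inside
  V3 ax = sub(X, A);
  double d00 = dot(ab, ab), d01 = dot(ab, ac), d11 = dot(ac, ac);
  double d20 = dot(ax, ab), d21 = dot(ax, ac);
  double den = d00 * d11 - d01 * d01;
  if (std::fabs(den) < 1e-20) return true;
  double u = (d11 * d20 - d01 * d21) / den;
  double v = (d00 * d21 - d01 * d20) / den;
  double tol = 1e-9;
  return (u >= -tol && v >= -tol && u + v <= 1.0 + tol);
}

}  // namespace

// KMT chain reduction: repeatedly delete an interior vertex whose triangle
// with its two neighbours is crossed by no other chain segment.
// [[Rcpp::export(name = ".kmt_reduce_cpp")]]
List kmt_reduce_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  if (n < 3) {
    IntegerVector idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i + 1;
    return List::create(_["coords"] = coords, _["indices"] = idx);
  }
  std::vector<V3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    if (i) scale = std::max(scale, norm(sub(P[i], P[i - 1])));
  }
  if (scale <= 0) scale = 1.0;

  std::vector<int> keep(n);
  for (int i = 0; i < n; ++i) keep[i] = i;

  bool changed = true;
  while (changed && keep.size() > 2) {
    changed = false;
    for (size_t pos = 1; pos + 1 < keep.size();) {
      const V3& A = P[keep[pos - 1]];
      const V3& B = P[keep[pos]];
      const V3& C = P[keep[pos + 1]];
      V3 nvec = cross(sub(B, A), sub(C, A));
      bool deletable;
      if (norm(nvec) < 1e-12 * scale * scale) {
        deletable = true;  // zero-area triangle never encloses anything
      } else {
        deletable = true;
        for (size_t q = 0; q + 1 < keep.size(); ++q) {
          if (q == pos - 1 || q == pos) continue;  // the triangle's own edges
          V3 Pq = P[keep[q]], Qq = P[keep[q + 1]];
          // segments attached at corner A or C: trim the shared endpoint so
          // mere corner contact does not block the deletion
          const double trim = 1e-7;
          if (q + 1 == pos - 1) {  // ends at A
            Qq = {Qq.x + trim * (Pq.x - Qq.x), Qq.y + trim * (Pq.y - Qq.y),
                  Qq.z + trim * (Pq.z - Qq.z)};
          }
          if (q == pos + 1) {  // starts at C
            Pq = {Pq.x + trim * (Qq.x - Pq.x), Pq.y + trim * (Qq.y - Pq.y),
                  Pq.z + trim * (Qq.z - Pq.z)};
          }
          if (seg_hits_tri(Pq, Qq, A, B, C, scale)) {
            deletable = false;
            break;
          }
        }
      }
      if (deletable) {
        keep.erase(keep.begin() + pos);
        changed = true;
      } else {
        ++pos;
      }
    }
  }

  int m = (int)keep.size();
  NumericMatrix out(m, 3);
  IntegerVector idx(m);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = P[keep[i]].x; out(i, 1) = P[keep[i]].y; out(i, 2) = P[keep[i]].z;
    idx[i] = keep[i] + 1;
  }
  return List::create(_["coords"] = out, _["indices"] = idx);
}

// One projection of a *closed* polygon -> crossing diagram -> |Alexander(-1)|
// plus diagram writhe.  Returns ok = FALSE when the projection is degenerate
// (crossing at a vertex, parallel overlap, ambiguous height) and should be
// resampled.  At t = -1 the Alexander row is sign-independent:
// -1 (under-in), -1 (under-out), +2 (over).
// [[Rcpp::export(name = ".alexander_proj_cpp")]]
List alexander_proj_cpp(NumericMatrix coords, NumericMatrix rot) {
  int n = coords.nrow();
  std::vector<double> px(n), py(n), pz(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    px[i] = rot(0, 0) * x + rot(0, 1) * y + rot(0, 2) * z;
    py[i] = rot(1, 0) * x + rot(1, 1) * y + rot(1, 2) * z;
    pz[i] = rot(2, 0) * x + rot(2, 1) * y + rot(2, 2) * z;
    scale = std::max(scale, std::fabs(px[i]) + std::fabs(py[i]));
  }
  if (scale <= 0) scale = 1.0;
  const double deg = 1e-9;

  struct Crossing { double pos_over, pos_under; int sgn; };
  std::vector<Crossing> cr;

  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2) continue;  // adjacent edges share a vertex
      double ax = px[i], ay = py[i];
      double bx = px[i2] - ax, by = py[i2] - ay;
      double cx = px[j], cy = py[j];
      double dx = px[j2] - cx, dy = py[j2] - cy;
      double den = bx * dy - by * dx;
      double ex = cx - ax, ey = cy - ay;
      if (std::fabs(den) < 1e-13 * scale * scale) {
        // parallel: overlapping parallel segments are degenerate
        double crossp = ex * by - ey * bx;
        if (std::fabs(crossp) < deg * scale * scale)
          return List::create(_["ok"] = false);
        continue;
      }
      double s = (ex * dy - ey * dx) / den;
      double t = (ex * by - ey * bx) / den;
      if (s <= -deg || s >= 1 + deg || t <= -deg || t >= 1 + deg) continue;
      if (s < deg || s > 1 - deg || t < deg || t > 1 - deg)
        return List::create(_["ok"] = false);  // crossing at a vertex
      double z1 = pz[i] + s * (pz[i2] - pz[i]);
      double z2 = pz[j] + t * (pz[j2] - pz[j]);
      if (std::fabs(z1 - z2) < deg * scale)
        return List::create(_["ok"] = false);
      bool i_over = z1 > z2;
      // sign from (over direction) x (under direction)
      double cp = i_over ? (bx * dy - by * dx) : (dx * by - dy * bx);
      Crossing c;
      c.sgn = cp > 0 ? 1 : -1;
      if (i_over) { c.pos_over = i + s; c.pos_under = j + t; }
      else        { c.pos_over = j + t; c.pos_under = i + s; }
      cr.push_back(c);
    }
  }

  int nc = (int)cr.size();
  int wr = 0;
  for (auto& c : cr) wr += c.sgn;
  if (nc == 0)
    return List::create(_["ok"] = true, _["det"] = 1.0, _["writhe"] = 0,
                        _["n_crossings"] = 0);

  // arcs delimited by sorted underpass positions
  std::vector<double> ev(nc);
  for (int c = 0; c < nc; ++c) ev[c] = cr[c].pos_under;
  std::vector<int> ord(nc);
  for (int c = 0; c < nc; ++c) ord[c] = c;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return ev[a] < ev[b]; });
  std::vector<double> evs(nc);
  for (int k = 0; k < nc; ++k) evs[k] = ev[ord[k]];
  // rank of crossing c's under event
  std::vector<int> rank(nc);
  for (int k = 0; k < nc; ++k) rank[ord[k]] = k;

  auto arc_of = [&](double pos) {
    // arc k runs from evs[k] to evs[k+1] (cyclic)
    int lo = (int)(std::upper_bound(evs.begin(), evs.end(), pos) - evs.begin()) - 1;
    if (lo < 0) lo = nc - 1;
    return lo;
  };

  if (nc == 1)
    return List::create(_["ok"] = true, _["det"] = 1.0, _["writhe"] = wr,
                        _["n_crossings"] = 1);

  std::vector<std::vector<double> > M(nc, std::vector<double>(nc, 0.0));
  for (int c = 0; c < nc; ++c) {
    int under_out = rank[c];
    int under_in = (rank[c] - 1 + nc) % nc;
    int over = arc_of(cr[c].pos_over);
    M[c][over] += 2.0;
    M[c][under_in] -= 1.0;
    M[c][under_out] -= 1.0;
  }

  // |det| of the (nc-1)x(nc-1) minor, plain LU with partial pivoting
  int m = nc - 1;
  double det = 1.0;
  for (int col = 0; col < m; ++col) {
    int piv = col;
    for (int r = col + 1; r < m; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
    if (std::fabs(M[piv][col]) < 1e-12) { det = 0.0; break; }
    if (piv != col) { std::swap(M[piv], M[col]); det = -det; }
    det *= M[col][col];
    for (int r = col + 1; r < m; ++r) {
      double fac = M[r][col] / M[col][col];
      for (int cc = col; cc < m; ++cc) M[r][cc] -= fac * M[col][cc];
    }
  }
  double adet = std::floor(std::fabs(det) + 0.5);
  return List::create(_["ok"] = true, _["det"] = adet, _["writhe"] = wr,
                      _["n_crossings"] = nc);
}

// Per-frame contact distance matrix helper: for each frame and each listed
// pair, is |r_i - r_j| < 1.2 r0 ?  frames is 3 x n x nf (as stored by the
// integrator); pairs are 0-based.
// [[Rcpp::export(name = ".contact_formed_cpp")]]
LogicalMatrix contact_formed_cpp(NumericVector frames, IntegerMatrix pairs,
                                 NumericVector r0, double factor) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[1], nf = dim[2];
  int np = pairs.nrow();
  LogicalMatrix out(nf, np);
  const double* fp = frames.begin();
  for (int f = 0; f < nf; ++f) {
    const double* base = fp + (R_xlen_t)f * 3 * n;
    for (int p = 0; p < np; ++p) {
      int i = pairs(p, 0), j = pairs(p, 1);
      double dx = base[3 * i] - base[3 * j];
      double dy = base[3 * i + 1] - base[3 * j + 1];
      double dz = base[3 * i + 2] - base[3 * j + 2];
      double lim = factor * r0[p];
      out(f, p) = (dx * dx + dy * dy + dz * dz) < lim * lim;
    }
  }
  return out;
}

// KMT reduction of a *closed* polygon (cyclic indices, no fixed endpoints):
// every deletion is a legal isotopy of the closed curve, so the knot type
// is preserved exactly.  Used by knot typing after closure.
// [[Rcpp::export(name = ".kmt_reduce_closed_cpp")]]
NumericMatrix kmt_reduce_closed_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  std::vector<V3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    int j = (i + 1) % n;
    double d = norm(sub(P[j], P[i]));
    if (d > scale) scale = d;
  }
  if (scale <= 0) scale = 1.0;

  std::vector<int> keep(n);
  for (int i = 0; i < n; ++i) keep[i] = i;

  bool changed = true;
  while (changed && (int)keep.size() > 4) {
    changed = false;
    int m = (int)keep.size();
    for (int pos = 0; pos < m && m > 4; ++pos) {
      int prev = (pos - 1 + m) % m, next = (pos + 1) % m;
      const V3& A = P[keep[prev]];
      const V3& B = P[keep[pos]];
      const V3& C = P[keep[next]];
      V3 nvec = cross(sub(B, A), sub(C, A));
      bool deletable;
      if (norm(nvec) < 1e-12 * scale * scale) {
        deletable = true;
      } else {
        deletable = true;
        for (int q = 0; q < m; ++q) {
          if (q == prev || q == pos) continue;  // the triangle's own edges
          int q2 = (q + 1) % m;
          V3 Pq = P[keep[q]], Qq = P[keep[q2]];
          const double trim = 1e-7;
          if (q2 == prev) {  // edge ending at corner A
            Qq = {Qq.x + trim * (Pq.x - Qq.x), Qq.y + trim * (Pq.y - Qq.y),
                  Qq.z + trim * (Pq.z - Qq.z)};
          }
          if (q == next) {  // edge starting at corner C
            Pq = {Pq.x + trim * (Qq.x - Pq.x), Pq.y + trim * (Qq.y - Pq.y),
                  Pq.z + trim * (Qq.z - Pq.z)};
          }
          if (seg_hits_tri(Pq, Qq, A, B, C, scale)) {
            deletable = false;
            break;
          }
        }
      }
      if (deletable) {
        keep.erase(keep.begin() + pos);
        changed = true;
        m = (int)keep.size();
        --pos;
      }
    }
  }

  int m = (int)keep.size();
  NumericMatrix out(m, 3);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = P[keep[i]].x; out(i, 1) = P[keep[i]].y; out(i, 2) = P[keep[i]].z;
  }
  return out;
}
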