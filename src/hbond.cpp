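// Geometric hydrogen-bond detection: donor X-H ... acceptor X' qualifies when
// the X-H...X' angle is >= a cutoff (120 deg) and the H...X' distance is <= a
// cutoff (3.5 A). Donor/acceptor candidate lists are prepared in R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double angle_deg(const double* x, const double* h,
                               const double* a) {
  double u[3], v[3];
  for (int k = 0; k < 3; ++k) { u[k] = x[k]-h[k]; v[k] = a[k]-h[k]; }
  double du = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
  double dv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
  double ct = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (du*dv);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return std::acos(ct) * 180.0 / M_PI;
}

static inline double dist3(const double* a, const double* b) {
  double dx = a[0]-b[0], dy = a[1]-b[1], dz = a[2]-b[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// donors: m x 2 matrix (heavy-atom index, hydrogen index), 0-based;
// acceptors: candidate N/O indices; resid: residue of every atom.
// [[Rcpp::export]]
IntegerVector hbond_count_cpp(NumericVector coords, IntegerMatrix donors,
                              IntegerVector acceptors, IntegerVector resid,
                              double min_angle, double max_dist) {
  IntegerVector dim = coords.attr("dim");
  const int natoms = dim[0], nframes = dim[2];
  IntegerVector counts(nframes);
  std::vector<double> fr(3 * natoms);
  for (int f = 0; f < nframes; ++f) {
    const double* slab = REAL(coords) + (R_xlen_t)f * natoms * 3;
    for (int a = 0; a < natoms; ++a)
      for (int k = 0; k < 3; ++k) fr[3*a + k] = slab[a + k*natoms];
    int n = 0;
    for (int d = 0; d < donors.nrow(); ++d) {
      const int xi = donors(d, 0), hi = donors(d, 1);
      const double* X = &fr[3*xi];
      const double* H = &fr[3*hi];
      for (int q = 0; q < acceptors.size(); ++q) {
        const int ai = acceptors[q];
        if (ai == xi || resid[ai] == resid[xi]) continue;
        const double* A = &fr[3*ai];
        if (dist3(H, A) > max_dist + 1e-9) continue;
        if (angle_deg(X, H, A) >= min_angle - 1e-9) ++n;
      }
    }
    counts[f] = n;
  }
  return counts;
}

// Qualifying (donor heavy, hydrogen, acceptor) triples for a single frame.
// [[Rcpp::export]]
IntegerMatrix hbond_triples_cpp(NumericMatrix xyz, IntegerMatrix donors,
                                IntegerVector acceptors, IntegerVector resid,
                                double min_angle, double max_dist) {
  const int natoms = xyz.nrow();
  std::vector<double> fr(3 * natoms);
  for (int a = 0; a < natoms; ++a)
    for (int k = 0; k < 3; ++k) fr[3*a + k] = xyz(a, k);
  std::vector<int> out;
  for (int d = 0; d < donors.nrow(); ++d) {
    const int xi = donors(d, 0), hi = donors(d, 1);
    for (int q = 0; q < acceptors.size(); ++q) {
      const int ai = acceptors[q];
      if (ai == xi || resid[ai] == resid[xi]) continue;
      if (dist3(&fr[3*hi], &fr[3*ai]) > max_dist + 1e-9) continue;
      if (angle_deg(&fr[3*xi], &fr[3*hi], &fr[3*ai]) >= min_angle - 1e-9) {
        out.push_back(xi); out.push_back(hi); out.push_back(ai);
      }
    }
  }
  IntegerMatrix res(out.size() / 3, 3);
  for (int r = 0; r < res.nrow(); ++r)
    for (int k = 0; k < 3; ++k) res(r, k) = out[3*r + k];
  return res;
}
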